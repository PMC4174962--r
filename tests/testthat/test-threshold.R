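test_that("bisection reaches a 10 uA bracket in at most 16 steps", {
  b <- bisect_threshold(function(a) a >= 123.456, c(5, 500), tol_mA = 0.01)
  expect_lte(b$n_bisections, 16)
  expect_lte(diff(b$bracket), 0.01)
  expect_lt(abs(b$threshold_mA - 123.456), 0.01)
  # the bracket actually straddles the true threshold
  expect_lt(b$bracket[1], 123.456)
  expect_gte(b$bracket[2], 123.456)
})

test_that("out-of-range searches are flagged, never clamped", {
  high <- bisect_threshold(function(a) FALSE)
  expect_identical(high$out_of_range, "high")
  expect_true(is.na(high$threshold_mA))
  # active already at 5 mA: bracket extended once to 0.1 mA
  low <- bisect_threshold(function(a) a >= 2)
  expect_identical(low$out_of_range, "low")
  expect_lt(abs(low$threshold_mA - 2), 0.01)
  stuck <- bisect_threshold(function(a) TRUE)
  expect_identical(stuck$out_of_range, "low")
  expect_true(is.na(stuck$threshold_mA))
})

test_that("threshold results are reproducible and carry the search bracket", {
  f <- build_fiber(12)
  prof <- point_source_profile(f)
  r1 <- find_threshold(prof, f, stimulus_waveform(0))
  r2 <- find_threshold(prof, f, stimulus_waveform(0))
  expect_identical(r1$threshold_mA, r2$threshold_mA) # bit-for-bit
  expect_lte(diff(r1$bracket_mA), 0.01)
  expect_identical(r1$out_of_range, "none")
  expect_true(r1$threshold_mA >= 5 && r1$threshold_mA <= 500)
  expect_identical(r1$n_field_solves, 0L) # the search never re-solves
})

test_that("activation monotonicity is checked and diagnosed", {
  expect_true(stimfield:::monotone_activation_pattern(
    c(FALSE, FALSE, TRUE, TRUE)))
  expect_false(stimfield:::monotone_activation_pattern(
    c(FALSE, TRUE, FALSE)))
  expect_true(stimfield:::monotone_activation_pattern(TRUE))
  f <- build_fiber(12)
  prof <- point_source_profile(f)
  th <- find_threshold(prof, f, stimulus_waveform(0))$threshold_mA
  flags <- activation_monotonicity_check(prof, f,
                                         th * c(0.5, 0.9, 1.1, 1.5))
  expect_identical(as.logical(flags), c(FALSE, FALSE, TRUE, TRUE))
  expect_true(attr(flags, "monotone"))
})

test_that("thresholds decrease as the fiber approaches the surface", {
  fix <- cm1_small_solution()
  f <- build_fiber(12)
  th <- vapply(c(3, 8, 14), function(d) {
    pl <- fiber_placement("anterior", d, 12)
    prof <- sample_along(fix$solution,
                         fiber_node_points(cm1_short(), pl,
                                           fix$electrodes, f))
    find_threshold(prof, f, stimulus_waveform(0))$threshold_mA
  }, 0)
  expect_true(all(diff(th) > 0))
})
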