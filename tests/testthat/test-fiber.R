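test_that("fiber geometry follows the diameter conventions", {
  f <- build_fiber(12)
  expect_equal(f$internode_mm, 1.2)
  expect_equal(f$node_count, 53L)
  expect_equal(f$axon_um, 8.4)
  expect_equal(build_fiber(8)$node_count, 79L)
  expect_equal(build_fiber(16)$node_count, 39L)
  # odd count puts a node exactly at the midpoint
  for (d in c(8, 12, 16)) {
    fb <- build_fiber(d)
    expect_true(fb$node_count %% 2 == 1)
    expect_equal(fb$node_z_mm[(fb$node_count + 1) / 2], 0)
    expect_lte(diff(range(fb$node_z_mm)), 63)
  }
  expect_error(build_fiber(12, length_mm = 10), "< 11")
})

test_that("CRRSS steady-state gates are monotone and rest is an equilibrium", {
  V <- seq(-50, 150, by = 1)
  ss <- crrss_steady_state(V)
  expect_true(all(diff(ss$m_inf) > 0))
  expect_true(all(diff(ss$h_inf) < 0))
  r <- crrss_rates(V)
  for (nm in names(r)) expect_true(all(r[[nm]] > 0 & is.finite(r[[nm]])))
  # nodal current at rest vanishes after leak-reversal calibration
  k <- crrss_constants()
  i_rest <- k$g_na_mScm2 * k$m0^2 * k$h0 * (0 - k$e_na_mV) +
    k$g_l_mScm2 * (0 - k$e_l_mV)
  expect_lt(abs(i_rest) / (k$c_n_uFcm2), 1e-6) # dV/dt in mV/ms
})

test_that("the membrane rests stably for 10 ms at all diameters", {
  wf <- stimulus_waveform(0, total_duration_ms = 10)
  for (d in c(8, 12, 16)) {
    f <- build_fiber(d)
    tr <- simulate_response(f, numeric(f$node_count), wf)
    expect_lt(max(abs(tr$V_mV)), 0.1)
    expect_false(tr$activated)
  }
})

test_that("a uniform extracellular profile produces no depolarization", {
  f <- build_fiber(12)
  wf <- stimulus_waveform(100)
  tr <- simulate_response(f, rep(-3, f$node_count), wf)
  expect_lt(max(abs(tr$V_mV)), 1e-6)
})

test_that("suprathreshold stimuli elicit a propagating action potential", {
  f <- build_fiber(12)
  prof <- point_source_profile(f)
  th <- find_threshold(prof, f, stimulus_waveform(0))
  tr <- simulate_response(f, prof, stimulus_waveform(2 * th$threshold_mA))
  expect_true(tr$activated)
  expect_true(all(is.finite(tr$V_mV)))
  # conduction latency increases node by node away from the initiation site
  cross <- tr$crossing_ms
  init <- which.min(cross)
  right <- cross[init:length(cross)]
  expect_true(all(diff(right[!is.na(right)]) > 0))
  left <- cross[init:1]
  expect_true(all(diff(left[!is.na(left)]) > 0))
  # both fiber ends are reached
  expect_false(is.na(cross[1]))
  expect_false(is.na(cross[length(cross)]))
})

test_that("activation detection applies the 80 mV propagation guard", {
  # 79.9 mV everywhere: below threshold
  t1 <- synthetic_trace(rep(60, 53), ifelse(rep(FALSE, 53), 1, NA))
  expect_false(detect_activation(t1)$activated)
  # crossing only at the node under the cathode: no propagation
  cross2 <- rep(NA_real_, 53); cross2[27] <- 0.3
  t2 <- synthetic_trace(c(rep(0, 26), 100, rep(0, 26)), cross2)
  expect_false(detect_activation(t2)$activated)
  # crossings at both ends after a central stimulus: activated
  cross3 <- rep(NA_real_, 53); cross3[c(1, 53)] <- c(1.0, 1.1)
  t3 <- synthetic_trace(c(rep(0, 26), 100, rep(0, 26)), cross3)
  det <- detect_activation(t3)
  expect_true(det$activated)
  expect_equal(det$activation_node, 1L)
  expect_equal(det$conduction_latency_ms, 0.1, tolerance = 1e-12)
})

test_that("strength-duration thresholds decrease with pulse width", {
  f <- build_fiber(12)
  prof <- point_source_profile(f)
  th <- vapply(c(0.1, 0.5, 1.0), function(pw)
    find_threshold(prof, f,
                   stimulus_waveform(0, pulse_width_ms = pw))$threshold_mA,
    0)
  expect_true(all(diff(th) < 0))
})

test_that("larger fibers are recruited first and conduct faster", {
  ths <- c(); vel <- c()
  for (d in c(8, 12, 16)) {
    f <- build_fiber(d)
    prof <- point_source_profile(f)
    th <- find_threshold(prof, f, stimulus_waveform(0))
    ths <- c(ths, th$threshold_mA)
    tr <- simulate_response(f, prof,
                            stimulus_waveform(1.5 * th$threshold_mA))
    cross <- tr$crossing_ms
    ok <- !is.na(cross)
    fit <- stats::coef(stats::lm(tr$node_z_mm[ok][tr$node_z_mm[ok] > 5] ~
                                   cross[ok][tr$node_z_mm[ok] > 5]))
    vel <- c(vel, fit[2]) # mm/ms on the distal limb
  }
  expect_true(all(diff(ths) < 0))  # threshold(8) > threshold(12) > threshold(16)
  expect_true(all(diff(vel) > 0))  # conduction velocity increases with D
})

test_that("halving the time step moves the threshold by less than 0.5%", {
  f <- build_fiber(12)
  prof <- point_source_profile(f)
  t1 <- find_threshold(prof, f, stimulus_waveform(0), dt_ms = 0.002)
  t2 <- find_threshold(prof, f, stimulus_waveform(0), dt_ms = 0.001)
  expect_lt(abs(t1$threshold_mA - t2$threshold_mA) / t2$threshold_mA,
            0.005)
})

test_that("the passive-internode variant also rests stably", {
  f <- build_fiber(12, myelin = "passive")
  wf <- stimulus_waveform(0, total_duration_ms = 2)
  tr <- simulate_response(f, numeric(f$node_count), wf)
  expect_lt(max(abs(tr$V_mV)), 0.1)
})
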