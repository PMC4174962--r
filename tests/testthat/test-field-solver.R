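# Small-scale correctness of the conduction solve; the analytic point-source
# oracles at full resolution live in the acceptance suite.

test_that("potential scales exactly with the injected current", {
  fix <- cm1_small_solution()
  s2 <- solve_unit_field(fix$domain, current_A = 2)
  expect_equal(s2$potential_V, 2 * fix$solution$potential_V,
               tolerance = 1e-12)
})

test_that("current is conserved through transverse planes", {
  fix <- cm1_small_solution()
  # any plane separating the electrodes carries the full injected current
  for (z in c(-1, 0, 1.5))
    expect_lt(abs(abs(flux_through_plane(fix$solution, z)) - 1), 0.01)
  # planes outside the electrode pair carry none
  expect_lt(abs(flux_through_plane(fix$solution, 10)), 0.01)
  # electrode patch currents balance
  expect_equal(electrode_current(fix$solution, "proximal"), -1,
               tolerance = 1e-6)
  expect_equal(electrode_current(fix$solution, "distal"), 1,
               tolerance = 1e-6)
})

test_that("swapping anode and cathode negates the field", {
  fix <- cm1_small_solution()
  el2 <- swap_electrode_roles(fix$electrodes)
  dom2 <- discretize(cm1_short(), el2, resolution_level = 0, base_dof = 3e4)
  s2 <- solve_unit_field(dom2)
  expect_lt(max(abs(s2$potential_V + fix$solution$potential_V)) /
              max(abs(fix$solution$potential_V)), 1e-8)
})

test_that("residual meets the solver tolerance and is reported", {
  fix <- cm1_small_solution()
  expect_lt(fix$solution$solve_residual, 1e-8)
  expect_gt(length(fix$solution$res_hist), 0)
})

test_that("sampling at a cell centre reproduces the nodal value", {
  fix <- pm1_small_solution()
  d <- fix$domain
  ix <- d$ix2[100]; iy <- d$iy2[100]; iz <- 15L
  ctr <- c(d$x0 + (ix - 0.5) * d$h_cm,
           d$y0 + (iy - 0.5) * d$h_cm,
           d$z0 + (iz - 0.5) * d$hz_cm)
  direct <- fix$solution$potential_V[(iz - 1L) * d$n2 + d$map2d[ix, iy]]
  expect_identical(sample_along(fix$solution, rbind(ctr))[1], direct)
  # polar grids share the property: knots of every interpolation stage
  cmfix <- cm1_small_solution()
  dp <- cmfix$domain
  i <- 8L; j <- 10L; iz <- 12L
  ctr_p <- c(dp$r_c[i, j] * cos(dp$theta[j]),
             dp$r_c[i, j] * sin(dp$theta[j]),
             dp$z0 + (iz - 0.5) * dp$hz_cm)
  direct_p <- cmfix$solution$potential_V[(iz - 1L) * dp$n2 + dp$map2d[i, j]]
  expect_equal(sample_along(cmfix$solution, rbind(ctr_p))[1], direct_p,
               tolerance = 1e-10)
})

test_that("points outside the domain are rejected with their index", {
  fix <- cm1_small_solution()
  pts <- rbind(c(0, 3, 0), c(50, 0, 0))
  expect_error(sample_along(fix$solution, pts), "point 2")
})

test_that("the profile is most negative beneath the cathode centre", {
  fix <- cm1_small_solution()
  f <- build_fiber(12)
  pl <- fiber_placement("anterior", 5, 12)
  pts <- fiber_node_points(cm1_short(), pl, fix$electrodes, f)
  prof <- sample_along(fix$solution, pts)
  expect_true(all(prof < 0))
  z_min <- pts[which.min(prof), 3]
  expect_lt(abs(z_min - mean(fix$electrodes$z_ranges$proximal)), 0.7)
})

test_that("the uniform-current-density electrode variant conserves current", {
  fix <- cm1_small_solution()
  s <- solve_unit_field(fix$domain, electrode_model = "uniform")
  expect_lt(abs(abs(flux_through_plane(s, 0)) - 1), 0.01)
})

test_that("PM mid-plane between symmetric electrodes sits at the gauge zero", {
  pm <- pm1_short()
  el <- place_electrodes(pm, "anterior", 9, 4)
  dom <- discretize(pm, el, base_dof = 4e4)
  s <- solve_unit_field(dom)
  pts <- cbind(seq(-8, 8, 1), 5.5, 0)
  expect_lt(max(abs(sample_along(s, pts))) / max(abs(s$potential_V)), 1e-7)
})

test_that("point sources decay toward the unbounded closed form", {
  # coarse sanity check; the quantitative 3% oracle runs in acceptance
  dom <- discretize_box(12, 12, 12, h_cm = 0.4, sigma_t_mSm = 100)
  sol <- solve_point_sources(dom, rbind(c(0, 0, -2), c(0, 0, 2)), c(1, -1),
                             source_radius_cm = 0.8)
  pos <- sol$source_points_cm
  pts <- rbind(pos[1, ] + c(1.2, 0, 0), pos[1, ] + c(2.0, 0, 0))
  v <- sample_along(sol, pts)
  cf <- vapply(seq_len(2), function(i) {
    p <- pts[i, ]
    r1 <- sqrt(sum((p - pos[1, ])^2)) / 100
    r2 <- sqrt(sum((p - pos[2, ])^2)) / 100
    1 / (4 * pi * 0.1 * r1) - 1 / (4 * pi * 0.1 * r2)
  }, 0)
  # the numeric ratio between the two radii tracks the closed form
  expect_equal(v[1] - v[2], cf[1] - cf[2], tolerance = 0.05 * abs(cf[1]))
})

test_that("inflating the cylinder moves its threshold toward the slab's", {
  # matched layer stacks; only the marrow core radius grows
  h_target <- 0.3
  stack_with <- function(extra) {
    l <- thigh_layers(1)
    l[[1]] <- tissue_layer("bone_marrow", 0.87 + extra)
    l
  }
  th_of <- function(m) {
    vol <- if (m$representation == "PM")
      m$pm_width_cm * m$radii[["skin"]] * 16
    else pi * m$radii[["skin"]]^2 * 16
    el <- place_electrodes(m, "anterior", 2.25, 3)
    dom <- discretize(m, el, base_dof = vol / h_target^3)
    sol <- solve_unit_field(dom, electrode_model = "uniform")
    f <- build_fiber(12)
    pl <- fiber_placement("anterior", 4, 12)
    prof <- sample_along(sol, fiber_node_points(m, pl, el, f))
    find_threshold(prof, f, stimulus_waveform(0))$threshold_mA
  }
  gaps <- vapply(c(0, 4, 12), function(ex) {
    s <- stack_with(ex)
    t_cm <- th_of(build_model("CM", s, axial_length_cm = 16))
    t_pm <- th_of(build_model("PM", s, axial_length_cm = 16,
                              pm_width_cm = pi * (7.26 + ex)))
    abs(t_cm - t_pm)
  }, 0)
  expect_true(all(diff(gaps) < 0))
})
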