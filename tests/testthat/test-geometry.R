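test_that("tissue conductivities match the tabulated values", {
  expect_equal(conductivity_of("skin")$sigma_transverse, 0.790)
  expect_equal(conductivity_of("blood")$sigma_transverse, 700.0)
  mus <- conductivity_of("muscle")
  expect_equal(mus$sigma_transverse, 82.38)
  expect_equal(mus$sigma_longitudinal, 329.53)
  expect_false(mus$isotropic)
  expect_true(conductivity_of("fat")$isotropic)
  expect_error(conductivity_of("cartilage"), "unknown tissue")
  expect_error(conductivity_tensor(-1), "strictly positive")
})

test_that("layer radii are cumulative sums, strictly increasing", {
  expect_equal(unname(compute_layer_radii(thigh_layers(1))),
               c(0.87, 1.50, 5.82, 7.06, 7.26))
  expect_equal(unname(compute_layer_radii(thigh_layers(2))),
               c(0.94, 1.51, 6.53, 8.26, 8.46))
  expect_equal(unname(compute_layer_radii(list(tissue_layer("muscle", 3)))),
               3)
  for (s in 1:2) {
    r <- compute_layer_radii(thigh_layers(s))
    expect_true(all(diff(r) > 0))
    expect_equal(unname(r[length(r)]),
                 sum(vapply(thigh_layers(s), `[[`, 1, "thickness_cm")))
  }
  bad <- thigh_layers(1)
  bad[[2]]$thickness_cm <- -0.1
  expect_error(compute_layer_radii(bad), "cortical_bone")
})

test_that("model builder enforces representation invariants", {
  expect_s3_class(cm1_model(), "volume_model")
  vessel <- inclusion_spec("blood_vessel", c(30, 0), 5)
  expect_error(build_model("CM", thigh_layers(1),
                           inclusions = list(vessel)),
               "inclusion-free")
  expect_error(build_model("PM", thigh_layers(1),
                           boundary_perturbation = list(
                             fat = list(k = 2, a_mm = 3, phase = 0))),
               "perturbation")
  # inclusion crossing the muscle-fat boundary is rejected
  expect_error(build_model("PSEUDO_AM", thigh_layers(1),
                           inclusions = list(
                             inclusion_spec("blood_vessel", c(55, 0), 8))),
               "inside the muscle")
  # wrong layer order
  expect_error(build_model("CM", rev(thigh_layers(1))), "layer order")
})

test_that("electrode pairs are geodesic squares about a fixed centerline", {
  cm1 <- cm1_model()
  e <- place_electrodes(cm1, "anterior", 25, 4)
  expect_equal(e$side_cm, 5)
  expect_equal(e$centerline_z_cm, 0)
  e9 <- place_electrodes(cm1, "posterior", 9, 4)
  expect_equal(mean(e9$z_ranges$distal) - mean(e9$z_ranges$proximal),
               3 + 4) # side + gap
  # gap variation keeps the pair centerline unchanged
  e2 <- place_electrodes(cm1, "anterior", 9, 2)
  expect_equal(mean(c(unlist(e2$z_ranges))), 0)
  expect_warning(place_electrodes(cm1, "anterior", 26, 4), "1-25")
  expect_warning(place_electrodes(cm1, "anterior", 9, 6.5), "0-6")
  expect_error(suppressWarnings(
    place_electrodes(cm1, "anterior", 160, 0)), "quadrant")
  # swapping roles leaves the geometry unchanged
  sw <- swap_electrode_roles(e9)
  expect_identical(sw$z_ranges, e9$z_ranges)
  expect_identical(unname(sw$roles["proximal"]), "anode")
})

test_that("fiber trajectories have 0.1 mm spacing inside the muscle", {
  cm1 <- cm1_model()
  el <- place_electrodes(cm1, "anterior", 9, 4)
  for (len in c(63, 40, 25.3)) {
    tr <- fiber_trajectory(cm1, fiber_placement("anterior", 5, 12, len), el)
    expect_equal(nrow(tr), round(len / 0.1) + 1)
  }
  # depth 0 sits exactly on the muscle outer boundary
  tr0 <- fiber_trajectory(cm1, fiber_placement("anterior", 0, 12), el)
  expect_equal(unname(sqrt(tr0[1, 1]^2 + tr0[1, 2]^2)), 5.82)
  expect_equal(max(abs(diff(tr0[, 3])) - 0.01), 0, tolerance = 1e-12)
  # midpoint under the proximal electrode centre
  tr <- fiber_trajectory(cm1, fiber_placement("anterior", 5, 12), el)
  expect_equal(unname(tr[316, 3]), mean(el$z_ranges$proximal))
  expect_error(
    fiber_trajectory(cm1, fiber_placement("anterior", 50, 12), el),
    "leaves the muscle")
})
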