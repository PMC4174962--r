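test_that("pseudo-anatomy generation is deterministic and seeded", {
  a1 <- generate_pseudo_anatomy(anatomy_params(seed = 11))
  a2 <- generate_pseudo_anatomy(anatomy_params(seed = 11))
  expect_identical(a1, a2)
  a3 <- generate_pseudo_anatomy(anatomy_params(seed = 12))
  expect_false(identical(a1$boundary_perturbation, a3$boundary_perturbation))
})

test_that("ablated variant differs only by the absent inclusions", {
  full <- generate_pseudo_anatomy(anatomy_params(seed = 5))
  vn <- generate_pseudo_anatomy(anatomy_params(seed = 5,
                                               include_vessel = FALSE,
                                               include_nerve = FALSE))
  expect_length(vn$inclusions, 0)
  expect_length(full$inclusions, 2)
  strip <- function(m) {
    m$inclusions <- NULL
    m$anatomy_params[c("include_vessel", "include_nerve")] <- NULL
    m
  }
  expect_identical(strip(full), strip(vn))
})

test_that("default inclusion sizes follow the bone cross-section ratios", {
  full <- generate_pseudo_anatomy(anatomy_params(seed = 5))
  radii <- compute_layer_radii(thigh_layers(1))
  a_bone_cm2 <- pi * (radii[["cortical_bone"]]^2 - radii[["bone_marrow"]]^2)
  kinds <- vapply(full$inclusions, `[[`, "", "kind")
  r_v <- full$inclusions[[which(kinds == "blood_vessel")]]$radius_mm
  r_n <- full$inclusions[[which(kinds == "nerve_trunk")]]$radius_mm
  expect_equal(pi * (r_v / 10)^2, 0.16 * a_bone_cm2, tolerance = 1e-10)
  expect_equal(pi * (r_n / 10)^2, 0.06 * a_bone_cm2, tolerance = 1e-10)
})

test_that("inclusions sit at the stated distances from the fat-muscle boundary", {
  full <- generate_pseudo_anatomy(anatomy_params(seed = 5))
  kinds <- vapply(full$inclusions, `[[`, "", "kind")
  vessel <- full$inclusions[[which(kinds == "blood_vessel")]]
  r_fm_mm <- boundary_radius(full, "muscle", pi) * 10  # medial ray
  surf_mm <- sqrt(sum(vessel$axis_offset_mm^2)) + vessel$radius_mm
  expect_equal(r_fm_mm - surf_mm, 20.17, tolerance = 1e-8)
  nerve <- full$inclusions[[which(kinds == "nerve_trunk")]]
  r_fm_post <- boundary_radius(full, "muscle", -pi / 2) * 10
  expect_equal(r_fm_post - (sqrt(sum(nerve$axis_offset_mm^2)) +
                              nerve$radius_mm), 30.07, tolerance = 1e-8)
})

test_that("infeasible clearances are rejected with the violated constraint", {
  expect_error(
    generate_pseudo_anatomy(anatomy_params(seed = 5,
                                           vessel_distance_mm = 38)),
    "inside the muscle|clearance")
})

test_that("depth series validates depths and flags inclusion collisions", {
  full <- generate_pseudo_anatomy(anatomy_params(seed = 5))
  el <- place_electrodes(full, "medial", 9, 4)
  ds <- depth_series(full, "medial", c(5, 10, 15), 12, el)
  expect_length(ds, 3)
  expect_false(any(vapply(ds, attr, logical(1), "flagged")))
  # a depth inside the vessel clearance band is flagged, not moved
  near <- depth_series(full, "medial", 20, 12, el)
  expect_true(attr(near[[1]], "flagged"))
  expect_equal(near[[1]]$depth_mm, 20)
  expect_error(depth_series(cm1_model(), "medial", 50, 12,
                            place_electrodes(cm1_model(), "medial", 9, 4)),
               "outside the muscle")
})
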