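test_that("refinement at least doubles the degrees of freedom", {
  cm1 <- cm1_short()
  el <- place_electrodes(cm1, "anterior", 9, 4)
  doms <- lapply(0:2, function(l)
    discretize(cm1, el, resolution_level = l, base_dof = 2e4))
  dofs <- vapply(doms, function(d) as.numeric(d$n_dof), numeric(1))
  expect_true(all(diff(log2(dofs)) >= 1))
})

test_that("all five tissue layers appear at the protocol's base resolution", {
  cm1 <- cm1_model()
  el <- place_electrodes(cm1, "anterior", 9, 4)
  dom <- discretize(cm1, el, resolution_level = 0) # default 2e5 DOF
  present <- stimfield:::tissue_code_levels[
    sort(unique(dom$tissue_code[dom$tissue_code > 0]))]
  expect_setequal(present, c("bone_marrow", "cortical_bone", "muscle",
                             "fat", "skin"))
})

test_that("discretized electrode patch areas match the nominal area", {
  cm1 <- cm1_short()
  for (area in c(1, 9, 25)) {
    el <- place_electrodes(cm1, "anterior", area, 4)
    dom <- discretize(cm1, el, base_dof = 3e4)
    expect_lt(max(abs(dom$patch_area_cm2 - area)) / area, 0.02)
  }
  pm <- pm1_short()
  el <- place_electrodes(pm, "anterior", 9, 4)
  dom <- discretize(pm, el, base_dof = 3e4)
  expect_lt(max(abs(dom$patch_area_cm2 - 9)) / 9, 0.02)
})

test_that("under-resolved inclusions are refused with the required level", {
  am <- fixture("am_seed1",
                generate_pseudo_anatomy(anatomy_params(seed = 1,
                                                       axial_length_cm = 24)))
  el <- place_electrodes(am, "medial", 9, 4)
  expect_error(discretize(am, el, resolution_level = 0, base_dof = 5e3),
               "thinner than 2 cells.*level >= [0-9]+")
})
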