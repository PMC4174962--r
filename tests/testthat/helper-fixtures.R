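# Shared fixtures, cached across test files (test_dir runs in one session).
fixture_env <- new.env()

fixture <- function(name, expr) {
  if (!exists(name, envir = fixture_env, inherits = FALSE))
    assign(name, expr, envir = fixture_env)
  get(name, envir = fixture_env, inherits = FALSE)
}

cm1_model <- function() fixture("cm1", build_model("CM", thigh_layers(1)))

cm1_short <- function()
  fixture("cm1_short", build_model("CM", thigh_layers(1),
                                   axial_length_cm = 24))

pm1_short <- function()
  fixture("pm1_short", build_model("PM", thigh_layers(1),
                                   axial_length_cm = 24))

# small solved CM1 geometry reused by the field-solver tests
cm1_small_solution <- function() {
  fixture("cm1_small_solution", {
    el <- place_electrodes(cm1_short(), "anterior", 9, 4)
    dom <- discretize(cm1_short(), el, resolution_level = 0, base_dof = 3e4)
    list(electrodes = el, domain = dom, solution = solve_unit_field(dom))
  })
}

pm1_small_solution <- function() {
  fixture("pm1_small_solution", {
    el <- place_electrodes(pm1_short(), "anterior", 9, 4)
    dom <- discretize(pm1_short(), el, base_dof = 4e4)
    list(electrodes = el, domain = dom, solution = solve_unit_field(dom))
  })
}

# closed-form extracellular profile of a cathodic point source at distance
# d over the fiber in a homogeneous medium: the membrane-model tests use it
# so they do not depend on the field solver
point_source_profile <- function(fiber, d_m = 0.017, sigma_Sm = 0.2) {
  z <- fiber$node_z_mm / 1000
  -1 / (4 * pi * sigma_Sm * sqrt(d_m^2 + z^2))
}

# synthetic trace with prescribed crossing pattern, for detector tests
synthetic_trace <- function(v_end_pulse, crossing_ms) {
  structure(
    list(times_ms = seq(0.002, 2, by = 0.002),
         V_mV = NULL,
         node_z_mm = seq_along(v_end_pulse),
         crossing_ms = crossing_ms,
         v_end_pulse_mV = v_end_pulse,
         waveform = stimulus_waveform(10), dt_ms = 0.002),
    class = "simulation_trace")
}
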