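# McNeal compartment cable with CRRSS nodal kinetics.
#
# Only the Ranvier nodes carry nonlinear membrane (sodium + leak, CRRSS
# rate functions at 37 C); the myelinated internodes are perfect insulators
# by default, with an optional passive-internode-compartment variant.
# Voltages are transmembrane deviations from rest (mV), time in ms,
# conductances in mS, capacitances in uF, currents in uA.

#' CRRSS nodal membrane constants (37 C)
#'
#' Sodium-plus-leak nodal membrane of a mammalian myelinated fiber:
#' maximal sodium conductance 1445 mS/cm^2, leak conductance 128 mS/cm^2,
#' sodium reversal +115.5 mV above rest, nodal capacitance 2.5 uF/cm^2,
#' axoplasmic resistivity 54.7 Ohm cm, resting potential -80 mV.  The leak
#' reversal is calibrated so that V = 0 (rest) is an exact equilibrium of
#' the full nodal current given the steady-state gates.
#'
#' @return Named list of constants.
#' @export
crrss_constants <- function() {
  g_na <- 1445    # mS/cm^2
  g_l <- 128      # mS/cm^2
  e_na <- 115.5   # mV above rest
  r <- crrss_rates(0)
  m0 <- r$alpha_m / (r$alpha_m + r$beta_m)
  h0 <- r$alpha_h / (r$alpha_h + r$beta_h)
  e_l <- -(g_na / g_l) * m0^2 * h0 * e_na  # exact resting equilibrium
  list(g_na_mScm2 = g_na, g_l_mScm2 = g_l, e_na_mV = e_na, e_l_mV = e_l,
       c_n_uFcm2 = 2.5, rho_i_ohmcm = 54.7, v_rest_mV = -80,
       m0 = m0, h0 = h0)
}

#' CRRSS gating rate functions
#'
#' Sodium activation (m) and inactivation (h) rates at 37 C as functions of
#' the transmembrane deviation from rest, mV.  `m_inf` is monotonically
#' increasing and `h_inf` monotonically decreasing in V.
#'
#' @param V numeric vector, mV above rest.
#' @return List with `alpha_m`, `beta_m`, `alpha_h`, `beta_h` (1/ms).
#' @export
crrss_rates <- function(V) {
  stopifnot(all(is.finite(V)))
  # numerator clamp keeps the rates positive for (unphysically) deep
  # hyperpolarizations below -267 mV
  alpha_m <- pmax(97 + 0.363 * V, 1e-9) / (1 + exp((31 - V) / 5.3))
  beta_m <- alpha_m / exp((V - 23.8) / 4.17)
  beta_h <- 15.6 / (1 + exp((24 - V) / 10))
  alpha_h <- beta_h / exp((V - 5.5) / 5)
  list(alpha_m = alpha_m, beta_m = beta_m,
       alpha_h = alpha_h, beta_h = beta_h)
}

#' Steady-state gates
#' @param V mV above rest.
#' @return List with `m_inf`, `h_inf`.
#' @export
crrss_steady_state <- function(V) {
  r <- crrss_rates(V)
  list(m_inf = r$alpha_m / (r$alpha_m + r$beta_m),
       h_inf = r$alpha_h / (r$alpha_h + r$beta_h))
}

#' Build a myelinated fiber model
#'
#' Standard myelinated-fiber geometry conventions: internode length =
#' 100 x outer diameter, axon diameter = 0.7 x outer diameter, node length
#' 1.5 um (all configurable).  The node count is the largest odd integer
#' whose span fits in the stated length, so a node sits exactly at the
#' fiber midpoint.
#'
#' @param diameter_um fiber outer diameter, um.
#' @param length_mm fiber length, default 63 mm.
#' @param internode_ratio internode length / outer diameter.
#' @param axon_ratio axon diameter / outer diameter.
#' @param node_length_um Ranvier node length.
#' @param myelin `"insulating"` (perfect-insulator internodes; nodes only)
#'   or `"passive"` (10 passive internodal compartments per internode with
#'   constant membrane conductance).
#' @param internode_g_mScm2,internode_c_uFcm2 passive internode membrane
#'   parameters (passive variant only).
#' @return A `fiber_model` object.
#' @examples
#' build_fiber(12)$node_count  # 53
#' @export
build_fiber <- function(diameter_um, length_mm = 63,
                        internode_ratio = 100, axon_ratio = 0.7,
                        node_length_um = 1.5,
                        myelin = c("insulating", "passive"),
                        internode_g_mScm2 = 1, internode_c_uFcm2 = 0.1) {
  myelin <- match.arg(myelin)
  stopifnot(diameter_um > 0, length_mm > 0)
  internode_mm <- internode_ratio * diameter_um / 1000
  n <- floor(length_mm / internode_mm) + 1
  if (n %% 2 == 0) n <- n - 1
  if (n < 11)
    stop(sprintf(
      "fiber of diameter %g um and length %g mm has only %d nodes (< 11)",
      diameter_um, length_mm, n), call. = FALSE)
  axon_um <- axon_ratio * diameter_um
  k <- crrss_constants()
  node_area_cm2 <- pi * (axon_um * 1e-4) * (node_length_um * 1e-4)
  ga_mS <- 1000 * pi * (axon_um * 1e-4)^2 /
    (4 * k$rho_i_ohmcm * internode_mm / 10)
  node_z_mm <- (seq_len(n) - (n + 1) / 2) * internode_mm
  structure(
    list(diameter_um = diameter_um, length_mm = length_mm,
         node_count = as.integer(n), internode_mm = internode_mm,
         node_length_um = node_length_um, axon_um = axon_um,
         node_z_mm = node_z_mm,
         node_area_cm2 = node_area_cm2,
         ga_mS = ga_mS,
         c_node_uF = k$c_n_uFcm2 * node_area_cm2,
         g_na_mS = k$g_na_mScm2 * node_area_cm2,
         g_l_mS = k$g_l_mScm2 * node_area_cm2,
         constants = k,
         myelin = myelin,
         internode_g_mScm2 = internode_g_mScm2,
         internode_c_uFcm2 = internode_c_uFcm2,
         n_internode_segments = 10L),
    class = "fiber_model")
}

#' @export
print.fiber_model <- function(x, ...) {
  cat(sprintf(
    "<fiber_model> D = %g um, %d nodes, internode %.2f mm, %s myelin\n",
    x$diameter_um, x$node_count, x$internode_mm, x$myelin))
  invisible(x)
}

#' Square stimulus waveform
#'
#' @param amplitude_mA non-negative amplitude; cathodic polarity is carried
#'   by the lead field (cathode-negative for positive amplitude).
#' @param pulse_width_ms square pulse duration, default 0.5 ms.
#' @param total_duration_ms simulated time, default 2 ms.
#' @export
stimulus_waveform <- function(amplitude_mA, pulse_width_ms = 0.5,
                              total_duration_ms = 2) {
  stopifnot(amplitude_mA >= 0, pulse_width_ms > 0,
            total_duration_ms >= pulse_width_ms)
  structure(list(shape = "square", polarity = "cathodic",
                 amplitude_mA = amplitude_mA,
                 pulse_width_ms = pulse_width_ms,
                 total_duration_ms = total_duration_ms),
            class = "stimulus_waveform")
}

# compartmentalized geometry for the passive-internode variant
fiber_compartments <- function(fiber) {
  if (fiber$myelin == "insulating") {
    n <- fiber$node_count
    return(list(z_mm = fiber$node_z_mm, is_node = rep(TRUE, n),
                ga_mS = rep(fiber$ga_mS, n - 1)))
  }
  ns <- fiber$n_internode_segments
  n <- fiber$node_count
  seg_mm <- fiber$internode_mm / (ns + 1)
  z <- sort(unique(c(fiber$node_z_mm,
                     unlist(lapply(seq_len(n - 1), function(i)
                       fiber$node_z_mm[i] + seg_mm * seq_len(ns))))))
  is_node <- z %in% fiber$node_z_mm
  k <- crrss_constants()
  dz <- diff(z)
  ga <- 1000 * pi * (fiber$axon_um * 1e-4)^2 / (4 * k$rho_i_ohmcm * dz / 10)
  list(z_mm = z, is_node = is_node, ga_mS = ga)
}

#' Simulate the transmembrane response to an extracellular profile
#'
#' Integrates the nodal cable equation with a semi-implicit scheme (exact
#' exponential gate update at the old voltage, then an implicit tridiagonal
#' voltage solve with the ionic conductances frozen at the new gates).  The
#' extracellular drive enters through the second spatial difference of the
#' potential profile at the compartments.
#'
#' @param fiber a [build_fiber()] model.
#' @param extracellular_profile extracellular potential at each node for a
#'   unit (1 A) stimulus, volts; cathodic polarity means the profile is
#'   negative under the proximal electrode.
#' @param waveform a [stimulus_waveform()].
#' @param dt_ms time step, default 2 us.
#' @return A `simulation_trace` with times, nodal voltages (mV above rest),
#'   per-node first 80 mV crossing times and activation summary.
#' @export
simulate_response <- function(fiber, extracellular_profile, waveform,
                              dt_ms = 0.002) {
  stopifnot(inherits(fiber, "fiber_model"),
            inherits(waveform, "stimulus_waveform"))
  if (length(extracellular_profile) != fiber$node_count)
    stop(sprintf("profile length %d != node count %d",
                 length(extracellular_profile), fiber$node_count),
         call. = FALSE)
  comp <- fiber_compartments(fiber)
  nc <- length(comp$z_mm)
  is_node <- comp$is_node
  # per-compartment extracellular potential (mV per mA = V per A)
  ve_unit <- if (all(is_node)) extracellular_profile else
    stats::approx(fiber$node_z_mm, extracellular_profile,
                  xout = comp$z_mm, rule = 2)$y

  k <- fiber$constants
  c_uF <- ifelse(is_node, fiber$c_node_uF, NA_real_)
  g_pas <- ifelse(is_node, fiber$g_l_mS, NA_real_)
  if (any(!is_node)) {
    seg_mm <- fiber$internode_mm / (fiber$n_internode_segments + 1)
    a_seg <- pi * (fiber$diameter_um * 1e-4) * (seg_mm / 10)
    c_uF[!is_node] <- fiber$internode_c_uFcm2 * a_seg
    g_pas[!is_node] <- fiber$internode_g_mScm2 * a_seg
  }
  ga <- comp$ga_mS
  nt <- ceiling(waveform$total_duration_ms / dt_ms)
  times <- seq_len(nt) * dt_ms

  V <- numeric(nc)
  m <- rep(k$m0, nc); h <- rep(k$h0, nc)
  v_hist <- matrix(NA_real_, nt, sum(is_node))
  node_idx <- which(is_node)
  crossing <- rep(NA_real_, sum(is_node))
  v_end_pulse <- NULL

  # tridiagonal axial structure (constant in time)
  lower <- -ga
  diag_ax <- c(ga, 0) + c(0, ga)
  amp_A <- waveform$amplitude_mA / 1000

  for (it in seq_len(nt)) {
    t_new <- times[it]
    # exact exponential gate update at the current voltage (nodes only)
    r <- crrss_rates(V[node_idx])
    tau_m <- 1 / (r$alpha_m + r$beta_m)
    m_inf <- r$alpha_m * tau_m
    tau_h <- 1 / (r$alpha_h + r$beta_h)
    h_inf <- r$alpha_h * tau_h
    m[node_idx] <- m_inf + (m[node_idx] - m_inf) * exp(-dt_ms / tau_m)
    h[node_idx] <- h_inf + (h[node_idx] - h_inf) * exp(-dt_ms / tau_h)

    on <- t_new <= waveform$pulse_width_ms
    ve <- if (on) 1000 * amp_A * ve_unit else numeric(nc)  # mV
    # second-difference drive (sealed ends use the one-sided difference)
    dve <- numeric(nc)
    if (nc > 1) {
      dve[1] <- ga[1] * (ve[2] - ve[1])
      dve[nc] <- ga[nc - 1] * (ve[nc - 1] - ve[nc])
      if (nc > 2)
        dve[2:(nc - 1)] <- ga[-1] * (ve[3:nc] - ve[2:(nc - 1)]) +
          ga[-(nc - 1)] * (ve[1:(nc - 2)] - ve[2:(nc - 1)])
    }
    g_ion <- numeric(nc)
    rhs_ion <- numeric(nc)
    g_na_eff <- fiber$g_na_mS * m[node_idx]^2 * h[node_idx]
    g_ion[node_idx] <- g_na_eff + fiber$g_l_mS
    rhs_ion[node_idx] <- g_na_eff * k$e_na_mV + fiber$g_l_mS * k$e_l_mV
    if (any(!is_node)) {
      g_ion[!is_node] <- g_pas[!is_node]
      # passive internode reversal at rest (0 deviation)
    }
    dg <- c_uF / dt_ms + g_ion + diag_ax
    rhs <- (c_uF / dt_ms) * V + dve + rhs_ion
    V <- thomas_solve(lower, dg, lower, rhs)
    if (any(!is.finite(V)))
      stop(sprintf("integration failure (non-finite state) at t = %.3f ms",
                   t_new), call. = FALSE)
    v_hist[it, ] <- V[node_idx]
    newly <- is.na(crossing) & V[node_idx] > 80
    crossing[newly] <- t_new
    if (is.null(v_end_pulse) && t_new >= waveform$pulse_width_ms)
      v_end_pulse <- V[node_idx]
  }
  if (is.null(v_end_pulse)) v_end_pulse <- V[node_idx]

  trace <- structure(
    list(times_ms = times, V_mV = v_hist,
         node_z_mm = fiber$node_z_mm,
         crossing_ms = crossing,
         v_end_pulse_mV = v_end_pulse,
         waveform = waveform, dt_ms = dt_ms,
         fiber = fiber),
    class = "simulation_trace")
  det <- detect_activation(trace)
  trace$activated <- det$activated
  trace$activation_node <- det$activation_node
  trace$conduction_latency_ms <- det$conduction_latency_ms
  trace
}

#' Detect a propagating action potential in a trace
#'
#' A fiber counts as activated when the transmembrane potential exceeds
#' +80 mV above rest at a node at least `guard_internodes` internodes away
#' from the most-depolarized node at the end of the pulse.  The guard
#' rejects purely local depolarization under the cathode that does not
#' propagate.
#'
#' @param trace a `simulation_trace`.
#' @param threshold_mV detection threshold, mV above rest.
#' @param guard_internodes minimum node distance from the end-of-pulse
#'   depolarization peak.
#' @return List with `activated`, `activation_node` (1-based index or NA),
#'   `activation_time_ms`, `conduction_latency_ms`.
#' @export
detect_activation <- function(trace, threshold_mV = 80,
                              guard_internodes = 5) {
  peak_node <- which.max(trace$v_end_pulse_mV)
  n <- length(trace$v_end_pulse_mV)
  eligible <- abs(seq_len(n) - peak_node) >= guard_internodes
  crossed <- !is.na(trace$crossing_ms) & eligible
  if (!any(crossed))
    return(list(activated = FALSE, activation_node = NA_integer_,
                activation_time_ms = NA_real_,
                conduction_latency_ms = NA_real_))
  first <- which.min(ifelse(crossed, trace$crossing_ms, Inf))
  all_cross <- trace$crossing_ms[!is.na(trace$crossing_ms)]
  list(activated = TRUE, activation_node = as.integer(first),
       activation_time_ms = trace$crossing_ms[first],
       conduction_latency_ms = max(all_cross) - min(all_cross))
}

#' @export
print.simulation_trace <- function(x, ...) {
  cat(sprintf(
    "<simulation_trace> %d nodes, %.2f ms at dt = %g us; %s\n",
    ncol(x$V_mV), max(x$times_ms), x$dt_ms * 1000,
    if (isTRUE(x$activated)) sprintf("activated (node %d)",
                                     x$activation_node) else "not activated"))
  invisible(x)
}

#' Export a simulation trace to CSV
#'
#' Long format: `time_ms`, `node_index`, `V_mV`.
#' @param trace a `simulation_trace`.
#' @param path output file.
#' @export
write_trace_csv <- function(trace, path) {
  n <- ncol(trace$V_mV)
  df <- data.frame(
    time_ms = rep(trace$times_ms, times = n),
    node_index = rep(seq_len(n), each = length(trace$times_ms)),
    V_mV = as.vector(trace$V_mV))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
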