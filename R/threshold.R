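#' Bisection on a monotone activation predicate
#'
#' Generic amplitude bisection used by the threshold search: assumes the
#' predicate is monotone (inactive below threshold, active above) and
#' narrows the bracket to the requested tolerance.
#'
#' @param predicate function(amplitude) -> logical.
#' @param bracket initial (low, high) amplitudes, mA.
#' @param tol_mA final bracket width, default 0.01 mA (10 uA).
#' @param low_extension value the bracket is extended down to (once) when
#'   the predicate is already true at the lower end.
#' @return List with `threshold_mA` (bracket midpoint; NA when flagged),
#'   `bracket`, `n_evals`, `n_bisections` and `out_of_range`
#'   (`"none"`, `"low"`, `"high"`).
#' @export
bisect_threshold <- function(predicate, bracket = c(5, 500), tol_mA = 0.01,
                             low_extension = 0.1) {
  lo <- bracket[1]; hi <- bracket[2]
  stopifnot(lo > 0, hi > lo, tol_mA > 0)
  n_evals <- 0L
  eval_p <- function(a) { n_evals <<- n_evals + 1L; isTRUE(predicate(a)) }
  out_of_range <- "none"
  if (!eval_p(hi))
    return(list(threshold_mA = NA_real_, bracket = c(hi, Inf),
                n_evals = n_evals, n_bisections = 0L,
                out_of_range = "high"))
  if (eval_p(lo)) {
    out_of_range <- "low"
    hi <- lo
    lo <- low_extension
    if (eval_p(lo))
      return(list(threshold_mA = NA_real_, bracket = c(0, lo),
                  n_evals = n_evals, n_bisections = 0L,
                  out_of_range = "low"))
  }
  n_bis <- 0L
  while (hi - lo > tol_mA) {
    mid <- (lo + hi) / 2
    if (eval_p(mid)) hi <- mid else lo <- mid
    n_bis <- n_bis + 1L
  }
  list(threshold_mA = (lo + hi) / 2, bracket = c(lo, hi),
       n_evals = n_evals, n_bisections = n_bis,
       out_of_range = out_of_range)
}

#' Find the activation threshold for a unit lead-field profile
#'
#' Because the field equation is linear, the extracellular profile for any
#' stimulus amplitude is the unit lead field scaled by the amplitude; the
#' search therefore re-runs only the fiber simulation, never the field
#' solve.
#'
#' @param unit_profile extracellular potential per node for 1 A, volts.
#' @param fiber a [build_fiber()] model.
#' @param waveform_template a [stimulus_waveform()] whose amplitude is
#'   overridden during the search.
#' @param bracket initial amplitude bracket, mA.
#' @param tol_mA bracket tolerance, default 0.01 mA (10 uA).
#' @param dt_ms fiber integration step.
#' @param context optional list recorded with the result.
#' @return A `threshold_result`.
#' @export
find_threshold <- function(unit_profile, fiber,
                           waveform_template = stimulus_waveform(0),
                           bracket = c(5, 500), tol_mA = 0.01,
                           dt_ms = 0.002, context = NULL) {
  n_sims <- 0L
  predicate <- function(amp) {
    n_sims <<- n_sims + 1L
    wf <- waveform_template
    wf$amplitude_mA <- amp
    simulate_response(fiber, unit_profile, wf, dt_ms = dt_ms)$activated
  }
  b <- bisect_threshold(predicate, bracket = bracket, tol_mA = tol_mA)
  structure(
    list(threshold_mA = b$threshold_mA, bracket_mA = b$bracket,
         out_of_range = b$out_of_range,
         n_fiber_sims = n_sims, n_field_solves = 0L,
         n_bisections = b$n_bisections,
         context = context),
    class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  if (is.na(x$threshold_mA))
    cat(sprintf("<threshold_result> out of range (%s)\n", x$out_of_range))
  else
    cat(sprintf(
      "<threshold_result> %.3f mA (bracket %.3f-%.3f), %d fiber sims\n",
      x$threshold_mA, x$bracket_mA[1], x$bracket_mA[2], x$n_fiber_sims))
  invisible(x)
}

#' Check monotonicity of activation in stimulus amplitude
#'
#' Guards the bisection's monotonicity assumption: evaluates activation at
#' each amplitude and warns if a non-monotone pattern (active below an
#' inactive amplitude) appears.
#'
#' @param unit_profile,fiber,waveform_template,dt_ms as [find_threshold()].
#' @param amplitudes_mA ascending amplitudes.
#' @return Logical activation flags, with attribute `monotone`.
#' @export
activation_monotonicity_check <- function(unit_profile, fiber,
                                          amplitudes_mA,
                                          waveform_template =
                                            stimulus_waveform(0),
                                          dt_ms = 0.002) {
  stopifnot(!is.unsorted(amplitudes_mA))
  flags <- vapply(amplitudes_mA, function(a) {
    wf <- waveform_template; wf$amplitude_mA <- a
    simulate_response(fiber, unit_profile, wf, dt_ms = dt_ms)$activated
  }, logical(1))
  monotone <- monotone_activation_pattern(flags)
  if (!monotone)
    warning("activation is non-monotone in amplitude; bisection is invalid for this configuration",
            call. = FALSE)
  structure(flags, monotone = monotone)
}

# a valid monotone pattern is any run of FALSE followed by a run of TRUE
monotone_activation_pattern <- function(flags) {
  !is.unsorted(as.integer(flags))
}

#' Sample positions of the fiber's Ranvier nodes
#'
#' @param model,placement,electrodes as [fiber_trajectory()].
#' @param fiber a [build_fiber()] model consistent with `placement`.
#' @return node_count x 3 matrix of (x, y, z), cm.
#' @export
fiber_node_points <- function(model, placement, electrodes, fiber) {
  traj <- fiber_trajectory(model, placement, electrodes)
  zc <- attr(traj, "center_z_cm")
  cbind(x = rep(traj[1, 1], fiber$node_count),
        y = rep(traj[1, 2], fiber$node_count),
        z = zc + fiber$node_z_mm / 10)
}
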