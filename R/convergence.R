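#' Mesh-convergence protocol for the activation threshold
#'
#' Refines the discretization, roughly doubling the degree-of-freedom
#' count per level starting from `base_dof`, re-solving the lead field and
#' re-computing the activation threshold at each level, until successive
#' thresholds differ by less than `rel_tol` with at least `min_evals`
#' evaluations performed.
#'
#' @param model a `volume_model`.
#' @param electrodes a [place_electrodes()] pair.
#' @param placement a [fiber_placement()].
#' @param waveform a [stimulus_waveform()] template.
#' @param start_level first refinement level.
#' @param base_dof level-0 degree-of-freedom target (default 2e5).
#' @param rel_tol relative threshold change for termination (default 0.1%).
#' @param min_evals minimum number of refinement evaluations.
#' @param max_evals refinement cap; if the sequence has not converged by
#'   then the full sequence is reported in the error.
#' @param dt_ms fiber integration step.
#' @param electrode_model passed to [solve_unit_field()].
#' @return List with the converged `solution`, `achieved_level`,
#'   `thresholds_mA`, `dofs`, `rel_changes` and `converged`.
#' @export
converge_threshold <- function(model, electrodes, placement,
                               waveform = stimulus_waveform(0),
                               start_level = 0, base_dof = 2e5,
                               rel_tol = 0.001, min_evals = 4,
                               max_evals = 8, dt_ms = 0.002,
                               electrode_model = "equipotential") {
  fiber <- build_fiber(placement$diameter_um, placement$length_mm)
  thresholds <- numeric(0)
  dofs <- integer(0)
  rel_changes <- numeric(0)
  solution <- NULL
  prev_dof <- 0L
  for (k in seq_len(max_evals)) {
    level <- start_level + k - 1
    domain <- discretize(model, electrodes, resolution_level = level,
                         base_dof = base_dof)
    if (prev_dof > 0 && domain$n_dof < 2L * prev_dof)
      stop(sprintf(
        "refinement level %d did not double the degrees of freedom (%d -> %d)",
        level, prev_dof, domain$n_dof), call. = FALSE)
    prev_dof <- domain$n_dof
    solution <- solve_unit_field(domain, electrode_model = electrode_model)
    pts <- fiber_node_points(model, placement, electrodes, fiber)
    profile <- sample_along(solution, pts)
    th <- find_threshold(profile, fiber, waveform, dt_ms = dt_ms,
                         context = list(level = level))
    if (is.na(th$threshold_mA))
      stop(sprintf("threshold out of range (%s) at level %d",
                   th$out_of_range, level), call. = FALSE)
    thresholds <- c(thresholds, th$threshold_mA)
    dofs <- c(dofs, domain$n_dof)
    if (k > 1)
      rel_changes <- c(rel_changes,
                       abs(diff(utils::tail(thresholds, 2))) /
                         utils::tail(thresholds, 1))
    if (k >= min_evals && utils::tail(rel_changes, 1) < rel_tol)
      return(list(solution = solution, achieved_level = level,
                  thresholds_mA = thresholds, dofs = dofs,
                  rel_changes = rel_changes, converged = TRUE))
  }
  stop(sprintf(
    "threshold sequence did not converge below %.2g%% after %d levels: %s (relative changes %s)",
    100 * rel_tol, max_evals,
    paste(sprintf("%.4f", thresholds), collapse = ", "),
    paste(sprintf("%.3g", rel_changes), collapse = ", ")),
    call. = FALSE)
}
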