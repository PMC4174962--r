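#' Define a comparison sweep
#'
#' @param models named list of `volume_model` objects.
#' @param reference name of the reference model in `models` (exactly one);
#'   `NULL` for sweeps without an error comparison.
#' @param sites character vector of stimulation sites.
#' @param areas_cm2,gaps_cm,diameters_um,depths_mm sweep grids (non-empty).
#' @param waveform a [stimulus_waveform()] template.
#' @param base_dof field-solve degree-of-freedom target.
#' @param resolution_level refinement level for all solves.
#' @param dt_ms fiber integration step.
#' @param electrode_model electrode formulation for the sweep solves.
#'   Defaults to the uniform-current-density variant: its prescribed
#'   per-cell load is insensitive to the mesh-scale slivers of the
#'   floating-patch contact at coarse resolutions and admits the exact
#'   separable solve.
#' @export
sweep_spec <- function(models, reference = NULL,
                       sites = "anterior",
                       areas_cm2 = 9, gaps_cm = 4,
                       diameters_um = 12, depths_mm = 5,
                       waveform = stimulus_waveform(0),
                       base_dof = 8e4, resolution_level = 0,
                       dt_ms = 0.002,
                       electrode_model = c("uniform", "equipotential")) {
  electrode_model <- match.arg(electrode_model)
  if (!length(models) || is.null(names(models)) ||
      any(!nzchar(names(models))))
    stop("models must be a non-empty named list", call. = FALSE)
  for (nm in c("sites", "areas_cm2", "gaps_cm", "diameters_um",
               "depths_mm")) {
    if (!length(get(nm)))
      stop(sprintf("sweep grid '%s' is empty", nm), call. = FALSE)
  }
  if (!is.null(reference) && !reference %in% names(models))
    stop(sprintf("reference '%s' is not among the models", reference),
         call. = FALSE)
  structure(
    list(models = models, reference = reference, sites = sites,
         areas_cm2 = areas_cm2, gaps_cm = gaps_cm,
         diameters_um = diameters_um, depths_mm = depths_mm,
         waveform = waveform, base_dof = base_dof,
         resolution_level = resolution_level, dt_ms = dt_ms,
         electrode_model = electrode_model),
    class = "sweep_spec")
}

#' Run a threshold sweep
#'
#' One field solve per (model, site, area, gap) geometry; fiber diameters
#' and depths reuse the geometry's lead field by linearity.  Individual
#' configuration failures are recorded (`status = "failed"` with the
#' reason) and never abort the sweep.
#'
#' @param spec a [sweep_spec()].
#' @return A tibble keyed by (model, site, area_cm2, gap_cm, diameter_um,
#'   depth_mm) with `threshold_mA`, bracket, search counters and status.
#' @export
run_sweep <- function(spec) {
  stopifnot(inherits(spec, "sweep_spec"))
  rows <- list()
  for (model_name in names(spec$models)) {
    model <- spec$models[[model_name]]
    for (site in spec$sites) for (area in spec$areas_cm2)
      for (gap in spec$gaps_cm) {
        geom <- tryCatch({
          electrodes <- place_electrodes(model, site, area, gap)
          domain <- discretize(model, electrodes,
                               resolution_level = spec$resolution_level,
                               base_dof = spec$base_dof)
          list(electrodes = electrodes,
               solution = solve_unit_field(
                 domain, electrode_model = spec$electrode_model))
        }, error = function(e) e)
        for (diam in spec$diameters_um) for (depth in spec$depths_mm) {
          row <- tibble::tibble(
            model = model_name, site = site, area_cm2 = area,
            gap_cm = gap, diameter_um = diam, depth_mm = depth,
            threshold_mA = NA_real_, bracket_lo_mA = NA_real_,
            bracket_hi_mA = NA_real_, out_of_range = NA_character_,
            n_field_solves = NA_integer_, n_fiber_sims = NA_integer_,
            status = "ok", reason = NA_character_)
          if (inherits(geom, "error")) {
            row$status <- "failed"
            row$reason <- conditionMessage(geom)
          } else {
            res <- tryCatch({
              fiber <- build_fiber(diam)
              placement <- fiber_placement(site, depth, diam)
              pts <- fiber_node_points(model, placement, geom$electrodes,
                                       fiber)
              profile <- sample_along(geom$solution, pts)
              find_threshold(profile, fiber, spec$waveform,
                             dt_ms = spec$dt_ms)
            }, error = function(e) e)
            if (inherits(res, "error")) {
              row$status <- "failed"
              row$reason <- conditionMessage(res)
            } else {
              row$threshold_mA <- res$threshold_mA
              row$bracket_lo_mA <- res$bracket_mA[1]
              row$bracket_hi_mA <- res$bracket_mA[2]
              row$out_of_range <- res$out_of_range
              row$n_field_solves <- 1L  # single lead-field solve per geometry
              row$n_fiber_sims <- res$n_fiber_sims
              if (res$out_of_range != "none" && is.na(res$threshold_mA)) {
                row$status <- "failed"
                row$reason <- paste0("threshold out of range (",
                                     res$out_of_range, ")")
              }
            }
          }
          rows[[length(rows) + 1L]] <- row
        }
      }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "reference") <- spec$reference
  out
}

#' Unsigned relative activation error
#'
#' `100 * |I_test - I_ref| / I_ref`, percent.
#'
#' @param threshold_test_mA,threshold_ref_mA thresholds, mA (vectorized).
#' @param signed if TRUE, keep the sign (positive when the test model
#'   overestimates the reference threshold).
#' @export
activation_error <- function(threshold_test_mA, threshold_ref_mA,
                             signed = FALSE) {
  if (any(!is.na(threshold_ref_mA) & threshold_ref_mA <= 0))
    stop("reference threshold must be positive", call. = FALSE)
  e <- 100 * (threshold_test_mA - threshold_ref_mA) / threshold_ref_mA
  if (signed) e else abs(e)
}

#' Activation-error table against the reference model
#'
#' Joins every non-reference row of a threshold table to the reference
#' model's threshold at the same (site, area, gap, diameter, depth) key.
#' Regeneration is deterministic and idempotent.
#'
#' @param threshold_table a [run_sweep()] result.
#' @param reference reference model name; defaults to the sweep's.
#' @return Tibble with `error_pct` (unsigned) and `error_signed_pct`.
#' @export
error_table <- function(threshold_table,
                        reference = attr(threshold_table, "reference")) {
  if (is.null(reference))
    stop("no reference model named", call. = FALSE)
  keys <- c("site", "area_cm2", "gap_cm", "diameter_um", "depth_mm")
  ref <- threshold_table[threshold_table$model == reference,
                         c(keys, "threshold_mA")]
  names(ref)[names(ref) == "threshold_mA"] <- "threshold_ref_mA"
  test <- threshold_table[threshold_table$model != reference, ]
  out <- dplyr::left_join(test, ref, by = keys)
  out$error_pct <- activation_error(out$threshold_mA, out$threshold_ref_mA)
  out$error_signed_pct <- activation_error(out$threshold_mA,
                                           out$threshold_ref_mA,
                                           signed = TRUE)
  out
}

#' Zero-lag cross-correlation of two threshold curves
#'
#' Pearson correlation of two curves sampled on the identical parameter
#' grid (the curves share an abscissa, so lagged correlation is not
#' meaningful).  A constant curve has no defined correlation and returns
#' NA with a warning.
#'
#' @param curve_a,curve_b equal-length numeric vectors, length >= 3.
#' @export
cross_correlate <- function(curve_a, curve_b) {
  if (length(curve_a) != length(curve_b))
    stop("curves must share the same parameter grid", call. = FALSE)
  if (length(curve_a) < 3)
    stop("need at least 3 points", call. = FALSE)
  if (stats::sd(curve_a) == 0 || stats::sd(curve_b) == 0) {
    warning("constant curve: correlation undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(curve_a, curve_b)
}

site_window_theta <- function(site, window_deg = 45, n = 1440) {
  ths <- site_angle(site)
  w <- window_deg * pi / 180
  # midpoint rule: exact for harmonics completing full periods in the window
  ths + (-w + (2 * seq_len(n) - 1) * w / n)
}

check_z_range <- function(model, z_range_cm) {
  if (is.null(z_range_cm)) return(invisible(NULL))
  if (length(z_range_cm) != 2 || z_range_cm[1] > z_range_cm[2])
    stop("z_range must be (lo, hi)", call. = FALSE)
  if (z_range_cm[1] < -model$axial_length_cm / 2 ||
      z_range_cm[2] > model$axial_length_cm / 2)
    stop("z_range lies outside the model", call. = FALSE)
  invisible(NULL)
}

#' Average fat thickness at a site
#'
#' Radial thickness of the fat layer (fat outer minus muscle outer
#' boundary) averaged over the site's +/-45 deg angular window and over
#' `z_range`.  The boundaries are extruded along z, so the z average is
#' exact; `z_range` is validated against the model.
#'
#' @param model a `volume_model`.
#' @param site stimulation site.
#' @param z_range_cm optional (lo, hi) axial range; by convention the range
#'   covered by the electrode footprints.
#' @param window_deg half-width of the angular window.
#' @return Average thickness, mm.
#' @export
average_fat_thickness <- function(model, site, z_range_cm = NULL,
                                  window_deg = 45) {
  check_z_range(model, z_range_cm)
  if (model$representation == "PM")
    return(model$layers[[4]]$thickness_cm * 10)
  th <- site_window_theta(site, window_deg)
  mean(boundary_radius(model, "fat", th) -
         boundary_radius(model, "muscle", th)) * 10
}

#' Average bone-to-muscle distance at a site
#'
#' Radial distance from the cortical-bone outer boundary to the fat-muscle
#' boundary along the site's rays, averaged over the +/-45 deg window and
#' `z_range`.
#'
#' @inheritParams average_fat_thickness
#' @return Average distance, mm.
#' @export
average_bone_to_muscle_distance <- function(model, site, z_range_cm = NULL,
                                            window_deg = 45) {
  check_z_range(model, z_range_cm)
  if (model$representation == "PM")
    return(model$layers[[3]]$thickness_cm * 10)
  th <- site_window_theta(site, window_deg)
  rb <- bone_exit_radius_cm(model, th)
  if (any(is.na(rb)))
    stop("some site rays miss the bone; distance undefined", call. = FALSE)
  mean(boundary_radius(model, "muscle", th) - rb) * 10
}

#' Adjust fat thickness and/or bone location to match targets
#'
#' Fat: a uniform thickness change, compensated in the muscle layer so the
#' outer radius is preserved.  Bone: a translation of the bone axis along
#' the site direction, solved so the re-measured average bone-to-muscle
#' distance matches the target.  Both targets `NULL` is the identity.
#'
#' @param model a `volume_model`.
#' @param site site at which the averages are matched.
#' @param target_fat_mm target average fat thickness, mm, or NULL.
#' @param target_bone_mm target average bone-to-muscle distance, mm, or
#'   NULL.
#' @return The adjusted `volume_model`.
#' @export
adjust_geometry <- function(model, site, target_fat_mm = NULL,
                            target_bone_mm = NULL) {
  if (is.null(target_fat_mm) && is.null(target_bone_mm)) return(model)
  layers <- model$layers
  bone_offset <- model$bone_offset_mm
  if (!is.null(target_fat_mm)) {
    delta_cm <- (target_fat_mm -
                   average_fat_thickness(model, site)) / 10
    new_fat <- layers[[4]]$thickness_cm + delta_cm
    new_muscle <- layers[[3]]$thickness_cm - delta_cm
    if (new_fat <= 0 || new_muscle <= 0)
      stop("fat target not achievable inside the layer stack",
           call. = FALSE)
    layers[[4]] <- tissue_layer("fat", new_fat, layers[[4]]$conductivity)
    layers[[3]] <- tissue_layer("muscle", new_muscle,
                                layers[[3]]$conductivity)
  }
  rebuild <- function(offset) build_model(
    model$representation, layers,
    axial_length_cm = model$axial_length_cm,
    inclusions = model$inclusions,
    boundary_perturbation = model$boundary_perturbation,
    bone_offset_mm = offset,
    pm_width_cm = model$pm_width_cm)
  out <- rebuild(bone_offset)
  if (!is.null(target_bone_mm)) {
    if (model$representation == "PM")
      stop("bone location adjustment applies to radial models",
           call. = FALSE)
    u <- c(cos(site_angle(site)), sin(site_angle(site)))
    f <- function(s) {
      m <- tryCatch(rebuild(bone_offset + s * u), error = function(e) NULL)
      if (is.null(m)) return(NA_real_)
      average_bone_to_muscle_distance(m, site) - target_bone_mm
    }
    d0 <- average_bone_to_muscle_distance(out, site)
    s_est <- d0 - target_bone_mm
    root <- tryCatch(
      stats::uniroot(f, interval = c(s_est - 3, s_est + 3),
                     extendInt = "yes", tol = 1e-6),
      error = function(e)
        stop("bone target forces the bone outside the muscle domain",
             call. = FALSE))
    out <- rebuild(bone_offset + root$root * u)
  }
  out
}

#' Write a threshold or error table to CSV
#'
#' Stable column schema as produced by [run_sweep()] / [error_table()].
#' @param table a tibble.
#' @param path output file.
#' @export
write_table_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
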