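#' Parameters of the synthetic pseudo-anatomical thigh generator
#'
#' The generator emulates the structural features an image-derived model
#' contributes over the concentric stack: smoothly perturbed (non-circular)
#' fat and muscle boundaries, an off-centre femur, and embedded
#' blood-vessel / nerve-trunk inclusions.  Default inclusion sizes follow
#' the tabulated bone-size ratios (vessel cross-section 16%, nerve trunk 6%
#' of the cortical-bone cross-section) and the tabulated mean distances from
#' the fat-muscle boundary (vessel 20.17 mm on the medial ray, nerve trunk
#' 30.07 mm on the posterior ray).
#'
#' @param seed integer seed; the spec is deterministic given the seed.
#' @param fat_perturbation_mm peak harmonic amplitude of the fat/muscle
#'   boundary perturbation, mm.
#' @param n_harmonics number of angular harmonics (<= 4).
#' @param bone_offset_mm length-2 transverse bone-axis offset, mm; the
#'   default shifts the femur 11.24 mm toward the anterior sector.
#' @param vessel_distance_mm radial gap between the fat-muscle boundary and
#'   the vessel surface on the medial ray.
#' @param nerve_distance_mm same for the nerve trunk on the posterior ray.
#' @param vessel_radius_mm,nerve_radius_mm inclusion radii; `NULL` derives
#'   them from the bone-size ratios.
#' @param include_vessel,include_nerve set `FALSE` for the ablated
#'   ("(VN)'") variant with identical boundaries and no inclusions.
#' @param subject 1 or 2, selects the base layer stack.
#' @param axial_length_cm model length.
#' @export
anatomy_params <- function(seed = 1L,
                           fat_perturbation_mm = 3,
                           n_harmonics = 3L,
                           bone_offset_mm = c(0, 11.24),
                           vessel_distance_mm = 20.17,
                           nerve_distance_mm = 30.07,
                           vessel_radius_mm = NULL,
                           nerve_radius_mm = NULL,
                           include_vessel = TRUE,
                           include_nerve = TRUE,
                           subject = 1,
                           axial_length_cm = 40) {
  if (n_harmonics > 4L)
    stop("at most 4 angular harmonics are supported", call. = FALSE)
  structure(
    list(seed = as.integer(seed),
         fat_perturbation_mm = fat_perturbation_mm,
         n_harmonics = as.integer(n_harmonics),
         bone_offset_mm = as.numeric(bone_offset_mm),
         vessel_distance_mm = vessel_distance_mm,
         nerve_distance_mm = nerve_distance_mm,
         vessel_radius_mm = vessel_radius_mm,
         nerve_radius_mm = nerve_radius_mm,
         include_vessel = isTRUE(include_vessel),
         include_nerve = isTRUE(include_nerve),
         subject = subject,
         axial_length_cm = axial_length_cm),
    class = "anatomy_params")
}

# Default inclusion radii from the cortical-bone cross-section area of the
# subject's stack: pi r^2 = ratio * A_bone (annulus between marrow and
# cortical-bone radii).
inclusion_radius_from_bone_mm <- function(layers, ratio) {
  radii <- compute_layer_radii(layers)
  a_bone <- pi * (radii[["cortical_bone"]]^2 - radii[["bone_marrow"]]^2)
  sqrt(ratio * a_bone / pi) * 10
}

#' Generate a pseudo-anatomical volume model
#'
#' Deterministic for a fixed seed: harmonic amplitudes and phases of the
#' boundary perturbation are drawn from a seeded generator, and the emitted
#' spec embeds the full parameter set.
#'
#' @param params an [anatomy_params()] object.
#' @return A `volume_model` with representation `"PSEUDO_AM"`.
#' @export
generate_pseudo_anatomy <- function(params = anatomy_params()) {
  stopifnot(inherits(params, "anatomy_params"))
  layers <- thigh_layers(params$subject)
  radii <- compute_layer_radii(layers)

  set.seed(params$seed)
  draw_harmonics <- function() {
    k <- seq_len(params$n_harmonics) + 1L   # harmonics 2..(n+1): no net shift
    a <- params$fat_perturbation_mm * stats::runif(length(k), 0.4, 1) / k
    phase <- stats::runif(length(k), 0, 2 * pi)
    list(k = k, a_mm = a, phase = phase)
  }
  pert <- if (params$fat_perturbation_mm > 0 && params$n_harmonics > 0)
    list(muscle = draw_harmonics(), fat = draw_harmonics()) else NULL

  r_v <- params$vessel_radius_mm %||%
    inclusion_radius_from_bone_mm(layers, 0.16)
  r_n <- params$nerve_radius_mm %||%
    inclusion_radius_from_bone_mm(layers, 0.06)

  # place inclusions along their site rays, measuring the stated distance
  # from the (perturbed) fat-muscle boundary to the inclusion surface
  probe <- build_model("PSEUDO_AM", layers,
                       axial_length_cm = params$axial_length_cm,
                       boundary_perturbation = pert,
                       bone_offset_mm = params$bone_offset_mm)
  place_on_ray <- function(site, dist_mm, radius_mm) {
    th <- site_angle(site)
    r_fm_mm <- boundary_radius(probe, "muscle", th) * 10
    c_r <- r_fm_mm - dist_mm - radius_mm
    c(c_r * cos(th), c_r * sin(th))
  }
  inclusions <- list()
  if (params$include_vessel)
    inclusions <- c(inclusions, list(inclusion_spec(
      "blood_vessel",
      place_on_ray("medial", params$vessel_distance_mm, r_v), r_v)))
  if (params$include_nerve)
    inclusions <- c(inclusions, list(inclusion_spec(
      "nerve_trunk",
      place_on_ray("posterior", params$nerve_distance_mm, r_n), r_n)))

  model <- build_model("PSEUDO_AM", layers,
                       axial_length_cm = params$axial_length_cm,
                       inclusions = inclusions,
                       boundary_perturbation = pert,
                       bone_offset_mm = params$bone_offset_mm)
  # enforce 2 mm clearance of inclusions from bone and boundaries
  for (inc in inclusions) {
    phi <- seq(0, 2 * pi, length.out = 181)[-181]
    px <- inc$axis_offset_mm[1] / 10 + inc$radius_mm / 10 * cos(phi)
    py <- inc$axis_offset_mm[2] / 10 + inc$radius_mm / 10 * sin(phi)
    probe2 <- model; probe2$inclusions <- list()
    if (!all(point_in_muscle(probe2, px, py, clearance_cm = 0.2)))
      stop(sprintf(
        "%s inclusion violates the 2 mm clearance from other boundaries",
        inc$kind), call. = FALSE)
  }
  model$anatomy_params <- params
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fiber placements at a series of depths along a site ray
#'
#' @param model a `volume_model`.
#' @param site stimulation site.
#' @param depths_mm depths below the fat-muscle boundary.
#' @param diameter_um fiber diameter.
#' @param electrodes electrode pair (axial placement reference).
#' @param clearance_mm minimum allowed distance between the fiber and any
#'   inclusion surface; closer placements are flagged, not moved.
#' @return List of [fiber_placement()] objects, each with attribute
#'   `flagged` (TRUE if within `clearance_mm` of an inclusion).  Depths
#'   outside the muscle are rejected.
#' @export
depth_series <- function(model, site, depths_mm, diameter_um, electrodes,
                         clearance_mm = 0.5) {
  th <- site_angle(site)
  r_fm <- boundary_radius(model, "muscle", th)
  lapply(depths_mm, function(d) {
    p <- fiber_placement(site, d, diameter_um)
    r <- r_fm - d / 10
    x <- r * cos(th); y <- r * sin(th)
    no_inc <- model; no_inc$inclusions <- list()
    if (!point_in_muscle(no_inc, x, y))
      stop(sprintf("depth %.1f mm at %s site is outside the muscle",
                   d, site), call. = FALSE)
    flagged <- FALSE
    for (inc in model$inclusions) {
      gap <- sqrt((x - inc$axis_offset_mm[1] / 10)^2 +
                  (y - inc$axis_offset_mm[2] / 10)^2) - inc$radius_mm / 10
      if (gap < clearance_mm / 10) flagged <- TRUE
    }
    attr(p, "flagged") <- flagged
    p
  })
}
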