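#' @importFrom stats uniroot integrate sd cor setNames
#' @importFrom utils write.csv head tail
NULL

canonical_layer_order <- c("bone_marrow", "cortical_bone", "muscle",
                           "fat", "skin")

#' Construct a tissue layer
#'
#' @param name tissue label (see [tissue_conductivities]).
#' @param thickness_cm layer thickness in cm, strictly positive.
#' @param conductivity a [conductivity_tensor()]; defaults to the tabulated
#'   value for `name`.
#' @return A `tissue_layer` object.
#' @export
tissue_layer <- function(name, thickness_cm,
                         conductivity = conductivity_of(name)) {
  if (!name %in% tissue_names())
    stop(sprintf("unknown tissue label '%s'", name), call. = FALSE)
  if (!is.finite(thickness_cm) || thickness_cm <= 0)
    stop(sprintf("layer '%s': thickness must be > 0 (got %s)",
                 name, format(thickness_cm)), call. = FALSE)
  stopifnot(inherits(conductivity, "conductivity_tensor"))
  structure(list(name = name, thickness_cm = thickness_cm,
                 conductivity = conductivity),
            class = "tissue_layer")
}

#' Layer stacks of the two tabulated thigh geometries
#'
#' Returns the five-layer stack (bone marrow, cortical bone, muscle, fat,
#' skin, innermost first) with the tabulated thicknesses for subject 1
#' (CM1/PM1) or subject 2 (CM2/PM2).
#'
#' @param subject 1 or 2.
#' @return List of [tissue_layer()] objects in canonical order.
#' @export
thigh_layers <- function(subject = 1) {
  th <- switch(as.character(subject),
    "1" = c(bone_marrow = 0.87, cortical_bone = 0.63, muscle = 4.32,
            fat = 1.24, skin = 0.20),
    "2" = c(bone_marrow = 0.94, cortical_bone = 0.57, muscle = 5.02,
            fat = 1.73, skin = 0.20),
    stop("subject must be 1 or 2", call. = FALSE))
  lapply(names(th), function(nm) tissue_layer(nm, th[[nm]]))
}

#' Cumulative outer radii of a layer stack
#'
#' @param layers ordered list of [tissue_layer()] (innermost first).
#' @return Numeric vector of outer radii in cm, one per layer, strictly
#'   increasing; the last element equals the total stack thickness.
#' @examples
#' compute_layer_radii(thigh_layers(1)) # 0.87 1.50 5.82 7.06 7.26
#' @export
compute_layer_radii <- function(layers) {
  th <- vapply(layers, function(l) l$thickness_cm, numeric(1))
  nm <- vapply(layers, function(l) l$name, character(1))
  bad <- which(!is.finite(th) | th <= 0)
  if (length(bad))
    stop(sprintf("layer '%s' has non-positive thickness", nm[bad[1]]),
         call. = FALSE)
  setNames(cumsum(th), nm)
}

site_angle <- function(site) {
  switch(site,
    lateral   = 0,
    anterior  = pi / 2,
    medial    = pi,
    posterior = -pi / 2,
    stop(sprintf("unknown site '%s'", site), call. = FALSE))
}

site_names <- function() c("anterior", "posterior", "medial", "lateral")

#' Specify a cylindrical inclusion embedded in the muscle
#'
#' Inclusions are circular cylinders parallel to the limb axis, spanning the
#' full model length.
#'
#' @param kind `"blood_vessel"` or `"nerve_trunk"`.
#' @param axis_offset_mm length-2 numeric, transverse (x, y) position of the
#'   inclusion axis in mm.
#' @param radius_mm inclusion radius, mm, > 0.
#' @param conductivity a [conductivity_tensor()]; defaults to blood / nerve
#'   tabulated values.
#' @export
inclusion_spec <- function(kind, axis_offset_mm, radius_mm,
                           conductivity = NULL) {
  kind <- match.arg(kind, c("blood_vessel", "nerve_trunk"))
  if (!is.numeric(axis_offset_mm) || length(axis_offset_mm) != 2)
    stop("axis_offset_mm must be length-2 numeric", call. = FALSE)
  if (!is.finite(radius_mm) || radius_mm <= 0)
    stop("inclusion radius must be > 0", call. = FALSE)
  if (is.null(conductivity))
    conductivity <- conductivity_of(
      if (kind == "blood_vessel") "blood" else "nerve")
  structure(list(kind = kind, axis_offset_mm = as.numeric(axis_offset_mm),
                 radius_mm = radius_mm, conductivity = conductivity),
            class = "inclusion_spec")
}

# Radial perturbation of an outer boundary: sum of cosine harmonics,
# amplitudes in mm. `p` is list(k = integer vector, a_mm, phase).
perturbation_delta_cm <- function(p, theta) {
  if (is.null(p)) return(rep(0, length(theta)))
  d <- numeric(length(theta))
  for (i in seq_along(p$k))
    d <- d + p$a_mm[i] * cos(p$k[i] * theta + p$phase[i])
  d / 10
}

#' Radius of a named boundary as a function of angle
#'
#' For the concentric representations this is constant; for perturbed
#' pseudo-anatomical models the muscle and fat boundaries carry angular
#' harmonics and the skin surface follows the fat boundary at constant
#' thickness.  The bone boundaries are circles about the (possibly offset)
#' bone axis and are returned via their centre/radius instead.
#'
#' @param model a `volume_model` spec.
#' @param which `"muscle"`, `"fat"` or `"skin"` outer boundary.
#' @param theta angle(s), radians.
#' @return Radius in cm at each `theta`.
#' @export
boundary_radius <- function(model, which = c("muscle", "fat", "skin"),
                            theta) {
  which <- match.arg(which)
  r <- model$radii[[switch(which, muscle = "muscle", fat = "fat",
                           skin = "skin")]]
  pert <- model$boundary_perturbation
  if (is.null(pert)) return(rep(r, length(theta)))
  if (which == "muscle")
    r + perturbation_delta_cm(pert$muscle, theta)
  else # fat outer and skin outer both follow the fat perturbation
    r + perturbation_delta_cm(pert$fat, theta)
}

# Distance from the model axis to the exit point of the cortical-bone outer
# boundary along the ray at angle theta (NA if the ray misses the bone).
bone_exit_radius_cm <- function(model, theta) {
  c_cm <- model$bone_offset_mm / 10
  rb <- model$radii[["cortical_bone"]]
  u <- cbind(cos(theta), sin(theta))
  along <- u[, 1] * c_cm[1] + u[, 2] * c_cm[2]
  perp2 <- sum(c_cm^2) - along^2
  out <- along + sqrt(pmax(rb^2 - perp2, 0))
  out[perp2 > rb^2] <- NA_real_
  out
}

point_in_muscle <- function(model, x_cm, y_cm, clearance_cm = 0) {
  th <- atan2(y_cm, x_cm)
  r <- sqrt(x_cm^2 + y_cm^2)
  c_cm <- model$bone_offset_mm / 10
  rb <- model$radii[["cortical_bone"]]
  d_bone <- sqrt((x_cm - c_cm[1])^2 + (y_cm - c_cm[2])^2)
  inside <- r <= boundary_radius(model, "muscle", th) - clearance_cm &
    d_bone >= rb + clearance_cm
  if (length(model$inclusions)) {
    for (inc in model$inclusions) {
      ic <- inc$axis_offset_mm / 10
      d <- sqrt((x_cm - ic[1])^2 + (y_cm - ic[2])^2)
      inside <- inside & d >= inc$radius_mm / 10 + clearance_cm
    }
  }
  inside
}

#' Build a validated volume-conductor model specification
#'
#' @param representation `"CM"` (concentric cylinder stack), `"PM"`
#'   (parallel slab stack) or `"PSEUDO_AM"` (perturbed pseudo-anatomy,
#'   optionally with inclusions).
#' @param layers ordered list of [tissue_layer()] from innermost
#'   (bone marrow) to outermost (skin); see [thigh_layers()].
#' @param axial_length_cm model length along z, default 40 cm.
#' @param inclusions list of [inclusion_spec()] (PSEUDO_AM only).
#' @param boundary_perturbation optional list with elements `muscle` and/or
#'   `fat`, each `list(k, a_mm, phase)` cosine harmonics (PSEUDO_AM only).
#' @param bone_offset_mm length-2 transverse offset of the bone axis, mm.
#' @param pm_width_cm lateral slab width for PM; defaults to half the
#'   equivalent cylinder circumference so the stimulated surface is
#'   comparable between representations.
#' @return A `volume_model` object.
#' @export
build_model <- function(representation = c("CM", "PM", "PSEUDO_AM"),
                        layers = thigh_layers(1),
                        axial_length_cm = 40,
                        inclusions = list(),
                        boundary_perturbation = NULL,
                        bone_offset_mm = c(0, 0),
                        pm_width_cm = NULL) {
  representation <- match.arg(representation)
  nm <- vapply(layers, function(l) l$name, character(1))
  if (!identical(nm, canonical_layer_order))
    stop(sprintf(
      "layer order must be %s (innermost first); got %s",
      paste(canonical_layer_order, collapse = ", "),
      paste(nm, collapse = ", ")), call. = FALSE)
  radii <- compute_layer_radii(layers)
  if (!is.finite(axial_length_cm) || axial_length_cm <= 0)
    stop("axial_length_cm must be > 0", call. = FALSE)
  if (representation %in% c("CM", "PM")) {
    if (length(inclusions))
      stop(sprintf("%s models must be inclusion-free", representation),
           call. = FALSE)
    if (!is.null(boundary_perturbation))
      stop(sprintf("%s models admit no boundary perturbation",
                   representation), call. = FALSE)
  }
  if (representation == "PM" && any(bone_offset_mm != 0))
    stop("PM models have no bone offset", call. = FALSE)
  if (is.null(pm_width_cm)) pm_width_cm <- pi * radii[["skin"]]
  model <- structure(
    list(representation = representation,
         layers = layers,
         radii = radii,
         axial_length_cm = axial_length_cm,
         inclusions = inclusions,
         boundary_perturbation = boundary_perturbation,
         bone_offset_mm = as.numeric(bone_offset_mm),
         pm_width_cm = pm_width_cm),
    class = "volume_model")
  if (representation != "PM") {
    # nesting: muscle < fat < skin boundary everywhere; bone inside muscle
    th <- seq(0, 2 * pi, length.out = 721)
    rm_ <- boundary_radius(model, "muscle", th)
    rf <- boundary_radius(model, "fat", th)
    rs <- boundary_radius(model, "skin", th)
    if (any(rm_ <= 0) || any(rf <= rm_) || any(rs <= rf - 1e-12))
      stop("perturbed boundaries are not nested", call. = FALSE)
    rb <- radii[["cortical_bone"]]
    if (sqrt(sum((bone_offset_mm / 10)^2)) + rb >= min(rm_))
      stop("bone offset pushes the bone outside the muscle boundary",
           call. = FALSE)
    for (inc in inclusions) {
      phi <- seq(0, 2 * pi, length.out = 361)[-361]
      px <- inc$axis_offset_mm[1] / 10 + inc$radius_mm / 10 * cos(phi)
      py <- inc$axis_offset_mm[2] / 10 + inc$radius_mm / 10 * sin(phi)
      model_no_inc <- model
      model_no_inc$inclusions <- list()
      if (!all(point_in_muscle(model_no_inc, px, py)))
        stop(sprintf("%s inclusion does not lie entirely inside the muscle",
                     inc$kind), call. = FALSE)
    }
  }
  model
}

#' @export
print.volume_model <- function(x, ...) {
  cat(sprintf("<volume_model> %s, outer radius %.2f cm, length %g cm\n",
              x$representation, x$radii[["skin"]], x$axial_length_cm))
  cat(sprintf("  layers (cm): %s\n",
              paste(sprintf("%s %.2f", names(x$radii),
                            vapply(x$layers, function(l) l$thickness_cm,
                                   numeric(1))),
                    collapse = ", ")))
  if (length(x$inclusions))
    cat(sprintf("  inclusions: %s\n",
                paste(vapply(x$inclusions, function(i)
                  sprintf("%s r=%.1f mm", i$kind, i$radius_mm),
                  character(1)), collapse = ", ")))
  invisible(x)
}

#' Place a surface electrode pair
#'
#' Two square patches on the outer (skin) surface, symmetric about the fixed
#' pair centerline at z = 0.  The proximal (cathode by default) patch
#' occupies negative z.  On cylindrical models the square is measured
#' geodesically (arc length) on the skin surface; on PM it is planar on the
#' top face.
#'
#' @param model a `volume_model`.
#' @param site `"anterior"`, `"posterior"`, `"medial"` or `"lateral"`.
#' @param area_cm2 patch area; values outside the studied 1--25 cm^2 range
#'   are accepted with a warning.
#' @param gap_cm edge-to-edge interelectrode distance; values outside
#'   0--6 cm warn.
#' @return An `electrode_pair` object.
#' @export
place_electrodes <- function(model, site, area_cm2, gap_cm) {
  site <- match.arg(site, site_names())
  if (!is.finite(area_cm2) || area_cm2 <= 0)
    stop("electrode area must be > 0", call. = FALSE)
  if (!is.finite(gap_cm) || gap_cm < 0)
    stop("interelectrode gap must be >= 0", call. = FALSE)
  if (area_cm2 < 1 || area_cm2 > 25)
    warning(sprintf("electrode area %.2f cm^2 outside the studied 1-25 cm^2 range",
                    area_cm2), call. = FALSE)
  if (gap_cm > 6)
    warning(sprintf("interelectrode distance %.2f cm outside the studied 0-6 cm range",
                    gap_cm), call. = FALSE)
  side <- sqrt(area_cm2)
  theta_s <- site_angle(site)
  if (model$representation != "PM") {
    r_skin <- boundary_radius(model, "skin", theta_s)
    if (side / r_skin > pi / 2)
      stop(sprintf(
        "electrode arc (%.2f rad) exceeds one quadrant of the skin cylinder",
        side / r_skin), call. = FALSE)
  } else {
    if (side > model$pm_width_cm)
      stop("electrode wider than the PM slab", call. = FALSE)
  }
  z_extent <- gap_cm / 2 + side
  if (z_extent > model$axial_length_cm / 2)
    stop("electrode extent exceeds the model surface", call. = FALSE)
  structure(
    list(site = site, area_cm2 = area_cm2, side_cm = side, gap_cm = gap_cm,
         centerline_z_cm = 0,
         # patch 1 is proximal (negative z); role assignment is separate
         z_ranges = list(proximal = c(-gap_cm / 2 - side, -gap_cm / 2),
                         distal   = c(gap_cm / 2, gap_cm / 2 + side)),
         roles = c(proximal = "cathode", distal = "anode"),
         theta_center = theta_s),
    class = "electrode_pair")
}

#' Swap cathode/anode roles (geometry is unchanged)
#' @param electrodes an `electrode_pair`.
#' @export
swap_electrode_roles <- function(electrodes) {
  electrodes$roles <- c(proximal = unname(electrodes$roles["distal"]),
                        distal = unname(electrodes$roles["proximal"]))
  electrodes
}

#' Centre (z, cm) of the proximal electrode patch
#' @keywords internal
proximal_center_z <- function(electrodes) mean(electrodes$z_ranges$proximal)

#' Describe a fiber placement
#'
#' @param site stimulation site.
#' @param depth_mm distance below the fat-muscle boundary, mm, >= 0.
#' @param diameter_um fiber outer diameter, um.
#' @param length_mm fiber length, default 63 mm.
#' @export
fiber_placement <- function(site, depth_mm, diameter_um, length_mm = 63) {
  site <- match.arg(site, site_names())
  stopifnot(depth_mm >= 0, diameter_um > 0, length_mm > 0)
  structure(list(site = site, depth_mm = depth_mm,
                 diameter_um = diameter_um, length_mm = length_mm,
                 orientation = "axial"),
            class = "fiber_placement")
}

#' Straight fiber trajectory at 0.1 mm spacing
#'
#' Points run parallel to z, centred under the proximal electrode centre, at
#' the stated depth below the local fat-muscle boundary along the site ray.
#'
#' @param model a `volume_model`.
#' @param placement a [fiber_placement()].
#' @param electrodes an [place_electrodes()] pair (fixes the axial centre).
#' @return n x 3 matrix of (x, y, z) in cm with `round(length/0.1) + 1`
#'   rows; attributes `placement` and `center_z_cm`.
#' @export
fiber_trajectory <- function(model, placement, electrodes) {
  spacing_mm <- 0.1
  n <- round(placement$length_mm / spacing_mm) + 1
  zc <- proximal_center_z(electrodes)
  z <- zc + (seq_len(n) - (n + 1) / 2) * spacing_mm / 10
  if (min(z) < -model$axial_length_cm / 2 ||
      max(z) > model$axial_length_cm / 2) {
    s_off <- if (min(z) < -model$axial_length_cm / 2) 0 else
      (max(z) + model$axial_length_cm / 2) * 10
    stop(sprintf("fiber trajectory exits the domain (arclength %.1f mm)",
                 s_off), call. = FALSE)
  }
  depth_cm <- placement$depth_mm / 10
  if (model$representation == "PM") {
    y_fm <- model$radii[["muscle"]] # fat-muscle plane height from bottom
    y <- y_fm - depth_cm
    if (depth_cm > model$layers[[3]]$thickness_cm)
      stop("fiber depth exceeds the muscle thickness", call. = FALSE)
    xy <- cbind(0, y)
  } else {
    th <- site_angle(placement$site)
    r_fm <- boundary_radius(model, "muscle", th)
    r <- r_fm - depth_cm
    x <- r * cos(th); y <- r * sin(th)
    ok <- point_in_muscle(model, x, y)
    on_boundary <- placement$depth_mm == 0
    if (!ok && !on_boundary)
      stop(sprintf(
        "fiber at depth %.1f mm leaves the muscle domain (arclength 0.0 mm)",
        placement$depth_mm), call. = FALSE)
    xy <- cbind(x, y)
  }
  pts <- cbind(x = rep(xy[1], n), y = rep(xy[2], n), z = z)
  attr(pts, "placement") <- placement
  attr(pts, "center_z_cm") <- zc
  pts
}
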