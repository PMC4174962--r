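#' Read a model/stimulation configuration file
#'
#' Structured YAML configuration naming the representation, layer
#' thicknesses (with optional conductivity overrides), electrodes, fiber
#' and inclusions.  Validation failures name the offending field.
#'
#' @param path YAML file.
#' @return List with `model` (a `volume_model`), `electrodes` (an
#'   `electrode_pair` or NULL) and `fiber` (a [fiber_placement()] or NULL).
#' @export
read_model_config <- function(path) {
  cfg <- tryCatch(yaml::read_yaml(path),
                  error = function(e)
                    stop(sprintf("cannot parse '%s': %s", path,
                                 conditionMessage(e)), call. = FALSE))
  need <- function(x, field) {
    if (is.null(x))
      stop(sprintf("%s: missing required field '%s'", path, field),
           call. = FALSE)
    x
  }
  rep_ <- need(cfg$representation, "representation")
  if (!rep_ %in% c("CM", "PM", "PSEUDO_AM"))
    stop(sprintf("%s: representation must be CM, PM or PSEUDO_AM (got '%s')",
                 path, rep_), call. = FALSE)
  layers <- if (is.null(cfg$layers)) {
    thigh_layers(cfg$subject %||% 1)
  } else {
    lapply(canonical_layer_order, function(nm) {
      spec <- need(cfg$layers[[nm]], paste0("layers.", nm))
      cond <- if (!is.null(spec$sigma_mSm))
        conductivity_tensor(spec$sigma_mSm,
                            spec$sigma_longitudinal_mSm %||% spec$sigma_mSm)
      else conductivity_of(nm)
      tissue_layer(nm, need(spec$thickness_cm,
                            paste0("layers.", nm, ".thickness_cm")), cond)
    })
  }
  inclusions <- lapply(cfg$inclusions, function(inc) {
    inclusion_spec(need(inc$kind, "inclusions.kind"),
                   need(inc$axis_offset_mm, "inclusions.axis_offset_mm"),
                   need(inc$radius_mm, "inclusions.radius_mm"))
  })
  model <- build_model(rep_, layers,
                       axial_length_cm = cfg$axial_length_cm %||% 40,
                       inclusions = inclusions,
                       boundary_perturbation = cfg$boundary_perturbation,
                       bone_offset_mm = cfg$bone_offset_mm %||% c(0, 0))
  electrodes <- NULL
  if (!is.null(cfg$electrodes)) {
    e <- cfg$electrodes
    electrodes <- place_electrodes(model, need(e$site, "electrodes.site"),
                                   need(e$area_cm2, "electrodes.area_cm2"),
                                   need(e$gap_cm, "electrodes.gap_cm"))
  }
  fiber <- NULL
  if (!is.null(cfg$fiber)) {
    f <- cfg$fiber
    fiber <- fiber_placement(need(f$site %||% cfg$electrodes$site,
                                  "fiber.site"),
                             need(f$depth_mm, "fiber.depth_mm"),
                             need(f$diameter_um, "fiber.diameter_um"),
                             f$length_mm %||% 63)
  }
  list(model = model, electrodes = electrodes, fiber = fiber)
}

#' Export the model's boundary surfaces as a Wavefront OBJ mesh
#'
#' Writes the layer boundaries (and inclusion cylinders) of a radial model
#' as extruded tube meshes for inspection in standard mesh viewers.
#'
#' @param model a `volume_model`.
#' @param path output `.obj` file.
#' @param n_theta angular resolution.
#' @export
write_model_obj <- function(model, path, n_theta = 96) {
  con <- file(path, "w")
  on.exit(close(con))
  zs <- c(-model$axial_length_cm / 2, model$axial_length_cm / 2)
  v_count <- 0L
  emit_tube <- function(xy, name) {
    writeLines(sprintf("o %s", name), con)
    for (z in zs)
      for (i in seq_len(nrow(xy)))
        writeLines(sprintf("v %.5f %.5f %.5f", xy[i, 1], xy[i, 2], z), con)
    n <- nrow(xy)
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      writeLines(sprintf("f %d %d %d %d",
                         v_count + i, v_count + j,
                         v_count + n + j, v_count + n + i), con)
    }
    v_count <<- v_count + 2L * n
  }
  th <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  if (model$representation == "PM") {
    w <- model$pm_width_cm / 2
    for (i in seq_along(model$radii)) {
      y <- unname(model$radii[i])
      xy <- rbind(c(-w, 0), c(w, 0), c(w, y), c(-w, y))
      emit_tube(xy, names(model$radii)[i])
    }
  } else {
    cb <- model$bone_offset_mm / 10
    emit_tube(cbind(cb[1] + model$radii[["bone_marrow"]] * cos(th),
                    cb[2] + model$radii[["bone_marrow"]] * sin(th)),
              "bone_marrow")
    emit_tube(cbind(cb[1] + model$radii[["cortical_bone"]] * cos(th),
                    cb[2] + model$radii[["cortical_bone"]] * sin(th)),
              "cortical_bone")
    for (nm in c("muscle", "fat", "skin")) {
      r <- boundary_radius(model, nm, th)
      emit_tube(cbind(r * cos(th), r * sin(th)), nm)
    }
    for (inc in model$inclusions) {
      ic <- inc$axis_offset_mm / 10
      emit_tube(cbind(ic[1] + inc$radius_mm / 10 * cos(th),
                      ic[2] + inc$radius_mm / 10 * sin(th)), inc$kind)
    }
  }
  invisible(path)
}
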