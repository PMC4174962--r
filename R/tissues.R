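#' Tissue conductivities for the layered thigh models
#'
#' Electrical conductivities (mS/m) of the seven tissues used by the volume
#' conductor models, at the 2 kHz-appropriate working point of the
#' quasistatic (nondispersive) approximation.  Muscle is anisotropic:
#' transverse conductivity applies in the limb cross-section, longitudinal
#' along the limb z-axis.  All other tissues are isotropic.
#'
#' @format A data frame with columns `tissue`, `sigma_transverse_mSm`,
#'   `sigma_longitudinal_mSm`, `isotropic`.
#' @export
tissue_conductivities <- data.frame(
  tissue = c("skin", "fat", "muscle", "cortical_bone", "bone_marrow",
             "blood", "nerve"),
  sigma_transverse_mSm  = c(0.790, 42.27,  82.38, 20.24, 101.93, 700.0, 29.89),
  sigma_longitudinal_mSm = c(0.790, 42.27, 329.53, 20.24, 101.93, 700.0, 29.89),
  isotropic = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE),
  stringsAsFactors = FALSE
)

#' Closed tissue vocabulary
#' @keywords internal
tissue_names <- function() tissue_conductivities$tissue

#' Construct a conductivity tensor
#'
#' A transversely isotropic conductivity with the distinguished axis along
#' the limb z-axis.  Values are in mS/m.
#'
#' @param sigma_transverse conductivity in the transverse (cross-section)
#'   plane, mS/m.
#' @param sigma_longitudinal conductivity along the limb axis, mS/m; defaults
#'   to `sigma_transverse` (isotropic).
#' @return An object of class `conductivity_tensor` with fields
#'   `sigma_transverse`, `sigma_longitudinal`, `isotropic`.
#' @export
conductivity_tensor <- function(sigma_transverse,
                                sigma_longitudinal = sigma_transverse) {
  if (!is.finite(sigma_transverse) || sigma_transverse <= 0)
    stop("sigma_transverse must be strictly positive", call. = FALSE)
  if (!is.finite(sigma_longitudinal) || sigma_longitudinal <= 0)
    stop("sigma_longitudinal must be strictly positive", call. = FALSE)
  structure(
    list(sigma_transverse = sigma_transverse,
         sigma_longitudinal = sigma_longitudinal,
         isotropic = isTRUE(all.equal(sigma_transverse, sigma_longitudinal))),
    class = "conductivity_tensor")
}

#' Look up the conductivity tensor of a tissue
#'
#' @param name one of `"skin"`, `"fat"`, `"muscle"`, `"cortical_bone"`,
#'   `"bone_marrow"`, `"blood"`, `"nerve"`.
#' @return A [conductivity_tensor()]; muscle returns the anisotropic tensor
#'   (82.38 mS/m transverse, 329.53 mS/m longitudinal), all other tissues are
#'   isotropic.
#' @examples
#' conductivity_of("skin")$sigma_transverse    # 0.790 mS/m
#' conductivity_of("muscle")$sigma_longitudinal # 329.53 mS/m
#' @export
conductivity_of <- function(name) {
  i <- match(name, tissue_conductivities$tissue)
  if (is.na(i))
    stop(sprintf("unknown tissue label '%s' (known: %s)", name,
                 paste(tissue_conductivities$tissue, collapse = ", ")),
         call. = FALSE)
  conductivity_tensor(tissue_conductivities$sigma_transverse_mSm[i],
                      tissue_conductivities$sigma_longitudinal_mSm[i])
}

#' @export
print.conductivity_tensor <- function(x, ...) {
  if (x$isotropic)
    cat(sprintf("<conductivity> isotropic %.4g mS/m\n", x$sigma_transverse))
  else
    cat(sprintf("<conductivity> transverse %.4g, longitudinal %.4g mS/m\n",
                x$sigma_transverse, x$sigma_longitudinal))
  invisible(x)
}
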