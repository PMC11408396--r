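#' Convert a HU voxel model to densities and material classes
#'
#' Mass density follows a two-segment linear ramp anchored at water:
#' \eqn{\rho = 1000 (1 + HU/1000)} kg/m^3 up to HU 100, and
#' \eqn{\rho = 1000 (1.052 + 0.48 (HU - 100)/1000)} above, the standard
#' CT-number-to-density calibration used in voxel Monte Carlo codes.
#' Material classes: air (HU < -950), lung (-950 to -200), soft tissue
#' (-200 to 120), bone (>= 120). HU below -1024 are clamped.
#'
#' @param model A `voxdose_model`.
#' @return A `voxdose_materials`: list with `density` (kg/m^3 array),
#'   `class` (integer array, 1 = air, 2 = lung, 3 = soft tissue, 4 = bone),
#'   `spacing`, `origin`, and `class_names` mapping classes to attenuation
#'   table materials.
#' @export
#' @examples
#' ph <- build_phantom(default_adult_spec("male", 1.76, 73, seed = 2))
#' mg <- hu_to_materials(ph$model)
hu_to_materials <- function(model) {
  stopifnot(inherits(model, "voxdose_model"))
  hu <- pmax(model$hu, -1024)
  dens <- ifelse(hu <= 100,
                 1000 * (1 + hu / 1000),
                 1000 * (1.052 + 0.48 * (hu - 100) / 1000))
  dens <- pmax(dens, 1e-3)  # avoid zero-mass voxels in vacuum-like air
  cls <- array(3L, dim = dim(hu))
  cls[hu < -950] <- 1L
  cls[hu >= -950 & hu < -200] <- 2L
  cls[hu >= 120] <- 4L
  structure(list(density = dens, class = cls,
                 spacing = model$spacing, origin = model$origin,
                 class_names = c("air", "lung", "soft_tissue", "bone")),
            class = "voxdose_materials")
}

#' @export
print.voxdose_materials <- function(x, ...) {
  tab <- table(factor(x$class, 1:4, x$class_names))
  cat("<material grid>",
      paste(sprintf("%s: %d", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  invisible(x)
}
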