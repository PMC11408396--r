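#' Longitudinal (z) scan range
#'
#' A half-open interval `[z_start, z_end)` in mm along the scanner axis.
#' All z arithmetic in the package uses the convention that slice `i`
#' (0-based) of a grid with inferior corner `z0` and slice thickness `dz`
#' occupies `[z0 + i*dz, z0 + (i+1)*dz)`.
#'
#' @param z_start,z_end Interval bounds in mm, `z_end > z_start`.
#' @return A `voxdose_zrange`.
#' @export
#' @examples
#' z_range(120, 303)
z_range <- function(z_start, z_end) {
  stopifnot(is.numeric(z_start), is.numeric(z_end),
            length(z_start) == 1, length(z_end) == 1)
  if (!is.finite(z_start) || !is.finite(z_end) || z_end <= z_start) {
    stop("invalid z range: need finite z_end > z_start, got [",
         z_start, ", ", z_end, ")")
  }
  structure(list(z_start = z_start, z_end = z_end), class = "voxdose_zrange")
}

#' @export
print.voxdose_zrange <- function(x, ...) {
  cat(sprintf("<z range> [%.1f, %.1f) mm (length %.1f mm)\n",
              x$z_start, x$z_end, x$z_end - x$z_start))
  invisible(x)
}

#' Length of a z range in mm
#' @param z A `voxdose_zrange`.
#' @export
z_length <- function(z) z$z_end - z$z_start

#' Extend a scan range by the helical overscan
#'
#' Helical reconstruction needs data beyond the reconstructed range, so the
#' x-ray exposure extends past it at both ends. The default protocols use a
#' 12 mm extension in both the superior and inferior direction.
#'
#' @param z A `voxdose_zrange`.
#' @param overscan_mm Overscan per side, mm, `>= 0`.
#' @return The extended `voxdose_zrange`.
#' @export
#' @examples
#' extend_with_overscan(z_range(120, 300), 12)  # [108, 312)
extend_with_overscan <- function(z, overscan_mm) {
  stopifnot(inherits(z, "voxdose_zrange"))
  if (!is.numeric(overscan_mm) || length(overscan_mm) != 1 ||
      !is.finite(overscan_mm) || overscan_mm < 0) {
    stop("overscan must be a single non-negative number of mm")
  }
  z_range(z$z_start - overscan_mm, z$z_end + overscan_mm)
}
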