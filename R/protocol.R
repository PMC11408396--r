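#' Helical CT scan protocol
#'
#' Bundles the exposure and geometry parameters of a helical scan. Defaults
#' mirror the simulated scanner's chest/cardiac protocols: 120 kV, 0.5 s
#' rotation, pitch 0.7, 19.2 mm collimation, 500 mm scan FOV and a 595 mm
#' focus-isocenter distance (full fan angle 2 atan(250/595) = 0.7957 rad),
#' with a 12 mm overscan on both sides of the scan range.
#'
#' @param scan_range A [z_range()] giving the reconstructed scan range, mm.
#' @param tube_kv Tube voltage, kV.
#' @param rotation_time Gantry rotation time, s.
#' @param pitch Table feed per rotation / collimation (dimensionless).
#' @param collimation Total beam collimation at the isocenter, mm.
#' @param scan_fov Scan field of view, mm.
#' @param focus_isocenter_distance mm.
#' @param fan_angle Full fan angle, rad; derived from `scan_fov` and
#'   `focus_isocenter_distance` when `NULL`, and checked for consistency
#'   against them otherwise.
#' @param overscan Overscan per side, mm: the additional irradiated length
#'   beyond the reconstructed scan range in each direction.
#' @param overscan_mode How the overscan maps to tube travel:
#'   `"irradiated"` (default) extends the emission range by
#'   `overscan - collimation/2` so the irradiated length beyond the range
#'   equals `overscan`; `"table"` extends the emission range by the full
#'   `overscan`.
#' @param tcm Tube-current-modulation table: data frame with columns `z`
#'   (slice position, mm) and `mas` (per-slice average tube current-time
#'   product). `NULL` means a constant tube current.
#' @param photon_budget Number of photon histories for simulations.
#' @param seed Integer seed recorded with simulation output.
#' @return A `voxdose_protocol`.
#' @export
scan_protocol <- function(scan_range, tube_kv = 120, rotation_time = 0.5,
                          pitch = 0.7, collimation = 19.2, scan_fov = 500,
                          focus_isocenter_distance = 595, fan_angle = NULL,
                          overscan = 12,
                          overscan_mode = c("irradiated", "table"),
                          tcm = NULL, photon_budget = 1e6, seed = 1L) {
  overscan_mode <- match.arg(overscan_mode)
  stopifnot(inherits(scan_range, "voxdose_zrange"))
  if (pitch <= 0) stop("pitch must be positive")
  if (collimation <= 0) stop("collimation must be positive")
  geo_fan <- 2 * atan((scan_fov / 2) / focus_isocenter_distance)
  if (is.null(fan_angle)) {
    fan_angle <- geo_fan
  } else if (abs(fan_angle - geo_fan) > 0.02) {
    stop(sprintf("fan angle %.4f rad inconsistent with scan FOV %g mm at FID %g mm (expect %.4f)",
                 fan_angle, scan_fov, focus_isocenter_distance, geo_fan))
  }
  if (!is.null(tcm)) {
    stopifnot(is.data.frame(tcm), all(c("z", "mas") %in% names(tcm)))
    if (nrow(tcm) == 0) stop("empty tcm table")
    if (any(!is.finite(tcm$mas)) || any(tcm$mas <= 0)) {
      stop("tcm mAs values must be positive and finite")
    }
  }
  structure(list(scan_range = scan_range, tube_kv = tube_kv,
                 rotation_time = rotation_time, pitch = pitch,
                 collimation = collimation, scan_fov = scan_fov,
                 focus_isocenter_distance = focus_isocenter_distance,
                 fan_angle = fan_angle, overscan = overscan,
                 overscan_mode = overscan_mode, tcm = tcm,
                 photon_budget = photon_budget, seed = as.integer(seed)),
            class = "voxdose_protocol")
}

#' @export
print.voxdose_protocol <- function(x, ...) {
  cat(sprintf(
    "<scan protocol> %g kV, pitch %.2f, collimation %.1f mm, range [%.1f, %.1f) mm + %g mm overscan, %s TCM\n",
    x$tube_kv, x$pitch, x$collimation, x$scan_range$z_start,
    x$scan_range$z_end, x$overscan,
    if (is.null(x$tcm)) "uniform" else "tabulated"))
  invisible(x)
}

# Emission (tube-travel) range implied by the overscan. The overscan
# parameter is the additional *irradiated* length beyond the reconstructed
# range; since the collimated beam already spills collimation/2 beyond the
# outermost table positions, the tube travel extends by
# overscan - collimation/2 (clamped at zero). overscan_mode = "table"
# treats the overscan as raw table-travel extension instead.
emission_range <- function(protocol) {
  ext <- if (identical(protocol$overscan_mode, "table")) {
    protocol$overscan
  } else {
    max(0, protocol$overscan - protocol$collimation / 2)
  }
  if (ext <= 0) protocol$scan_range else {
    extend_with_overscan(protocol$scan_range, ext)
  }
}

#' Number of gantry rotations over the exposed range
#'
#' Table feed per rotation is pitch x collimation; the exposed range is the
#' scan range extended by the overscan on both sides.
#' @param protocol A `voxdose_protocol`.
#' @export
n_rotations <- function(protocol) {
  z_length(emission_range(protocol)) / (protocol$pitch * protocol$collimation)
}

# tcm weight at z positions: nearest-slice lookup normalised to the mean mAs
# of the supplied table. Normalising by the full table keeps the dose scale
# identical across simulations that share a TCM table but expose different
# sub-ranges (truncated vs whole-body scenarios); restrict the table before
# building the protocol to normalise per scan instead.
tcm_weight <- function(protocol, z) {
  if (is.null(protocol$tcm)) return(rep(1, length(z)))
  tab <- protocol$tcm
  idx <- vapply(z, function(zz) which.min(abs(tab$z - zz)), integer(1))
  tab$mas[idx] / mean(tab$mas)
}

#' Source state along the helical trajectory
#'
#' For a normalised scan parameter s in [0, 1): tube angle, table position,
#' focal-spot location and the tube-current weight. The table advances
#' linearly over the overscan-extended range with feed pitch x collimation
#' per rotation; the focal spot circles at the focus-isocenter distance.
#'
#' @param protocol A `voxdose_protocol`.
#' @param s Normalised scan parameter values in [0, 1).
#' @param isocenter (x, y) of the rotation axis, mm (default c(0, 0)).
#' @return Tibble: `s`, `z` (table position), `angle` (rad), focal-spot
#'   `fx`, `fy`, `fz`, and `mas_weight`.
#' @export
source_state <- function(protocol, s, isocenter = c(0, 0)) {
  stopifnot(all(s >= 0 & s < 1))
  ze <- emission_range(protocol)
  z <- ze$z_start + s * z_length(ze)
  angle <- 2 * pi * s * n_rotations(protocol)
  fid <- protocol$focus_isocenter_distance
  tibble::tibble(
    s = s, z = z, angle = angle,
    fx = isocenter[1] + fid * cos(angle),
    fy = isocenter[2] + fid * sin(angle),
    fz = z,
    mas_weight = tcm_weight(protocol, z))
}

#' Sample photon emissions from the helical source
#'
#' Draws photon origins, directions, energies and statistical weights for
#' the helical trajectory: s uniform over the exposed range, fan angle
#' uniform across the full fan, cone angle uniform within
#' collimation / (2 FID), energy from the spectrum. The bowtie filter is
#' applied as a multiplicative weight \eqn{e^{-\mu_{Al}(E) t(\gamma)}}
#' rather than by rejection, which has the same expectation at lower
#' variance; the tube-current weight multiplies in as well.
#'
#' @param protocol A `voxdose_protocol`.
#' @param spec A `voxdose_spectrum`.
#' @param bowtie A `voxdose_bowtie` or `NULL` for no bowtie.
#' @param n Number of photons.
#' @param atten Attenuation table (needed when a bowtie is given).
#' @param isocenter (x, y) of the rotation axis, mm.
#' @return Tibble with origin (`x`, `y`, `z`), unit direction (`ux`, `uy`,
#'   `uz`), `energy_kev`, `weight`, and the emission table position
#'   `z_table`.
#' @export
sample_emission <- function(protocol, spec, bowtie = NULL, n,
                            atten = NULL, isocenter = c(0, 0)) {
  if (!is.null(bowtie) && is.null(atten)) {
    stop("atten is required when a bowtie model is given")
  }
  st <- source_state(protocol, stats::runif(n), isocenter)
  gamma <- stats::runif(n, -protocol$fan_angle / 2, protocol$fan_angle / 2)
  psi_max <- protocol$collimation / (2 * protocol$focus_isocenter_distance)
  psi <- stats::runif(n, -psi_max, psi_max)
  energy <- sample(spec$energy_kev, n, replace = TRUE, prob = spec$weight)

  # central direction points from the focal spot to the isocenter; the fan
  # offset rotates it in-plane, the cone offset tilts it along z
  ca <- cos(st$angle + pi)  # unit vector focal spot -> isocenter
  sa <- sin(st$angle + pi)
  ux <- ca * cos(gamma) - sa * sin(gamma)
  uy <- sa * cos(gamma) + ca * sin(gamma)
  uz <- tan(psi)
  nrm <- sqrt(ux^2 + uy^2 + uz^2)

  w <- st$mas_weight
  if (!is.null(bowtie)) {
    t_mm <- bowtie_thickness(bowtie, gamma)
    w <- w * exp(-mu_al_linear(atten, energy) * t_mm)
  }
  tibble::tibble(x = st$fx, y = st$fy, z = st$fz,
                 ux = ux / nrm, uy = uy / nrm, uz = uz / nrm,
                 energy_kev = energy, weight = w, z_table = st$z)
}

#' Typical mean tube current-time products for absolute-dose reporting
#'
#' Doses are computed normalised to the mean mAs; multiplying by a mean
#' tube current-time product (over 100) gives absolute organ doses. These
#' defaults are typical diagnostic values for the two protocols.
#'
#' @param protocol_name `"chest"` or `"cardiac"`.
#' @return Mean mAs (141 for chest, 112 for cardiac).
#' @export
default_mean_mas <- function(protocol_name = c("chest", "cardiac")) {
  c(chest = 141, cardiac = 112)[[match.arg(protocol_name)]]
}

#' Synthesise a tube-current-modulation table from body attenuation
#'
#' Longitudinal TCM proportional to the water-equivalent area of each slice
#' (the attenuation-following behaviour of clinical modulation), scaled to
#' a given mean mAs. Angular modulation is not modelled: per-slice values
#' are treated as angular averages.
#'
#' @param model A `voxdose_model`.
#' @param mean_mas Mean tube current-time product over the model, mAs.
#' @param floor_frac Lower bound on modulation as a fraction of the mean.
#' @return A tibble with columns `z` and `mas`, one row per slice.
#' @export
synthesise_tcm <- function(model, mean_mas = 100, floor_frac = 0.3) {
  nz <- dim(model$hu)[3]
  dz <- model$spacing[3]
  apix <- model$spacing[1] * model$spacing[2]
  aw <- vapply(seq_len(nz), function(k) {
    sl <- model$hu[, , k]
    body <- sl > -950
    if (!any(body)) return(0) else sum((sl[body] / 1000 + 1) * apix)
  }, numeric(1))
  mas <- pmax(aw, floor_frac * mean(aw[aw > 0]))
  mas <- mas / mean(mas) * mean_mas
  tibble::tibble(z = model$origin[3] + (seq_len(nz) - 0.5) * dz, mas = mas)
}
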