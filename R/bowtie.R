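#' Fit a bowtie filter model from a lateral air-kerma profile
#'
#' A bowtie filter is characterised by moving a dosimeter laterally from the
#' isocenter with the tube stationary and recording relative air kerma at
#' each position. Each lateral distance d maps to a fan angle
#' \eqn{\gamma = \arctan(d / \mathrm{FID})}; the equivalent aluminium
#' thickness at that angle is the thickness that attenuates the spectrum's
#' air kerma to the measured relative value, solved by bisection. Between
#' measured angles the thickness is interpolated linearly; a one-sided
#' profile is completed symmetrically.
#'
#' @param profile Data frame with columns `distance_cm` (lateral distance
#'   from the isocenter, may be one-sided) and `relative_kerma` (in (0, 1],
#'   1 at the isocenter).
#' @param geometry A [scan_protocol()] (only `focus_isocenter_distance` is
#'   used).
#' @param spec Spectrum the measurement was made with.
#' @param atten Attenuation table.
#' @return A `voxdose_bowtie`: tibble of `gamma` (rad, signed) and
#'   `thickness_mm` equivalent aluminium, zero at the central ray.
#' @export
bowtie_from_profile <- function(profile, geometry, spec, atten) {
  stopifnot(all(c("distance_cm", "relative_kerma") %in% names(profile)))
  if (!any(profile$distance_cm == 0)) {
    stop("profile must contain the isocenter point (distance 0)")
  }
  k0 <- profile$relative_kerma[match(0, profile$distance_cm)]
  rel <- profile$relative_kerma / k0
  if (any(rel <= 0) || any(rel > 1 + 1e-9)) {
    stop("relative kerma must lie in (0, 1] after normalisation to the central ray")
  }
  rel <- pmin(rel, 1)
  fid <- geometry$focus_isocenter_distance
  gamma <- atan(profile$distance_cm * 10 / fid)

  kerma0 <- kerma_behind_al(spec, atten, 0)
  solve_t <- function(target) {
    if (target >= 1) return(0)
    f <- function(t) kerma_behind_al(spec, atten, t) / kerma0 - target
    lo <- 0
    hi <- 1
    while (f(hi) > 0 && hi < 2000) hi <- hi * 2
    if (f(hi) > 0) stop("bowtie thickness out of range for relative kerma ", target)
    for (i in seq_len(200)) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) lo <- mid else hi <- mid
      if (hi - lo < 1e-5) break
    }
    (lo + hi) / 2
  }
  t_mm <- vapply(rel, solve_t, numeric(1))

  tab <- tibble::tibble(gamma = gamma, thickness_mm = t_mm)
  if (all(gamma >= 0)) {  # symmetric completion
    mirror <- tab[tab$gamma > 0, ]
    mirror$gamma <- -mirror$gamma
    tab <- rbind(mirror, tab)
  }
  tab <- tab[order(tab$gamma), ]
  structure(tab, class = c("voxdose_bowtie", class(tibble::tibble())))
}

#' A bowtie model with no filtration (flat profile)
#' @return A `voxdose_bowtie` with zero thickness everywhere.
#' @export
flat_bowtie <- function() {
  structure(tibble::tibble(gamma = c(-1, 0, 1), thickness_mm = 0),
            class = c("voxdose_bowtie", class(tibble::tibble())))
}

#' Equivalent aluminium thickness of a bowtie model at given fan angles
#'
#' @param bowtie A `voxdose_bowtie`.
#' @param gamma Fan angles, rad (signed). Angles beyond the measured range
#'   are clamped to the outermost measured thickness.
#' @return Thickness in mm of aluminium.
#' @export
bowtie_thickness <- function(bowtie, gamma) {
  stats::approx(bowtie$gamma, bowtie$thickness_mm, xout = gamma,
                rule = 2)$y
}

#' Re-evaluate the lateral kerma profile a bowtie model implies
#'
#' Forward model for checking a fit: the relative air kerma a stationary
#' measurement would see at each lateral distance.
#'
#' @inheritParams bowtie_from_profile
#' @param bowtie A fitted `voxdose_bowtie`.
#' @param distance_cm Lateral distances to evaluate at.
#' @return Tibble of `distance_cm` and `relative_kerma`.
#' @export
bowtie_profile <- function(bowtie, geometry, spec, atten, distance_cm) {
  gamma <- atan(distance_cm * 10 / geometry$focus_isocenter_distance)
  t_mm <- bowtie_thickness(bowtie, gamma)
  k0 <- kerma_behind_al(spec, atten, 0)
  rel <- vapply(t_mm, function(t) kerma_behind_al(spec, atten, t) / k0,
                numeric(1))
  tibble::tibble(distance_cm = distance_cm, relative_kerma = rel)
}
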