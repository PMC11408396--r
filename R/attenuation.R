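#' Photon attenuation data for the simulation materials
#'
#' Loads the bundled table of mass attenuation (\eqn{\mu/\rho}) and mass
#' energy-absorption (\eqn{\mu_{en}/\rho}) coefficients together with partial
#' interaction fractions (photoelectric / Compton / Rayleigh) for the six
#' simulation materials: air, water, lung, soft tissue, cortical bone and
#' aluminium. Values are tabulated at standard reference energies between 10
#' and 150 keV and interpolated log-log onto a uniform 1 keV grid, the working
#' resolution of the transport engine.
#'
#' @param path Optional path to a CSV with columns `material`, `energy_kev`,
#'   `mu_rho`, `muen_rho`, `f_photoelectric`, `f_compton`, `f_rayleigh`.
#'   Defaults to the table bundled with the package.
#' @return An object of class `voxdose_atten`: a list with the energy grid
#'   (keV) and, per material, interpolated coefficient vectors.
#' @export
#' @examples
#' atten <- attenuation_table()
#' mu_over_rho(atten, "water", 60)
attenuation_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "attenuation.csv", package = "voxdose")
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("material", "energy_kev", "mu_rho", "muen_rho",
              "f_photoelectric", "f_compton", "f_rayleigh")
  if (!all(needed %in% names(raw))) {
    stop("attenuation table is missing columns: ",
         paste(setdiff(needed, names(raw)), collapse = ", "))
  }
  grid <- seq(10, 150, by = 1)
  mats <- unique(raw$material)
  per_mat <- lapply(mats, function(m) {
    d <- raw[raw$material == m, ]
    d <- d[order(d$energy_kev), ]
    loglog <- function(y) {
      exp(stats::approx(log(d$energy_kev), log(y), xout = log(grid),
                        rule = 2)$y)
    }
    lin <- function(y) {
      stats::approx(d$energy_kev, y, xout = grid, rule = 2)$y
    }
    f_pe <- lin(d$f_photoelectric)
    f_co <- lin(d$f_compton)
    f_ra <- lin(d$f_rayleigh)
    tot <- f_pe + f_co + f_ra
    list(mu_rho = loglog(d$mu_rho),
         muen_rho = loglog(d$muen_rho),
         f_photoelectric = f_pe / tot,
         f_compton = f_co / tot,
         f_rayleigh = f_ra / tot)
  })
  names(per_mat) <- mats
  structure(list(energies = grid, materials = mats, tables = per_mat),
            class = "voxdose_atten")
}

#' @export
print.voxdose_atten <- function(x, ...) {
  cat("<voxdose_atten> materials:", paste(x$materials, collapse = ", "),
      sprintf("| %d-%d keV at 1 keV\n", min(x$energies), max(x$energies)))
  invisible(x)
}

atten_lookup <- function(atten, material, energy, what) {
  if (!material %in% atten$materials) {
    stop("unknown material: ", material)
  }
  if (any(energy < min(atten$energies) | energy > max(atten$energies))) {
    stop("energy outside tabulated range ", min(atten$energies), "-",
         max(atten$energies), " keV")
  }
  stats::approx(atten$energies, atten$tables[[material]][[what]],
                xout = energy, rule = 2)$y
}

#' Interpolated attenuation coefficients
#'
#' @param atten An attenuation table from [attenuation_table()].
#' @param material One of the table's materials (e.g. `"water"`,
#'   `"aluminium"`).
#' @param energy Photon energy (keV), may be a vector; must lie within the
#'   tabulated 10-150 keV range.
#' @return Mass attenuation or mass energy-absorption coefficient
#'   (\ifelse{html}{\out{cm<sup>2</sup>/g}}{cm^2/g}).
#' @export
mu_over_rho <- function(atten, material, energy) {
  atten_lookup(atten, material, energy, "mu_rho")
}

#' @rdname mu_over_rho
#' @export
muen_over_rho <- function(atten, material, energy) {
  atten_lookup(atten, material, energy, "muen_rho")
}

#' Partial interaction fractions at a given energy
#'
#' @inheritParams mu_over_rho
#' @return A tibble with columns `process` and `fraction`, summing to 1.
#' @export
interaction_fractions <- function(atten, material, energy) {
  f <- c(photoelectric = atten_lookup(atten, material, energy, "f_photoelectric"),
         compton = atten_lookup(atten, material, energy, "f_compton"),
         rayleigh = atten_lookup(atten, material, energy, "f_rayleigh"))
  tibble::tibble(process = names(f), fraction = unname(f / sum(f)))
}

# linear attenuation coefficient of aluminium, 1/mm
mu_al_linear <- function(atten, energy) {
  mu_over_rho(atten, "aluminium", energy) * 2.699 / 10
}
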