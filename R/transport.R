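# eV per gram -> mGy (1 eV = 1.602176634e-19 J; per g = x1e3 per kg; Gy -> mGy x1e3)
EV_PER_G_TO_MGY <- 1.602176634e-19 * 1e3 * 1e3

# attenuation tables for the four voxel material classes as nE x 4 matrices
# in class order air, lung, soft tissue, bone
class_tables <- function(atten) {
  cls <- c("air", "lung", "soft_tissue", "bone")
  get <- function(what) {
    vapply(cls, function(m) atten$tables[[m]][[what]],
           numeric(length(atten$energies)))
  }
  list(energies = atten$energies,
       mu_rho = get("mu_rho"),
       f_pe = get("f_photoelectric"),
       f_ray = get("f_rayleigh"))
}

#' Sample a photon interaction type
#'
#' Draws photoelectric / Compton / Rayleigh proportional to the partial
#' cross sections of the material at the interpolated energy.
#'
#' @param energy Photon energy, keV (within the tabulated 10-150 keV).
#' @param material Material name in the attenuation table.
#' @param atten Attenuation table.
#' @param n Number of draws.
#' @return Character vector of interaction types.
#' @export
sample_interaction <- function(energy, material, atten, n = 1) {
  f <- interaction_fractions(atten, material, energy)
  sample(f$process, n, replace = TRUE, prob = f$fraction)
}

#' Sample Compton scattering from the Klein-Nishina cross section
#'
#' Free-electron Klein-Nishina angular sampling (rejection method); the
#' scattered energy follows the Compton relation
#' \eqn{E' = E / (1 + (E/511)(1 - \cos\theta))}.
#'
#' @param energy Incident photon energy, keV.
#' @param n Number of samples.
#' @return Tibble with `cos_theta` and `energy_kev` (scattered).
#' @export
sample_compton <- function(energy, n = 1) {
  stopifnot(energy > 0)
  s <- cpp_sample_compton(as.integer(n), energy)
  tibble::tibble(cos_theta = s$cos_theta, energy_kev = s$energy_kev)
}

#' Transport a single photon through a material grid
#'
#' Woodcock delta tracking with the grid-wide majorant attenuation.
#' Photoelectric absorption deposits the remaining energy locally; Compton
#' scattering deposits the energy transferred and continues with the
#' scattered photon; Rayleigh scattering only changes direction. Histories
#' end on grid exit or below the energy cutoff (depositing the remainder).
#'
#' @param photon A list or one-row data frame with `x`, `y`, `z` (mm),
#'   `ux`, `uy`, `uz` (unit direction), `energy_kev`, and optionally
#'   `weight` (default 1).
#' @param matgrid A `voxdose_materials` from [hu_to_materials()].
#' @param atten Attenuation table.
#' @param energy_cutoff keV; default 10.
#' @return Tibble of deposits (`voxel` 1-based linear index, `energy_kev`
#'   weighted) with attribute `n_interactions`.
#' @export
transport_photon <- function(photon, matgrid, atten, energy_cutoff = 10) {
  stopifnot(inherits(matgrid, "voxdose_materials"))
  tabs <- class_tables(atten)
  w <- if (is.null(photon$weight)) 1 else photon$weight
  res <- cpp_transport_one(
    c(photon$x, photon$y, photon$z), c(photon$ux, photon$uy, photon$uz),
    photon$energy_kev, w,
    as.numeric(matgrid$density) / 1000,  # kg/m^3 -> g/cm^3
    as.integer(matgrid$class), dim(matgrid$class),
    matgrid$spacing, matgrid$origin,
    tabs$mu_rho, tabs$f_pe, tabs$f_ray,
    tabs$energies[1], tabs$energies[2] - tabs$energies[1], energy_cutoff)
  out <- tibble::tibble(voxel = res$voxel, energy_kev = res$energy_kev)
  attr(out, "n_interactions") <- res$n_interactions
  out
}

new_dose_grid <- function(dose, uncertainty, spacing, origin, n_photons,
                          seed = NA_integer_, unit = "eV/g per photon") {
  structure(list(dose = dose, uncertainty = uncertainty, spacing = spacing,
                 origin = origin, n_photons = n_photons, seed = seed,
                 unit = unit),
            class = "voxdose_dose")
}

#' @export
print.voxdose_dose <- function(x, ...) {
  d <- dim(x$dose)
  cat(sprintf(
    "<dose grid> %dx%dx%d [%s], %g photons, mean rel. uncertainty %.3f\n",
    d[1], d[2], d[3], x$unit, x$n_photons,
    mean(x$uncertainty[x$dose > 0], na.rm = TRUE)))
  invisible(x)
}

# core engine: transports a photon budget in batches and returns one raw
# dose accumulator (eV/g per photon) per emission tag. tag_fun maps the
# emission table position (mm) to an integer tag in 1..ntags.
mc_engine <- function(matgrid, protocol, spec, bowtie, atten,
                      n_photons, n_batches = 10, energy_cutoff = 10,
                      tag_fun = NULL, ntags = 1, chunk = 1e5) {
  stopifnot(inherits(matgrid, "voxdose_materials"))
  if (n_photons <= 0) stop("photon budget must be positive")
  tabs <- class_tables(atten)
  dims <- dim(matgrid$class)
  # rotation axis through the grid centre in xy
  iso <- c(matgrid$origin[1] + dims[1] * matgrid$spacing[1] / 2,
           matgrid$origin[2] + dims[2] * matgrid$spacing[2] / 2)
  dens <- as.numeric(matgrid$density) / 1000
  clsv <- as.integer(matgrid$class)
  voxvol_cm3 <- prod(matgrid$spacing) / 1000
  mass_g <- dens * voxvol_cm3
  nvox <- prod(dims)

  sum1 <- vector("list", ntags)
  sum2 <- vector("list", ntags)
  for (t in seq_len(ntags)) {
    sum1[[t]] <- numeric(nvox)
    sum2[[t]] <- numeric(nvox)
  }
  per_batch <- ceiling(n_photons / n_batches)
  stream_seed <- abs(as.numeric(protocol$seed)) %% 2^31
  counter <- 0
  for (b in seq_len(n_batches)) {
    acc <- lapply(seq_len(ntags), function(t) numeric(nvox))
    left <- per_batch
    while (left > 0) {
      m <- min(chunk, left)
      left <- left - m
      ph <- sample_emission(protocol, spec, bowtie, m, atten, iso)
      tag <- if (is.null(tag_fun)) rep(1L, m) else as.integer(tag_fun(ph$z_table))
      dep <- cpp_transport_batch(
        cbind(ph$x, ph$y, ph$z), cbind(ph$ux, ph$uy, ph$uz),
        ph$energy_kev, ph$weight, tag - 1L, as.integer(ntags),
        dens, clsv, dims, matgrid$spacing, matgrid$origin,
        tabs$mu_rho, tabs$f_pe, tabs$f_ray,
        tabs$energies[1], tabs$energies[2] - tabs$energies[1],
        energy_cutoff, stream_seed, counter)
      counter <- counter + m
      for (t in seq_len(ntags)) acc[[t]] <- acc[[t]] + dep[[t]]
    }
    for (t in seq_len(ntags)) {
      bd <- acc[[t]] * 1000 / mass_g / per_batch  # keV -> eV, per photon
      sum1[[t]] <- sum1[[t]] + bd
      sum2[[t]] <- sum2[[t]] + bd^2
    }
  }
  lapply(seq_len(ntags), function(t) {
    mean_d <- sum1[[t]] / n_batches
    var_d <- pmax(sum2[[t]] / n_batches - mean_d^2, 0) / max(n_batches - 1, 1)
    rel <- sqrt(var_d) / ifelse(mean_d > 0, mean_d, NA_real_)
    new_dose_grid(array(mean_d, dims), array(rel, dims),
                  matgrid$spacing, matgrid$origin,
                  n_photons = per_batch * n_batches, seed = protocol$seed)
  })
}

#' Run a Monte Carlo CT dose simulation
#'
#' Simulates the helical exposure defined by the protocol on the voxel
#' model and scores per-voxel absorbed dose in raw units of eV/g per source
#' photon, with relative standard errors from batch statistics. Calibrate
#' to mGy per 100 mAs with [calibrate()]. Reproducible: call `set.seed()`
#' first; identical seeds and budgets give identical grids.
#'
#' @param model A `voxdose_model`.
#' @param protocol A `voxdose_protocol` (its `photon_budget` is used unless
#'   `n_photons` is given).
#' @param spec A `voxdose_spectrum`.
#' @param bowtie A `voxdose_bowtie` or `NULL`.
#' @param atten Attenuation table.
#' @param n_photons Photon histories (default `protocol$photon_budget`).
#' @param n_batches Batches for uncertainty estimation (default 10).
#' @param energy_cutoff keV (default 10).
#' @return A `voxdose_dose` grid.
#' @export
run_simulation <- function(model, protocol, spec, bowtie = NULL, atten,
                           n_photons = NULL, n_batches = 10,
                           energy_cutoff = 10) {
  matgrid <- hu_to_materials(model)
  if (is.null(n_photons)) n_photons <- protocol$photon_budget
  mc_engine(matgrid, protocol, spec, bowtie, atten, n_photons, n_batches,
            energy_cutoff)[[1]]
}

#' Simulated air kerma free-in-air at the isocenter
#'
#' One axial rotation with no phantom: photons travel in straight lines,
#' and the kerma in a small spherical scoring cell at the isocenter is
#' estimated with a track-length estimator,
#' \eqn{K = \sum w E (\mu_{en}/\rho)_{air} L / V}. This is the quantity the
#' dosimetric calibration of the simulation is based on.
#'
#' @param protocol A `voxdose_protocol` (its scan range is ignored; the
#'   tube circles the isocenter in one plane).
#' @param spec A `voxdose_spectrum`.
#' @param atten Attenuation table.
#' @param n_photons Number of sampled emissions.
#' @param bowtie Optional `voxdose_bowtie` (a physical measurement sees the
#'   bowtie; the central ray is unattenuated either way).
#' @param cell_radius Scoring sphere radius, mm (default 5).
#' @param cell_center Scoring cell centre, mm (default the isocenter,
#'   `c(0, 0, 0)`); moving it along the central ray exposes the
#'   inverse-square falloff.
#' @return Kerma per source photon, mGy.
#' @export
air_kerma_free_in_air <- function(protocol, spec, atten, n_photons = 1e5,
                                  bowtie = NULL, cell_radius = 5,
                                  cell_center = c(0, 0, 0)) {
  axial <- protocol
  axial$tcm <- NULL  # kerma measured at constant tube current
  st_s <- stats::runif(n_photons)
  angle <- 2 * pi * st_s
  fid <- protocol$focus_isocenter_distance
  gamma <- stats::runif(n_photons, -protocol$fan_angle / 2,
                        protocol$fan_angle / 2)
  psi_max <- protocol$collimation / (2 * fid)
  psi <- stats::runif(n_photons, -psi_max, psi_max)
  energy <- sample(spec$energy_kev, n_photons, replace = TRUE,
                   prob = spec$weight)
  w <- rep(1, n_photons)
  if (!is.null(bowtie)) {
    w <- exp(-mu_al_linear(atten, energy) * bowtie_thickness(bowtie, gamma))
  }
  # focal spot on a circle in the z = 0 plane around the isocenter
  fx <- fid * cos(angle); fy <- fid * sin(angle); fz <- 0
  ca <- cos(angle + pi); sa <- sin(angle + pi)
  ux <- ca * cos(gamma) - sa * sin(gamma)
  uy <- sa * cos(gamma) + ca * sin(gamma)
  uz <- tan(psi)
  nrm <- sqrt(ux^2 + uy^2 + uz^2)
  ux <- ux / nrm; uy <- uy / nrm; uz <- uz / nrm
  # chord length of the ray through the scoring sphere
  fx <- fx - cell_center[1]; fy <- fy - cell_center[2]
  fz <- fz - cell_center[3]
  b <- fx * ux + fy * uy + fz * uz
  c0 <- fx^2 + fy^2 + fz^2 - cell_radius^2
  disc <- b^2 - c0
  hit <- disc > 0 & -b > 0
  if (!any(hit)) stop("no sampled photon crossed the scoring cell")
  chord_mm <- 2 * sqrt(disc[hit])
  muen <- muen_over_rho(atten, "air", energy[hit])          # cm^2/g
  vol_cm3 <- 4 / 3 * pi * (cell_radius / 10)^3
  kev_per_g <- sum(w[hit] * energy[hit] * muen * (chord_mm / 10)) / vol_cm3
  kev_per_g / n_photons * 1000 * EV_PER_G_TO_MGY
}

#' Dosimetric calibration of a raw dose grid
#'
#' The simulation scores dose per source photon; the scanner's measured air
#' kerma free-in-air at the isocenter (per 100 mAs) fixes the number of
#' photons a real exposure corresponds to. `calibration_factor()` forms the
#' scale from the measured kerma and the simulated kerma-per-photon;
#' `calibrate()` applies it linearly to every voxel.
#'
#' @param measured_air_kerma Measured air kerma free-in-air at the
#'   isocenter, mGy per 100 mAs.
#' @param simulated_kerma Simulated kerma per source photon, mGy (from
#'   [air_kerma_free_in_air()]).
#' @return A `voxdose_calibration` (list with `scale` and the inputs).
#' @export
calibration_factor <- function(measured_air_kerma, simulated_kerma) {
  if (measured_air_kerma <= 0 || simulated_kerma <= 0) {
    stop("kerma values must be positive")
  }
  structure(list(scale = measured_air_kerma / simulated_kerma,
                 measured_air_kerma = measured_air_kerma,
                 simulated_kerma = simulated_kerma),
            class = "voxdose_calibration")
}

#' @rdname calibration_factor
#' @param raw A raw `voxdose_dose` grid (eV/g per photon).
#' @param cal A `voxdose_calibration`, or a single positive scale factor.
#' @return `calibrate()`: the dose grid scaled voxelwise (relative
#'   uncertainties unchanged).
#' @export
calibrate <- function(raw, cal) {
  stopifnot(inherits(raw, "voxdose_dose"))
  scale <- if (inherits(cal, "voxdose_calibration")) cal$scale else cal
  if (!is.numeric(scale) || length(scale) != 1 || !is.finite(scale) ||
      scale <= 0) {
    stop("calibration scale must be a single positive number")
  }
  out <- raw
  out$dose <- raw$dose * scale
  out$unit <- "mGy per 100 mAs"
  out
}
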