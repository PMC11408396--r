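#' Tabulated x-ray tube spectra
#'
#' Returns a bundled tungsten-anode spectrum for one of the supported tube
#' voltages. The bundled spectra are synthetic (Kramers' bremsstrahlung with
#' inherent aluminium filtration and tungsten K lines) and serve as the base
#' for half-value-layer matching with [equivalent_spectrum()]: the base shape
#' matters much less than the HVL the hardened spectrum is tuned to.
#'
#' @param tube_kv Tube voltage in kV; one of 80, 100, 120, 140.
#' @return A `voxdose_spectrum`: a tibble with columns `energy_kev` and
#'   `weight` (relative photon fluence per 1 keV bin, normalised to sum 1).
#' @export
#' @examples
#' s <- base_spectrum(120)
#' mean_energy(s)
base_spectrum <- function(tube_kv) {
  supported <- c(80, 100, 120, 140)
  if (length(tube_kv) != 1 || !tube_kv %in% supported) {
    stop("unsupported tube voltage: ", tube_kv,
         " (bundled spectra: ", paste(supported, collapse = ", "), " kV)")
  }
  path <- system.file("extdata", sprintf("spectrum_%dkv.csv", tube_kv),
                      package = "voxdose")
  d <- utils::read.csv(path)
  new_spectrum(d$energy_kev, d$weight)
}

new_spectrum <- function(energies, weights) {
  if (any(weights < 0) || sum(weights) <= 0) {
    stop("spectrum weights must be non-negative with positive sum")
  }
  out <- tibble::tibble(energy_kev = energies, weight = weights / sum(weights))
  class(out) <- c("voxdose_spectrum", class(out))
  out
}

#' Mean energy of a spectrum
#' @param spec A `voxdose_spectrum`.
#' @return Fluence-weighted mean photon energy, keV.
#' @export
mean_energy <- function(spec) {
  sum(spec$energy_kev * spec$weight) / sum(spec$weight)
}

# air kerma per fluence for a spectrum behind t mm of aluminium
# (relative units: sum w * E * muen/rho_air * exp(-mu_Al t))
kerma_behind_al <- function(spec, atten, t_mm) {
  muen <- muen_over_rho(atten, "air", spec$energy_kev)
  mual <- mu_al_linear(atten, spec$energy_kev)
  sum(spec$weight * spec$energy_kev * muen * exp(-mual * t_mm))
}

#' First half-value layer of a spectrum
#'
#' Aluminium thickness that halves the air kerma of the beam,
#' \eqn{K(t) = \sum_E w(E) E (\mu_{en}/\rho)_{air}(E) e^{-\mu_{Al}(E) t}},
#' solved by bisection to \eqn{10^{-4}} mm.
#'
#' @param spec A `voxdose_spectrum`.
#' @param atten An attenuation table from [attenuation_table()].
#' @return HVL in mm of aluminium.
#' @export
compute_hvl <- function(spec, atten) {
  if (nrow(spec) == 0 || sum(spec$weight) <= 0) stop("empty spectrum")
  k0 <- kerma_behind_al(spec, atten, 0)
  target <- function(t) kerma_behind_al(spec, atten, t) / k0 - 0.5
  lo <- 0
  hi <- 1
  while (target(hi) > 0 && hi < 1000) hi <- hi * 2
  if (target(hi) > 0) stop("HVL bisection failed to bracket")
  for (i in seq_len(200)) {
    mid <- (lo + hi) / 2
    if (target(mid) > 0) lo <- mid else hi <- mid
    if (hi - lo < 1e-4) return((lo + hi) / 2)
  }
  stop("HVL bisection did not converge in 200 iterations")
}

#' Harden a spectrum to a target first half-value layer
#'
#' Adds the virtual aluminium filtration (weights multiplied by
#' \eqn{e^{-\mu_{Al}(E) x}}) that brings the spectrum's first HVL to the
#' measured target, the standard way of building an equivalent CT spectrum
#' from a half-value-layer measurement.
#'
#' @param base Base spectrum, e.g. from [base_spectrum()].
#' @param target_hvl Measured first HVL, mm Al. Must not be below the base
#'   spectrum's own HVL (filtration can only harden).
#' @param atten Attenuation table.
#' @param tol Relative tolerance on the achieved HVL (default 0.5%).
#' @return A `voxdose_spectrum` with attribute `added_filtration_mm`.
#' @export
equivalent_spectrum <- function(base, target_hvl, atten, tol = 0.005) {
  hvl0 <- compute_hvl(base, atten)
  if (target_hvl < hvl0 * (1 - 1e-9)) {
    stop(sprintf(
      "target HVL %.3f mm Al is below the base spectrum's %.3f mm Al; %s",
      target_hvl, hvl0, "filtration cannot soften a beam"))
  }
  harden <- function(x) {
    mual <- mu_al_linear(atten, base$energy_kev)
    new_spectrum(base$energy_kev, base$weight * exp(-mual * x))
  }
  if (target_hvl <= hvl0 * (1 + 1e-9)) {
    out <- base
    attr(out, "added_filtration_mm") <- 0
    return(out)
  }
  f <- function(x) compute_hvl(harden(x), atten) - target_hvl
  lo <- 0
  hi <- 1
  while (f(hi) < 0 && hi < 500) hi <- hi * 2
  if (f(hi) < 0) stop("cannot reach target HVL with aluminium filtration")
  for (i in seq_len(200)) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
    if (abs(compute_hvl(harden(mid), atten) - target_hvl) / target_hvl < tol) {
      out <- harden(mid)
      attr(out, "added_filtration_mm") <- mid
      return(out)
    }
  }
  stop("equivalent-spectrum bisection did not converge")
}
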