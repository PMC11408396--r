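# Regenerates the bundled physics fixtures under inst/extdata/.
#
# attenuation.csv — per-material photon interaction coefficients, 10-150 keV.
#   Total mass attenuation (mu_rho) and mass energy-absorption (muen_rho)
#   coefficients are hand-tabulated from the standard NIST XCOM / ICRU
#   reference tables at the usual grid energies. The incoherent component is
#   computed from the Klein-Nishina per-electron cross section times
#   electrons per gram; the coherent component is tabulated approximately;
#   the photoelectric component is total minus the two (clamped at zero), so
#   partial interaction fractions are self-consistent with the totals.
#
# spectrum_*kv.csv — synthetic tungsten-anode bremsstrahlung spectra at 1 keV
#   resolution (Kramers' model filtered by inherent aluminium, plus tungsten
#   K lines above 70 kV). These are generic spectra, not measurements of any
#   particular scanner; the package hardens them to a target half-value layer
#   at run time.

kn_sigma <- function(E_keV) {
  # Klein-Nishina total cross section per electron, cm^2
  k <- E_keV / 511
  re2 <- 7.940787e-26  # classical electron radius squared, cm^2
  2 * pi * re2 * ((1 + k) / k^2 * (2 * (1 + k) / (1 + 2 * k) - log(1 + 2 * k) / k) +
                    log(1 + 2 * k) / (2 * k) - (1 + 3 * k) / (1 + 2 * k)^2)
}

NA_AVOGADRO <- 6.02214076e23

energies <- c(10, 15, 20, 30, 40, 50, 60, 80, 100, 150)

# NIST total mass attenuation / mass energy-absorption coefficients, cm^2/g
nist <- list(
  air = list(
    za = 0.49919,
    mu   = c(5.120, 1.614, 0.7779, 0.3538, 0.2485, 0.2080, 0.1875, 0.1662, 0.1541, 0.1356),
    muen = c(4.742, 1.334, 0.5389, 0.1537, 0.06833, 0.04098, 0.03041, 0.02407, 0.02325, 0.02496),
    coh  = c(0.55, 0.30, 0.19, 0.095, 0.060, 0.042, 0.032, 0.020, 0.0135, 0.0070)
  ),
  water = list(
    za = 0.55509,
    mu   = c(5.329, 1.673, 0.8096, 0.3756, 0.2683, 0.2269, 0.2059, 0.1837, 0.1707, 0.1505),
    muen = c(4.944, 1.374, 0.5503, 0.1557, 0.06947, 0.04223, 0.03190, 0.02597, 0.02546, 0.02764),
    coh  = c(0.62, 0.34, 0.215, 0.108, 0.068, 0.048, 0.0365, 0.0230, 0.0155, 0.0080)
  ),
  lung = list(  # ICRU-44 lung tissue (composition; density handled separately)
    za = 0.55048,
    mu   = c(5.346, 1.682, 0.8146, 0.3779, 0.2696, 0.2279, 0.2067, 0.1844, 0.1713, 0.1510),
    muen = c(4.963, 1.383, 0.5539, 0.1566, 0.06978, 0.04237, 0.03198, 0.02601, 0.02548, 0.02766),
    coh  = c(0.62, 0.34, 0.215, 0.108, 0.068, 0.048, 0.0365, 0.0230, 0.0155, 0.0080)
  ),
  soft_tissue = list(  # ICRU-44 soft tissue
    za = 0.54996,
    mu   = c(5.379, 1.693, 0.8205, 0.3783, 0.2694, 0.2276, 0.2064, 0.1841, 0.1710, 0.1508),
    muen = c(4.987, 1.388, 0.5550, 0.1565, 0.06962, 0.04227, 0.03192, 0.02599, 0.02547, 0.02765),
    coh  = c(0.62, 0.34, 0.215, 0.108, 0.068, 0.048, 0.0365, 0.0230, 0.0155, 0.0080)
  ),
  bone = list(  # ICRU-44 cortical bone
    za = 0.51478,
    mu   = c(28.51, 9.032, 4.001, 1.331, 0.6655, 0.4242, 0.3148, 0.2229, 0.1855, 0.1480),
    muen = c(26.80, 8.388, 3.601, 1.070, 0.4507, 0.2336, 0.1400, 0.06896, 0.04585, 0.03183),
    coh  = c(1.95, 1.05, 0.66, 0.330, 0.205, 0.143, 0.107, 0.066, 0.044, 0.022)
  ),
  aluminium = list(
    za = 0.48181,
    mu   = c(26.23, 7.955, 3.441, 1.128, 0.5685, 0.3681, 0.2778, 0.2018, 0.1704, 0.1378),
    muen = c(25.43, 7.487, 3.094, 0.8778, 0.3601, 0.1840, 0.1099, 0.05511, 0.03794, 0.02827),
    coh  = c(1.70, 0.92, 0.58, 0.290, 0.180, 0.126, 0.094, 0.058, 0.039, 0.019)
  )
)

rows <- lapply(names(nist), function(m) {
  x <- nist[[m]]
  inc <- kn_sigma(energies) * NA_AVOGADRO * x$za       # incoherent, cm^2/g
  coh <- pmin(x$coh, 0.45 * x$mu)                      # keep coherent subdominant
  pe <- pmax(x$mu - inc - coh, 0)
  tot <- pe + inc + coh
  data.frame(material = m, energy_kev = energies,
             mu_rho = x$mu, muen_rho = x$muen,
             f_photoelectric = pe / tot,
             f_compton = inc / tot,
             f_rayleigh = coh / tot)
})
atten <- do.call(rbind, rows)
dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
write.csv(format(atten, digits = 6, trim = TRUE),
          "inst/extdata/attenuation.csv", row.names = FALSE, quote = FALSE)

# --- spectra ---------------------------------------------------------------
mu_al <- splinefun(log(energies), log(nist$aluminium$mu))
mu_al_of <- function(E) exp(mu_al(log(E)))  # cm^2/g
RHO_AL <- 2.699  # g/cm^3

make_spectrum <- function(kv, inherent_mm_al = 2.5) {
  E <- seq(10, kv, by = 1)
  w <- pmax(kv - E, 0)                                  # Kramers
  w <- w * exp(-mu_al_of(E) * RHO_AL * inherent_mm_al / 10)
  if (kv > 70) {                                        # tungsten K lines
    lines <- c(`58` = 0.6, `59` = 1.0, `67` = 0.35, `69` = 0.1)
    for (le in names(lines)) {
      i <- match(as.numeric(le), E)
      w[i] <- w[i] + lines[[le]] * 0.08 * sum(w)
    }
  }
  data.frame(energy_kev = E, weight = w / sum(w))
}

for (kv in c(80, 100, 120, 140)) {
  write.csv(format(make_spectrum(kv), digits = 6, trim = TRUE),
            sprintf("inst/extdata/spectrum_%dkv.csv", kv),
            row.names = FALSE, quote = FALSE)
}

message("fixtures written")
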