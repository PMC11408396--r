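# shared fixtures, built once per test run
.fx <- new.env(parent = emptyenv())

fx <- function(name, expr) {
  if (is.null(.fx[[name]])) assign(name, force(expr), envir = .fx)
  .fx[[name]]
}

fx_atten <- function() fx("atten", attenuation_table())
fx_spec <- function() fx("spec120", base_spectrum(120))

fx_phantom <- function() {
  fx("phantom", build_phantom(default_adult_spec("female", 1.63, 60,
                                                 seed = 1)))
}

# aluminium linear attenuation, 1/mm, from the public surface
mu_al_mm <- function(energy) {
  mu_over_rho(fx_atten(), "aluminium", energy) * 2.699 / 10
}

# a single-line ("monoenergetic") spectrum at the given energy
mono_spectrum <- function(energy) {
  s <- base_spectrum(120)
  s$weight <- as.numeric(s$energy_kev == energy)
  s$weight <- s$weight / sum(s$weight)
  s
}

# homogeneous water cylinder along z (for depth-dose and WED checks)
water_cylinder_model <- function(radius_mm = 100, hu = 0, n_xy = 101,
                                 n_z = 20, sp_xy = 2.5, sp_z = 6) {
  xs <- (seq_len(n_xy) - 0.5) * sp_xy
  c0 <- n_xy * sp_xy / 2
  hu_arr <- array(-1000, dim = c(n_xy, n_xy, n_z))
  disc <- outer(xs - c0, xs - c0, function(a, b) a^2 + b^2) <= radius_mm^2
  for (k in seq_len(n_z)) hu_arr[, , k][disc] <- hu
  structure(list(hu = hu_arr, spacing = c(sp_xy, sp_xy, sp_z),
                 origin = c(0, 0, 0), sex = "male", height = 1.76,
                 weight = 73),
            class = "voxdose_model")
}

# homogeneous water slab: x in [0, thickness_mm], generous y/z extent
water_slab_materials <- function(thickness_mm = 100, n_x = 25) {
  hu <- array(0, dim = c(n_x, 21, 21))
  model <- structure(list(hu = hu,
                          spacing = c(thickness_mm / n_x, 10, 10),
                          origin = c(0, 0, 0), sex = "male",
                          height = 1.76, weight = 73),
                     class = "voxdose_model")
  hu_to_materials(model)
}

# an attenuation table whose water entries force a single interaction type
forced_interaction_atten <- function(process = "photoelectric") {
  at <- attenuation_table()
  n <- length(at$energies)
  at$tables$water$f_photoelectric <- rep(as.numeric(process == "photoelectric"), n)
  at$tables$water$f_compton <- rep(as.numeric(process == "compton"), n)
  at$tables$water$f_rayleigh <- rep(as.numeric(process == "rayleigh"), n)
  at
}

# Klein-Nishina moments by numerical quadrature (independent of the sampler)
kn_moments <- function(energy) {
  k <- energy / 511
  f <- function(x) {
    r <- 1 / (1 + k * (1 - x))
    r^2 * (r + 1 / r - (1 - x^2))
  }
  norm <- stats::integrate(f, -1, 1)$value
  m1 <- stats::integrate(function(x) x * f(x), -1, 1)$value / norm
  m2 <- stats::integrate(function(x) x^2 * f(x), -1, 1)$value / norm
  list(mean = m1, var = m2 - m1^2)
}

# hand-built scenario table for comparison-logic tests (no Monte Carlo)
fake_scenarios <- function(d_a, d_b, d_c, d_d, d_e = d_b,
                           absent = rep(FALSE, length(d_a)),
                           organ = paste0("organ", seq_along(d_a))) {
  out <- tibble::tibble(organ = organ, d_a = d_a, d_b = d_b, d_c = d_c,
                        d_d = d_d, d_e = d_e,
                        v_in_m3 = 1e-4, v_total_m3 = 1e-4,
                        v_ref_m3 = 1e-4, absent = absent)
  class(out) <- c("voxdose_scenarios", class(out))
  out
}
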