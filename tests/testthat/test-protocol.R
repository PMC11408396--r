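proto <- function(...) {
  scan_protocol(z_range(0, 134.4), overscan = 0, photon_budget = 1, ...)
}

test_that("rotation count follows table feed = pitch x collimation", {
  expect_equal(n_rotations(proto()), 10)  # 134.4 / (0.7 * 19.2)
  expect_equal(n_rotations(proto(pitch = 1.4)), 5)
})

test_that("protocol validation catches inconsistent geometry and bad TCM", {
  expect_error(proto(pitch = 0), "pitch")
  expect_error(proto(collimation = -1), "collimation")
  expect_error(proto(fan_angle = 0.5), "inconsistent")
  expect_silent(proto(fan_angle = 0.7955))  # the DICOM-header value
  expect_error(proto(tcm = data.frame(z = numeric(), mas = numeric())),
               "empty tcm")
  expect_error(proto(tcm = data.frame(z = 1, mas = -5)), "positive")
})

test_that("source state starts at the range edge and advances helically", {
  p <- proto()
  st <- source_state(p, c(0, 0.5))
  expect_equal(st$z[1], 0)
  expect_equal(st$angle[1], 0)
  expect_equal(st$z[2], 67.2)
  expect_equal(st$angle[2], 2 * pi * 5)
  expect_equal(st$fx[1], 595)  # focal spot at the focus-isocenter distance
  expect_error(source_state(p, 1.2), "s >= 0")
})

test_that("overscan extends the emitted range by the extra irradiated length", {
  p12 <- scan_protocol(z_range(0, 100), overscan = 12, photon_budget = 1)
  st <- source_state(p12, 0)
  expect_equal(st$z[1], -(12 - 19.2 / 2))  # tube travel extension 2.4 mm
  p_table <- scan_protocol(z_range(0, 100), overscan = 12,
                           overscan_mode = "table", photon_budget = 1)
  expect_equal(source_state(p_table, 0)$z[1], -12)
})

test_that("TCM weights are nearest-slice lookups normalised to the table mean", {
  tcm <- data.frame(z = c(5, 15, 25, 35), mas = c(50, 100, 150, 100))
  p <- scan_protocol(z_range(0, 40), overscan = 0, tcm = tcm,
                     photon_budget = 1)
  st <- source_state(p, c(0.05, 0.3, 0.62))
  expect_equal(st$mas_weight, c(50, 100, 150) / 100)

  # uniform table gives unit weights
  pu <- scan_protocol(z_range(0, 40), overscan = 0,
                      tcm = data.frame(z = c(10, 30), mas = c(80, 80)),
                      photon_budget = 1)
  expect_true(all(source_state(pu, c(0, 0.5, 0.99))$mas_weight == 1))
})

test_that("emission sampling respects spectrum, fan geometry and weights", {
  set.seed(42)
  p <- scan_protocol(z_range(0, 134.4), overscan = 0, photon_budget = 1)
  s <- fx_spec()
  n <- 1e5
  ph <- sample_emission(p, s, NULL, n)

  # unit directions
  expect_equal(ph$ux^2 + ph$uy^2 + ph$uz^2, rep(1, n), tolerance = 1e-12)

  # mean sampled energy within 3 sigma of the spectrum mean
  mu <- mean_energy(s)
  sd_e <- sqrt(sum(s$weight * (s$energy_kev - mu)^2))
  expect_lt(abs(mean(ph$energy_kev) - mu), 3 * sd_e / sqrt(n))

  # no bowtie, uniform tcm: weights identically 1
  expect_true(all(ph$weight == 1))

  # every ray passes the rotation axis within the scan FOV half-width
  # (distance of closest approach in the xy plane)
  dca <- abs(ph$x * ph$uy - ph$y * ph$ux) / sqrt(ph$ux^2 + ph$uy^2)
  expect_lte(max(dca), 500 / 2 + 1)

  # helical coverage: z density uniform over the range within 4 sigma
  bins <- table(cut(ph$z_table, breaks = seq(0, 134.4, length.out = 11)))
  expect_true(all(abs(bins - n / 10) < 4 * sqrt(n / 10)))
})

test_that("bowtie enters as multiplicative attenuation weight, doubling TCM doubles weights", {
  p <- scan_protocol(z_range(0, 100), overscan = 0, photon_budget = 1)
  bt <- structure(tibble::tibble(gamma = c(-1, 0, 1), thickness_mm = 2),
                  class = c("voxdose_bowtie", class(tibble::tibble())))
  set.seed(1)
  ph <- sample_emission(p, mono_spectrum(60), bt, 1000, fx_atten())
  expect_equal(ph$weight, rep(exp(-mu_al_mm(60) * 2), 1000))

  tcm1 <- data.frame(z = c(25, 75), mas = c(60, 120))
  tcm2 <- transform(tcm1, mas = mas * 2)
  p1 <- scan_protocol(z_range(0, 100), overscan = 0, tcm = tcm1,
                      photon_budget = 1)
  p2 <- scan_protocol(z_range(0, 100), overscan = 0, tcm = tcm2,
                      photon_budget = 1)
  set.seed(9); w1 <- sample_emission(p1, mono_spectrum(60), NULL, 500)$weight
  set.seed(9); w2 <- sample_emission(p2, mono_spectrum(60), NULL, 500)$weight
  # doubling every entry leaves mean-normalised weights identical (the
  # absolute mAs scale enters through the calibration, not the weights)
  expect_equal(w1, w2)
  expect_setequal(round(unique(w1), 12), round(c(60, 120) / 90, 12))
})

test_that("synthesised TCM tracks body attenuation at the requested mean", {
  ph <- fx_phantom()
  tcm <- synthesise_tcm(ph$model, mean_mas = 120)
  expect_equal(mean(tcm$mas), 120)
  # slices through the shoulders/abdomen demand more mAs than lung slices
  chest <- scan_range_for(ph$masks, "chest")
  mid_chest <- tcm$mas[tcm$z > chest$z_start & tcm$z < chest$z_end]
  below <- tcm$mas[tcm$z < chest$z_start - 50 & tcm$z > chest$z_start - 200]
  expect_gt(mean(below), mean(mid_chest))
})
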