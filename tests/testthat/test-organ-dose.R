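dose_grid_from <- function(arr, spacing = c(1, 1, 1)) {
  structure(list(dose = arr, uncertainty = array(0, dim(arr)),
                 spacing = spacing, origin = c(0, 0, 0), n_photons = 1,
                 seed = 1L, unit = "mGy per 100 mAs"),
            class = "voxdose_dose")
}

test_that("slice profiles carry areas, means and fractions that sum to one", {
  dose <- dose_grid_from(array(1:400 * 0.01, c(20, 20, 1)))
  mask <- array(FALSE, c(20, 20, 1))
  mask[1:10, 1, 1] <- TRUE
  p <- slice_profile(dose, mask)
  expect_equal(p$frac, 1)

  # two slices with areas 100 and 300 mm^2 -> fractions 0.25 / 0.75
  dose2 <- dose_grid_from(array(0, c(20, 20, 2)))
  dose2$dose[, , 1] <- 2; dose2$dose[, , 2] <- 4
  m2 <- array(FALSE, c(20, 20, 2))
  m2[1:10, 1:10, 1] <- TRUE
  m2[1:20, 1:15, 2] <- TRUE
  p2 <- slice_profile(dose2, m2)
  expect_equal(p2$area_mm2, c(100, 300))
  expect_equal(p2$frac, c(0.25, 0.75))
  expect_equal(organ_dose(p2), 0.25 * 2 + 0.75 * 4)  # 3.5

  # random masks: fractions always sum to 1
  set.seed(5)
  for (i in 1:10) {
    m <- array(runif(20 * 20 * 4) < 0.2, c(20, 20, 4))
    if (!any(m)) next
    expect_equal(sum(slice_profile(dose_grid_from(array(runif(1600), c(20, 20, 4))),
                                   m)$frac), 1, tolerance = 1e-12)
  }

  expect_error(slice_profile(dose, array(FALSE, c(20, 20, 1))), "empty")
  expect_error(slice_profile(dose, array(TRUE, c(5, 5, 1))),
               "5x5x1.*20x20x1")
})

test_that("the organ dose is a convex combination of slice means", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(2:8, 1)
    a <- runif(n, 1, 100)
    profile <- tibble::tibble(slice = seq_len(n), z = seq_len(n),
                              area_mm2 = a, mean_dose = runif(n, 0, 20),
                              frac = a / sum(a))
    class(profile) <- c("voxdose_slice_profile", class(profile))
    d <- organ_dose(profile)
    expect_gte(d, min(profile$mean_dose) - 1e-12)
    expect_lte(d, max(profile$mean_dose) + 1e-12)
  }
  # uniform dose collapses to that dose
  uni <- tibble::tibble(slice = 1:3, z = 1:3, area_mm2 = c(5, 10, 2),
                        mean_dose = 7, frac = c(5, 10, 2) / 17)
  class(uni) <- c("voxdose_slice_profile", class(uni))
  expect_equal(organ_dose(uni), 7)
})

test_that("the slice aggregation equals plain voxel averaging on uniform grids", {
  set.seed(11)
  dose <- dose_grid_from(array(rexp(30 * 30 * 10), c(30, 30, 10)),
                         spacing = c(2, 2, 5))
  for (i in 1:5) {
    mask <- array(runif(30 * 30 * 10) < 0.1, c(30, 30, 10))
    d_eq <- organ_dose(slice_profile(dose, mask))
    d_vox <- mean(dose$dose[mask])
    expect_equal(d_eq, d_vox, tolerance = 1e-10)
  }
})

test_that("volume rescaling follows the energy-spreading model", {
  expect_equal(rescale_full_volume(10, 5e-4, 1e-3), 5)
  expect_equal(rescale_full_volume(10, 1e-3, 1e-3), 10)  # identity when covered
  expect_error(rescale_full_volume(10, 0, 1e-3), "absent")
  expect_error(rescale_full_volume(10, 2e-3, 1e-3), "exceeds")

  # implied missing-volume overestimate: (V_total/V_in - 1) * 100 %
  set.seed(2)
  for (i in 1:10) {
    v_tot <- runif(1, 1e-4, 1e-3)
    phi <- runif(1, 0.1, 1)
    d_t <- runif(1, 1, 20)
    d_full <- rescale_full_volume(d_t, phi * v_tot, v_tot)
    expect_equal(percentage_difference(d_t, d_full), (1 / phi - 1) * 100,
                 tolerance = 1e-9)
  }

  expect_equal(rescale_reference_volume(10, 0.5e-3, 1e-3), 5)
  expect_equal(rescale_reference_volume(10, 1e-3, 1e-3), 10)
  expect_error(rescale_reference_volume(10, 1e-3, 0), "positive")
})

test_that("reference organ volumes reproduce the ICRP tabulation", {
  expect_equal(reference_volume(1.800, 1060), 1.70e-3, tolerance = 0.002)
  expect_error(reference_volume(0, 1000), "positive")
  expect_error(reference_volume(1, -5), "positive")

  printed <- list(
    male = c(breast = 2.45e-5, liver = 1.70e-3, lungs = 2.89e-3,
             kidneys = 2.07e-4, oesophagus = 3.86e-5, ribs = 5.44e-4,
             thyroid = 1.90e-5, spine = 1.48e-3),
    female = c(breast = 4.90e-4, liver = 1.32e-3, lungs = 2.30e-3,
               kidneys = 1.83e-4, oesophagus = 3.38e-5, ribs = 3.24e-4,
               thyroid = 1.62e-5, spine = 1.18e-3))
  for (sex in names(printed)) {
    tab <- reference_organ_table(sex)
    for (organ in names(printed[[sex]])) {
      v <- tab$volume_m3[tab$organ == organ]
      p <- printed[[sex]][[organ]]
      # agreement within one unit in the last printed digit (3 s.f.)
      expect_lt(abs(v - p), 10^(floor(log10(p)) - 2) * 1.001,
                label = sprintf("%s %s volume %.4g vs %.4g", sex, organ, v, p))
    }
  }

  # ribs and spine masses derive from skeletal-mass fractions
  male <- reference_organ_table("male")
  female <- reference_organ_table("female")
  expect_equal(male$mass_kg[male$organ == "ribs"], 0.07 * 10.5)     # 0.735
  expect_equal(male$mass_kg[male$organ == "spine"], 0.19 * 10.5)    # 1.995
  expect_equal(female$mass_kg[female$organ == "ribs"], 0.056 * 7.8)
  expect_equal(female$mass_kg[female$organ == "spine"], 0.204 * 7.8)
})

test_that("effective dose is the tissue-weighted sum with partial flagging", {
  expect_equal(as.numeric(effective_dose(c(lungs = 8),
                                         weights = c(lungs = 1))), 8)
  w <- icrp103_weights()
  d <- setNames(rep(3, length(w)), names(w))
  ed <- effective_dose(d, w)
  expect_equal(as.numeric(ed), 3 * sum(w))
  expect_true(attr(ed, "partial"))  # the modelled organs are a subset
  expect_error(effective_dose(c(lungs = 1), weights = c(lungs = -0.1)),
               "non-negative")
  expect_error(effective_dose(c(stomach = 1), weights = c(lungs = 0.12)),
               "no supplied organ")
})

test_that("the organ dose report combines doses, volumes and rescales", {
  ph <- fx_phantom()
  cardiac <- scan_range_for(ph$masks, "cardiac")
  crop <- crop_to_range(ph$model, ph$masks, cardiac)
  dims <- dim(crop$model$hu)
  dose <- dose_grid_from(array(1, dims), spacing = crop$model$spacing)
  dose$origin <- crop$model$origin
  tab <- organ_dose_table(dose, crop$masks, reference_organ_table("female"))

  expect_setequal(tab$organ, names(ph$masks$masks))
  thy <- tab[tab$organ == "thyroid", ]
  expect_true(thy$absent)
  expect_equal(thy$d_full, 0)
  expect_equal(thy$d_refvol, 0)

  heart <- tab[tab$organ == "heart", ]
  expect_false(heart$absent)
  expect_equal(heart$d_t, 1)                 # uniform dose
  expect_equal(heart$d_full, 1)              # fully covered organ: identity
  expect_true(is.na(heart$v_ref_m3))         # no reference entry for heart

  lungs <- tab[tab$organ == "lungs", ]
  expect_equal(lungs$d_full, lungs$d_t * lungs$v_in_m3 / lungs$v_total_m3)
})
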