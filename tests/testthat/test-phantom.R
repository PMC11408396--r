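test_that("z ranges are validated half-open intervals with overscan arithmetic", {
  z <- z_range(120, 300)
  expect_equal(z_length(z), 180)
  expect_error(z_range(300, 120), "invalid z range")
  expect_error(z_range(1, 1), "invalid z range")

  ze <- extend_with_overscan(z, 12)
  expect_equal(c(ze$z_start, ze$z_end), c(108, 312))
  z0 <- extend_with_overscan(z, 0)
  expect_equal(c(z0$z_start, z0$z_end), c(120, 300))
  expect_error(extend_with_overscan(z, -5), "non-negative")
})

test_that("default adult specs validate inputs and realise the intended anatomy", {
  expect_error(default_adult_spec("male", 1.76, -1, seed = 0), "weight")
  expect_error(default_adult_spec("male", 0, 70, seed = 0), "height")

  for (args in list(list("female", 1.63, 60, 1), list("male", 1.76, 73, 2))) {
    ph <- build_phantom(default_adult_spec(args[[1]], args[[2]], args[[3]],
                                           seed = args[[4]]))
    masks <- ph$masks
    chest <- scan_range_for(masks, "chest")
    cardiac <- scan_range_for(masks, "cardiac")
    crop <- crop_to_range(ph$model, masks, chest)
    v_in <- sapply(crop$masks$masks, sum)
    v_tot <- sapply(masks$masks, sum)
    frac <- v_in / v_tot

    expect_equal(frac[["heart"]], 1)    # heart fully inside the chest range
    expect_equal(frac[["lungs"]], 1)    # by definition of the range
    expect_gt(frac[["liver"]], 0.3)     # liver partially inside
    expect_lt(frac[["liver"]], 0.7)
    expect_lt(frac[["kidneys"]], 0.1)   # kidneys mostly outside
    expect_gt(frac[["kidneys"]], 0)

    # thyroid entirely outside the cardiac range
    crop_c <- crop_to_range(ph$model, masks, cardiac)
    expect_equal(sum(crop_c$masks$masks$thyroid), 0)
    # heart fully inside the cardiac range
    expect_equal(sum(crop_c$masks$masks$heart), v_tot[["heart"]])
    # chest range contains the cardiac range
    expect_lte(chest$z_start, cardiac$z_start)
    expect_gte(chest$z_end, cardiac$z_end)
    # breasts on female phantoms only
    expect_equal("breast" %in% names(masks$masks), args[[1]] == "female")
  }
})

test_that("phantom rasterisation is deterministic and clips are detected", {
  spec <- default_adult_spec("male", 1.76, 73, seed = 5)
  a <- build_phantom(spec)
  b <- build_phantom(spec)
  expect_identical(a$model$hu, b$model$hu)
  expect_identical(a$masks$masks, b$masks$masks)
  # HU assignments land in the material-class bins
  expect_true(all(a$model$hu[a$masks$masks$lungs] == -700))
  expect_true(all(a$model$hu[a$masks$masks$spine] == 700))
  # a grid too small for the body errors out
  expect_error(build_phantom(spec, grid_shape = c(20, 20, 180)), "clipped")
})

test_that("masks do not overlap and volumes are consistent bookkeeping", {
  ph <- fx_phantom()
  lab <- Reduce(`+`, lapply(ph$masks$masks, function(m) as.integer(m)))
  expect_lte(max(lab), 1)  # non-overlap after rasterisation

  voxvol <- prod(ph$model$spacing) * 1e-9
  counted <- sapply(ph$masks$masks, function(m) sum(m) * voxvol)
  expect_equal(unname(ph$masks$total_volumes[names(counted)]),
               unname(counted))

  # any crop retains total volumes and in-grid volume is a subset
  crop <- crop_to_range(ph$model, ph$masks,
                        scan_range_for(ph$masks, "cardiac"))
  expect_identical(crop$masks$total_volumes, ph$masks$total_volumes)
  v_in <- sapply(crop$masks$masks, function(m) sum(m) * voxvol)
  expect_true(all(v_in <= ph$masks$total_volumes[names(v_in)] + 1e-15))
})

test_that("scan ranges come from mask extents snapped to whole slices", {
  # lungs spanning 0-based slices 40-100 at dz = 3, origin 0 -> [120, 303)
  m <- array(FALSE, dim = c(4, 4, 120))
  m[2, 2, 41:101] <- TRUE  # 1-based indices 41..101
  masks <- structure(list(masks = list(lungs = m),
                          total_volumes = c(lungs = sum(m) * 48e-9),
                          spacing = c(4, 4, 3), origin = c(0, 0, 0)),
                     class = "voxdose_masks")
  z <- scan_range_for(masks, "chest")
  expect_equal(c(z$z_start, z$z_end), c(120, 303))
  expect_error(scan_range_for(structure(list(masks = list(), spacing = c(4, 4, 3),
                                             origin = c(0, 0, 0)),
                                        class = "voxdose_masks"), "chest"),
               "lungs")
})

test_that("cropping keeps exactly the slices intersecting the range", {
  ph <- fx_phantom()
  nz <- dim(ph$model$hu)[3]
  dz <- ph$model$spacing[3]
  full <- crop_to_range(ph$model, ph$masks, z_range(0, nz * dz))
  expect_identical(full$model$hu, ph$model$hu)

  part <- crop_to_range(ph$model, ph$masks, z_range(10, 20))  # dz = 6
  expect_equal(dim(part$model$hu)[3], 3)  # slices [6,12), [12,18), [18,24)
  expect_equal(part$model$origin[3], 6)
  expect_error(crop_to_range(ph$model, ph$masks, z_range(5000, 6000)),
               "does not intersect")
})

test_that("water-equivalent diameter matches closed forms on cylinders", {
  wc <- water_cylinder_model(radius_mm = 100, hu = 0)
  dw <- water_equivalent_diameter(wc)
  expect_equal(dw, 200, tolerance = 0.02)  # rasterisation tolerance

  half <- water_cylinder_model(radius_mm = 100, hu = -500)
  expect_equal(water_equivalent_diameter(half), 200 * sqrt(0.5),
               tolerance = 0.02)

  air_only <- water_cylinder_model(radius_mm = 100, hu = 0)
  air_only$hu[] <- -1000
  expect_error(water_equivalent_diameter(air_only), "in-body")
})

test_that("heavier phantoms at fixed height have larger water-equivalent diameter", {
  dw <- sapply(c(55, 70, 90), function(w) {
    ph <- build_phantom(default_adult_spec("male", 1.76, w, seed = 3,
                                           jitter = 0))
    water_equivalent_diameter(ph$model, scan_range_for(ph$masks, "chest"))
  })
  expect_true(all(diff(dw) > 0))
})
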