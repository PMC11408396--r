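#' Parametric specification of a synthetic adult phantom
#'
#' Builds the parametric description of a synthetic whole-trunk adult voxel
#' phantom: an elliptical body cylinder with neck and head, and shape
#' primitives (ellipsoids, tubes, shells) for the organs needed in chest and
#' cardiac CT dosimetry: lungs, heart (with great-vessel stub up to the
#' aortic-arch level), oesophagus, thyroid, ribs, liver, spine, kidneys, and
#' breasts for female phantoms. Sizes scale with height and weight; a seeded
#' jitter perturbs organ sizes and positions so a cohort of specs emulates
#' anatomical variation.
#'
#' The anatomy is arranged so that on the realised phantom the heart and
#' lungs lie entirely inside the chest scan range (lung apex to base), the
#' liver lies partially inside (roughly 30-70% by volume), the kidneys
#' almost entirely outside (< 10% inside), and the thyroid entirely outside
#' the cardiac range.
#'
#' @param sex `"male"` or `"female"`.
#' @param height Body height in m.
#' @param weight Body weight in kg.
#' @param seed Integer seed controlling the anatomical jitter.
#' @param jitter Fractional scale of the size/position perturbations
#'   (default 0.04; 0 gives the unperturbed reference anatomy).
#' @return A `voxdose_phantom_spec`.
#' @export
#' @examples
#' spec <- default_adult_spec("female", 1.63, 60, seed = 1)
default_adult_spec <- function(sex = c("male", "female"), height, weight,
                               seed = 1L, jitter = 0.04) {
  sex <- match.arg(sex)
  if (!is.numeric(height) || length(height) != 1 || !is.finite(height) ||
      height <= 0) {
    stop("height must be a single positive number of metres")
  }
  if (!is.numeric(weight) || length(weight) != 1 || !is.finite(weight) ||
      weight <= 0) {
    stop("weight must be a single positive number of kilograms")
  }

  # jitter draws are made in a fixed order so a spec is a pure function of
  # its arguments
  rng <- local({
    state <- seed
    function(n, sd) {
      state <<- state + 1L
      set.seed(state)
      stats::rnorm(n, 0, sd)
    }
  })
  jf <- function(n = 1) pmax(pmin(1 + rng(n, jitter), 1 + 3 * jitter),
                             1 - 3 * jitter)          # size factors
  jp <- function(n = 1) rng(n, jitter / 8)            # position offsets, frac of L

  L <- 0.55 * height * 1000   # modelled length (trunk + neck + head), mm

  # body cross-section scales with weight per height (trunk area ~ w/h)
  ref <- (73 / 1.76)
  scale_xy <- sqrt((weight / height) / ref)
  a <- 95 * scale_xy * jf()   # lateral semi-axis, mm
  b <- 0.72 * a * jf()        # anteroposterior semi-axis

  frac <- function(f) f * L   # anatomical landmarks as fractions of L
  lung_base <- frac(0.50 + jp())
  lung_apex <- frac(0.74 + jp())
  lung_c <- (lung_base + lung_apex) / 2
  lung_h <- (lung_apex - lung_base) / 2

  heart_c <- lung_base + 0.30 * (lung_apex - lung_base)
  heart_hz <- 0.24 * (lung_apex - lung_base) * jf()
  arch_z <- heart_c + heart_hz + 0.055 * L * jf()  # aortic-arch level

  organs <- list()
  organs$lungs <- list(
    type = "paired_ellipsoid", hu = -700,
    center = c(0.45 * a, -0.05 * b, lung_c),
    semi = c(0.30 * a * jf(), 0.58 * b * jf(), lung_h))
  organs$liver <- list(
    type = "ellipsoid", hu = 55,
    center = c(0.28 * a, 0.05 * b, lung_base - 0.011 * L + jp() * L / 2),
    semi = c(0.48 * a * jf(), 0.52 * b * jf(), 0.075 * L * jf()))
  organs$kidneys <- list(
    type = "paired_ellipsoid", hu = 40,
    center = c(0.42 * a, -0.32 * b, lung_base - 0.044 * L + jp() * L / 2),
    semi = c(0.14 * a * jf(), 0.17 * b * jf(), 0.060 * L * jf()))
  organs$heart <- list(
    type = "heart", hu = 40,
    center = c(-0.10 * a, 0.18 * b, heart_c),
    semi = c(0.34 * a * jf(), 0.38 * b * jf(), heart_hz),
    vessel_radius = 13 * jf(), arch_z = arch_z)
  organs$thyroid <- list(
    type = "ellipsoid", hu = 40,
    center = c(0, -0.25 * b, lung_apex - 0.007 * L + jp() * L / 2),
    semi = c(22 * jf(), 12 * jf(), 0.013 * L * jf()))
  if (sex == "female") {
    organs$breast <- list(
      type = "paired_ellipsoid", hu = -50,
      center = c(0.42 * a, 0.92 * b, lung_base + 0.45 * (lung_apex - lung_base)),
      semi = c(0.30 * a * jf(), 0.30 * b * jf(), 0.042 * L * jf()))
  }
  organs$ribs <- list(
    type = "shell", hu = 700,
    semi_outer = c(0.90 * a, 0.90 * b), thickness = 8,
    z = c(lung_base - 0.016 * L, lung_apex + 0.014 * L))
  organs$spine <- list(
    type = "tube", hu = 700, radius = 15 * jf(),
    center = c(0, -0.62 * b, 0),
    z = c(frac(0.06), frac(0.76)))
  # listed last: the thin prevertebral tube must win the overlap
  # resolution against the spine or it rasterises away on coarse grids
  organs$oesophagus <- list(
    type = "tube", hu = 40, radius = 7 * jf(),
    center = c(0, -0.45 * b, 0),
    z = c(lung_base - 0.01 * L, lung_apex + 0.012 * L))

  structure(list(
    sex = sex, height = height, weight = weight, seed = seed,
    jitter = jitter, length_mm = L,
    body = list(a = a, b = b, hu = 40,
                trunk_z = c(0, frac(0.78)),
                neck = list(radius = 0.30 * a, z = c(frac(0.78), frac(0.86))),
                head = list(semi = c(0.55 * a, 0.62 * b, 0.07 * L),
                            center_z = frac(0.93))),
    organs = organs,
    landmarks = list(lung_base = lung_base, lung_apex = lung_apex,
                     aortic_arch = arch_z)),
    class = "voxdose_phantom_spec")
}

#' @export
print.voxdose_phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom spec> %s, %.2f m, %.1f kg (BMI %.1f), seed %d, %d organs\n",
              x$sex, x$height, x$weight, x$weight / x$height^2, x$seed,
              length(x$organs)))
  invisible(x)
}

new_voxel_model <- function(hu, spacing, origin, sex, height, weight) {
  stopifnot(length(dim(hu)) == 3, all(spacing > 0))
  hu[hu < -1024] <- -1024
  structure(list(hu = hu, spacing = spacing, origin = origin,
                 sex = sex, height = height, weight = weight),
            class = "voxdose_model")
}

#' @export
print.voxdose_model <- function(x, ...) {
  d <- dim(x$hu)
  cat(sprintf("<voxel model> %dx%dx%d @ %gx%gx%g mm | %s, %.2f m, %.1f kg\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              x$sex, x$height, x$weight))
  invisible(x)
}

# world coordinates of voxel centres along each axis
axis_coords <- function(n, spacing, origin) origin + (seq_len(n) - 0.5) * spacing

# world z of the inferior face of slice k (1-based) and slice count of a grid
slice_z0 <- function(model, k) model$origin[3] + (k - 1) * model$spacing[3]

#' Rasterise a phantom spec onto a voxel grid
#'
#' Paints the body and organ primitives into a Hounsfield-unit grid and
#' builds the aligned organ masks. Rasterisation is deterministic: the same
#' spec and grid always produce bit-identical output. Overlapping organs are
#' resolved in favour of the later-listed primitive, and masks are stored
#' after resolution so no two masks share a voxel. Whole-body organ volumes
#' (`total_volumes`) are voxel counts times voxel volume, in m^3.
#'
#' @param spec A `voxdose_phantom_spec`.
#' @param grid_shape Integer vector (nx, ny, nz); default 64 x 64 x 180.
#' @param spacing Voxel size (dx, dy, dz) in mm; default 4 x 4 x 6.
#' @return A list with elements `model` (a `voxdose_model`) and `masks`
#'   (a `voxdose_masks`).
#' @export
#' @examples
#' ph <- build_phantom(default_adult_spec("male", 1.76, 73, seed = 2))
build_phantom <- function(spec, grid_shape = c(64, 64, 180),
                          spacing = c(4, 4, 6)) {
  stopifnot(inherits(spec, "voxdose_phantom_spec"),
            length(grid_shape) == 3, length(spacing) == 3,
            all(spacing > 0), all(grid_shape >= 2))
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  origin <- c(0, 0, 0)
  xs <- axis_coords(nx, spacing[1], origin[1])
  ys <- axis_coords(ny, spacing[2], origin[2])
  zs <- axis_coords(nz, spacing[3], origin[3])
  cx <- mean(range(xs)); cy <- mean(range(ys))

  # body must fit inside the grid
  if (spec$body$a >= (max(xs) - min(xs)) / 2 ||
      spec$body$b >= (max(ys) - min(ys)) / 2 ||
      spec$length_mm > max(zs) + spacing[3] / 2) {
    stop(sprintf(
      "body (a=%.0f, b=%.0f, length=%.0f mm) is clipped by the %dx%dx%d grid at %gx%gx%g mm",
      spec$body$a, spec$body$b, spec$length_mm, nx, ny, nz,
      spacing[1], spacing[2], spacing[3]))
  }

  X <- array(rep(xs, times = ny * nz), dim = c(nx, ny, nz))
  Y <- array(rep(rep(ys, each = nx), times = nz), dim = c(nx, ny, nz))
  Z <- array(rep(zs, each = nx * ny), dim = c(nx, ny, nz))

  ellipsoid <- function(center, semi, mirror_x = FALSE) {
    ctr_x <- cx + center[1]; ctr_y <- cy + center[2]
    m <- ((X - ctr_x) / semi[1])^2 + ((Y - ctr_y) / semi[2])^2 +
      ((Z - center[3]) / semi[3])^2 <= 1
    if (mirror_x) {
      m <- m | (((X - (cx - center[1])) / semi[1])^2 +
                  ((Y - ctr_y) / semi[2])^2 +
                  ((Z - center[3]) / semi[3])^2 <= 1)
    }
    m
  }
  tube <- function(center, radius, zlim) {
    ((X - (cx + center[1]))^2 + (Y - (cy + center[2]))^2 <= radius^2) &
      Z >= zlim[1] & Z < zlim[2]
  }

  hu <- array(-1000, dim = grid_shape)

  # body: trunk + neck + head, all soft tissue
  trunk <- (((X - cx) / spec$body$a)^2 + ((Y - cy) / spec$body$b)^2 <= 1) &
    Z >= spec$body$trunk_z[1] & Z < spec$body$trunk_z[2]
  neck <- tube(c(0, -0.1 * spec$body$b), spec$body$neck$radius,
               spec$body$neck$z)
  head <- ellipsoid(c(0, -0.1 * spec$body$b, spec$body$head$center_z),
                    spec$body$head$semi)
  hu[trunk | neck | head] <- spec$body$hu

  rasterise <- function(o) {
    switch(o$type,
      ellipsoid = ellipsoid(o$center, o$semi),
      paired_ellipsoid = ellipsoid(o$center, o$semi, mirror_x = TRUE),
      tube = tube(o$center[1:2], o$radius, o$z),
      heart = {
        m <- ellipsoid(o$center, o$semi)
        m | tube(o$center[1:2], o$vessel_radius,
                 c(o$center[3], o$arch_z))
      },
      shell = {
        r2o <- ((X - cx) / o$semi_outer[1])^2 + ((Y - cy) / o$semi_outer[2])^2
        ai <- o$semi_outer[1] - o$thickness
        bi <- o$semi_outer[2] - o$thickness
        r2i <- ((X - cx) / ai)^2 + ((Y - cy) / bi)^2
        r2o <= 1 & r2i > 1 & Z >= o$z[1] & Z < o$z[2]
      },
      stop("unknown primitive type: ", o$type))
  }

  inside_body <- hu > -1000
  masks <- vector("list", length(spec$organs))
  names(masks) <- names(spec$organs)
  for (nm in names(spec$organs)) {
    m <- rasterise(spec$organs[[nm]]) & inside_body
    hu[m] <- spec$organs[[nm]]$hu
    masks[[nm]] <- m
  }
  # overlap resolution: later-listed organ wins; masks stored post-resolution
  nms <- names(masks)
  for (i in seq_along(nms)) {
    if (i < length(nms)) {
      later <- Reduce(`|`, masks[(i + 1):length(nms)])
      masks[[i]] <- masks[[i]] & !later
    }
    if (!any(masks[[i]])) {
      stop("organ '", nms[i], "' rasterised to an empty mask on this grid")
    }
  }

  model <- new_voxel_model(hu, spacing, origin, spec$sex, spec$height,
                           spec$weight)
  voxvol_m3 <- prod(spacing) * 1e-9
  total_volumes <- vapply(masks, function(m) sum(m) * voxvol_m3, numeric(1))
  mask_set <- structure(list(masks = masks, total_volumes = total_volumes,
                             spacing = spacing, origin = origin),
                        class = "voxdose_masks")
  list(model = model, masks = mask_set)
}

#' @export
print.voxdose_masks <- function(x, ...) {
  cat("<organ masks>", paste(names(x$masks), collapse = ", "), "\n")
  invisible(x)
}

# volume (m^3) of each mask as present in its grid
in_grid_volumes <- function(masks) {
  voxvol <- prod(masks$spacing) * 1e-9
  vapply(masks$masks, function(m) sum(m) * voxvol, numeric(1))
}

check_alignment <- function(model, masks) {
  for (nm in names(masks$masks)) {
    if (!identical(dim(masks$masks[[nm]]), dim(model$hu))) {
      stop(sprintf("mask '%s' has shape %s but the model grid is %s", nm,
                   paste(dim(masks$masks[[nm]]), collapse = "x"),
                   paste(dim(model$hu), collapse = "x")))
    }
  }
  invisible(TRUE)
}

#' Anatomy-specific scan range from organ masks
#'
#' The chest protocol scans from the lung apex to the lung base; the cardiac
#' protocol from the aortic arch down to the heart apex. On synthetic
#' phantoms the aortic-arch landmark is the superior extent of the
#' heart-plus-great-vessel mask. Ranges snap outward to whole slices, since
#' reconstructed CT exists as whole slices.
#'
#' @param masks A `voxdose_masks` with the required organs (`lungs` for
#'   chest; `heart` for cardiac).
#' @param protocol_name `"chest"` or `"cardiac"`.
#' @param model The `voxdose_model` the masks belong to (for slice
#'   geometry); if omitted, mask spacing/origin are used.
#' @return A `voxdose_zrange` covering whole slices.
#' @export
scan_range_for <- function(masks, protocol_name = c("chest", "cardiac"),
                           model = NULL) {
  protocol_name <- match.arg(protocol_name)
  need <- if (protocol_name == "chest") "lungs" else "heart"
  if (!need %in% names(masks$masks)) {
    stop("the ", protocol_name, " scan range needs a '", need, "' mask")
  }
  m <- masks$masks[[need]]
  ks <- which(apply(m, 3, any))
  dz <- masks$spacing[3]
  z0 <- masks$origin[3]
  z_range(z0 + (min(ks) - 1) * dz, z0 + max(ks) * dz)
}

#' Crop a voxel model and its masks to a z range
#'
#' Keeps exactly the whole slices that intersect the half-open range. The
#' `total_volumes` of the mask set are retained unchanged from the
#' whole-body model -- they are what makes the entire-organ-volume rescale
#' of a truncated model possible.
#'
#' @param model A `voxdose_model`.
#' @param masks The aligned `voxdose_masks`.
#' @param z A `voxdose_zrange` within the model extent.
#' @return A list with cropped `model` and `masks`.
#' @export
crop_to_range <- function(model, masks, z) {
  stopifnot(inherits(model, "voxdose_model"), inherits(z, "voxdose_zrange"))
  check_alignment(model, masks)
  nz <- dim(model$hu)[3]
  dz <- model$spacing[3]
  z0 <- model$origin[3]
  k <- which(z0 + (seq_len(nz) - 1) * dz < z$z_end &
               z0 + seq_len(nz) * dz > z$z_start)
  if (length(k) == 0) {
    stop("z range [", z$z_start, ", ", z$z_end,
         ") does not intersect the model extent")
  }
  new_model <- new_voxel_model(model$hu[, , k, drop = FALSE], model$spacing,
                               c(model$origin[1:2], z0 + (min(k) - 1) * dz),
                               model$sex, model$height, model$weight)
  new_masks <- structure(list(
    masks = lapply(masks$masks, function(m) m[, , k, drop = FALSE]),
    total_volumes = masks$total_volumes,
    spacing = masks$spacing,
    origin = c(masks$origin[1:2], z0 + (min(k) - 1) * dz)),
    class = "voxdose_masks")
  list(model = new_model, masks = new_masks)
}

#' Water-equivalent diameter over a scan range
#'
#' Per slice, the water-equivalent area is
#' \eqn{A_w = \sum_{pixels} (HU/1000 + 1) a_{pixel}} over in-body pixels
#' (HU above -950), and \eqn{D_w = 2\sqrt{A_w/\pi}}; the returned value is
#' the mean of \eqn{D_w} over the slices in the range. This is the standard
#' patient-size metric used by size-specific dose estimates.
#'
#' @param model A `voxdose_model`.
#' @param z A `voxdose_zrange`; defaults to the full model extent.
#' @return Mean water-equivalent diameter in mm.
#' @export
water_equivalent_diameter <- function(model, z = NULL) {
  stopifnot(inherits(model, "voxdose_model"))
  nz <- dim(model$hu)[3]
  dz <- model$spacing[3]
  z0 <- model$origin[3]
  if (is.null(z)) z <- z_range(z0, z0 + nz * dz)
  k <- which(z0 + (seq_len(nz) - 1) * dz < z$z_end &
               z0 + seq_len(nz) * dz > z$z_start)
  if (length(k) == 0) stop("z range does not intersect the model extent")
  apix <- model$spacing[1] * model$spacing[2]
  dw <- vapply(k, function(kk) {
    sl <- model$hu[, , kk]
    body <- sl > -950
    if (!any(body)) return(NA_real_)
    aw <- sum((sl[body] / 1000 + 1) * apix)
    2 * sqrt(aw / pi)
  }, numeric(1))
  if (all(is.na(dw))) stop("no in-body pixels in the requested slice range")
  mean(dw, na.rm = TRUE)
}
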