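#' Per-slice dose profile of an organ
#'
#' Overlays an organ mask on a dose grid slice by slice: contour area
#' \eqn{A_i} (voxel count times pixel area), mean dose within the contour
#' \eqn{M_i}, and fractional area \eqn{f_i = A_i / \sum A_i}. This is the
#' input to the organ-dose aggregation of [organ_dose()].
#'
#' @param dose A `voxdose_dose` grid.
#' @param mask Logical array of the same shape.
#' @return A `voxdose_slice_profile` tibble with columns `slice`, `z`
#'   (slice centre, mm), `area_mm2`, `mean_dose`, `frac`.
#' @export
slice_profile <- function(dose, mask) {
  stopifnot(inherits(dose, "voxdose_dose"), is.logical(mask))
  if (!identical(dim(mask), dim(dose$dose))) {
    stop(sprintf("mask shape %s does not match dose grid %s",
                 paste(dim(mask), collapse = "x"),
                 paste(dim(dose$dose), collapse = "x")))
  }
  if (!any(mask)) stop("empty organ mask")
  ks <- which(apply(mask, 3, any))
  apix <- dose$spacing[1] * dose$spacing[2]
  area <- vapply(ks, function(k) sum(mask[, , k]) * apix, numeric(1))
  md <- vapply(ks, function(k) mean(dose$dose[, , k][mask[, , k]]),
               numeric(1))
  out <- tibble::tibble(
    slice = ks,
    z = dose$origin[3] + (ks - 0.5) * dose$spacing[3],
    area_mm2 = area,
    mean_dose = md,
    frac = area / sum(area))
  class(out) <- c("voxdose_slice_profile", class(out))
  out
}

#' Organ dose from a slice profile
#'
#' The organ dose is the fractional-area-weighted sum of per-slice mean
#' doses, \eqn{D_T = \sum_i f_i M_i}. With uniform slice thickness this
#' equals the plain voxel mean of dose over the organ mask.
#'
#' @param profile A `voxdose_slice_profile`.
#' @return Organ dose, same unit as the dose grid.
#' @export
#' @examples
#' # two slices with areas 100 and 300 mm2 and mean doses 2 and 4 mGy
#' # give f = (0.25, 0.75) and D = 3.5 mGy
organ_dose <- function(profile) {
  stopifnot(inherits(profile, "voxdose_slice_profile") ||
              all(c("frac", "mean_dose") %in% names(profile)))
  if (abs(sum(profile$frac) - 1) > 1e-12) {
    stop("slice area fractions must sum to 1")
  }
  sum(profile$frac * profile$mean_dose)
}

#' Rescale a truncated-model organ dose to the entire organ volume
#'
#' A voxel model limited to the scan range only contains part of some
#' organs; the dose computed on the contained part overestimates the mean
#' dose to the whole organ. Spreading the absorbed energy over the whole
#' organ mass (zero dose assumed outside the modelled volume) gives
#' \eqn{D_{full} = D_T V_{in} / V_{total}}.
#'
#' @param d_t Organ dose from the truncated model.
#' @param v_in Organ volume present in the truncated model, m^3.
#' @param v_total Whole-body organ volume, m^3.
#' @return Rescaled dose \eqn{D_{full} \le D_T}.
#' @export
rescale_full_volume <- function(d_t, v_in, v_total) {
  if (v_in <= 0) {
    stop("organ absent from the truncated model (v_in = 0); dose undefined")
  }
  if (v_in > v_total * (1 + 1e-9)) {
    stop("in-model organ volume exceeds the whole-body volume")
  }
  d_t * v_in / v_total
}

#' Rescale a truncated-model organ dose to the ICRP reference volume
#'
#' \eqn{D_{T,ref} = D_T V_T / V_{T,ref}} with \eqn{V_T} the organ volume
#' present in the voxel model and \eqn{V_{T,ref}} the ICRP reference organ
#' volume -- the correction available when the patient's whole-body organ
#' volume is unknown.
#'
#' @param d_t Organ dose from the truncated model.
#' @param v_in Organ volume present in the voxel model, m^3.
#' @param v_ref ICRP reference organ volume, m^3.
#' @return Rescaled dose.
#' @export
rescale_reference_volume <- function(d_t, v_in, v_ref) {
  if (!is.numeric(v_ref) || v_ref <= 0) stop("reference volume must be positive")
  d_t * v_in / v_ref
}

#' Reference organ volume from mass and density
#'
#' @param mass Organ mass, kg (> 0).
#' @param density Organ density, kg/m^3 (> 0).
#' @return Volume in m^3.
#' @export
#' @examples
#' reference_volume(1.800, 1060)  # reference adult male liver, 1.70e-3 m3
reference_volume <- function(mass, density) {
  if (any(mass <= 0) || any(density <= 0)) {
    stop("mass and density must be positive")
  }
  mass / density
}

# ICRP reference organ masses (Publication 89) and densities (110/145) for
# the reference adult male (1.76 m, 73 kg) and female (1.63 m, 60 kg).
# Ribs and spine masses derive from fractions of the total skeletal mass
# (male 10.5 kg, female 7.8 kg): ribs 7% / 5.6%, spine 19% / 20.4%.
icrp_reference_data <- function() {
  skeletal <- c(male = 10.5, female = 7.8)
  frac <- list(ribs = c(male = 0.07, female = 0.056),
               spine = c(male = 0.19, female = 0.204))
  tibble::tibble(
    organ = rep(c("breast", "liver", "lungs", "kidneys", "oesophagus",
                  "ribs", "thyroid", "spine"), 2),
    sex = rep(c("male", "female"), each = 8),
    mass_kg = c(0.025, 1.800, 1.200, 0.217, 0.040,
                frac$ribs[["male"]] * skeletal[["male"]], 0.020,
                frac$spine[["male"]] * skeletal[["male"]],
                0.500, 1.400, 0.950, 0.193, 0.035,
                frac$ribs[["female"]] * skeletal[["female"]], 0.017,
                frac$spine[["female"]] * skeletal[["female"]]),
    density_kg_m3 = c(1020, 1060, 415, 1050, 1037, 1350, 1051, 1350,
                      1020, 1060, 413, 1050, 1036, 1350, 1051, 1350))
}

#' ICRP reference organ table
#'
#' Reference organ masses (ICRP 89), densities (ICRP 110/145) and the
#' derived volumes for the reference adult male (1.76 m, 73 kg) or female
#' (1.63 m, 60 kg). Ribs and spine masses are computed from their fractions
#' of the total skeletal mass. Organs without a reference entry (the heart
#' in this study design, which is always fully in the field of view) are
#' absent from the table.
#'
#' @param sex `"male"` or `"female"`.
#' @return A `voxdose_reference_table` tibble: `organ`, `mass_kg`,
#'   `density_kg_m3`, `volume_m3`.
#' @export
#' @examples
#' reference_organ_table("male")
reference_organ_table <- function(sex = c("male", "female")) {
  sex <- match.arg(sex)
  d <- icrp_reference_data()
  d <- d[d$sex == sex, c("organ", "mass_kg", "density_kg_m3")]
  d$volume_m3 <- reference_volume(d$mass_kg, d$density_kg_m3)
  class(d) <- c("voxdose_reference_table", class(d))
  d
}

# ICRP 103 tissue weighting factors for the organs this pipeline models.
# (The full ICRP set also covers gonads, colon, stomach, bone marrow, etc.;
# sums over a subset are therefore partial by construction.)
#' ICRP 103 tissue weighting factors
#' @return Named numeric vector of weights for the modelled organs.
#' @export
icrp103_weights <- function() {
  c(breast = 0.12, lungs = 0.12, liver = 0.04, oesophagus = 0.04,
    thyroid = 0.04, ribs = 0.01, spine = 0.01, kidneys = 0.12 / 13,
    heart = 0.12 / 13)
}

#' Tissue-weighted (effective) dose from organ doses
#'
#' The weighted sum \eqn{\sum_T w_T D_T} with ICRP 103 tissue weighting
#' factors (photon radiation weighting factor 1). A sum over a subset of
#' the ICRP tissues is flagged partial.
#'
#' @param doses Named numeric vector of organ doses (mGy).
#' @param weights Named numeric vector of tissue weighting factors
#'   (default [icrp103_weights()] restricted to the supplied organs).
#' @return The weighted sum, with attributes `partial` (logical) and
#'   `weight_sum`.
#' @export
effective_dose <- function(doses, weights = icrp103_weights()) {
  stopifnot(!is.null(names(doses)))
  if (any(weights < 0)) stop("tissue weighting factors must be non-negative")
  use <- intersect(names(doses), names(weights))
  if (length(use) == 0) stop("no supplied organ has a tissue weighting factor")
  out <- sum(weights[use] * doses[use])
  attr(out, "partial") <- length(use) < length(weights) ||
    sum(weights[use]) < 1
  attr(out, "weight_sum") <- sum(weights[use])
  out
}

#' Organ dose report for a dose grid and mask set
#'
#' The full per-organ dosimetry table: the slice-profile organ dose `d_t`,
#' the in-grid and whole-body organ volumes, the entire-organ-volume
#' rescaled dose `d_full`, and -- where a reference volume exists -- the
#' ICRP reference-volume rescaled dose `d_refvol`. Organs whose mask is
#' empty in the (possibly cropped) grid are reported absent with zero
#' rescaled doses, the convention for organs wholly outside the scan range.
#'
#' @param dose A `voxdose_dose` grid.
#' @param masks A `voxdose_masks` aligned to it (its `total_volumes` are
#'   the whole-body volumes even after cropping).
#' @param reference A `voxdose_reference_table` or `NULL`.
#' @return A tibble: `organ`, `d_t`, `v_in_m3`, `v_total_m3`, `d_full`,
#'   `v_ref_m3`, `d_refvol`, `absent`.
#' @export
organ_dose_table <- function(dose, masks, reference = NULL) {
  stopifnot(inherits(dose, "voxdose_dose"), inherits(masks, "voxdose_masks"))
  v_in <- in_grid_volumes(masks)
  rows <- lapply(names(masks$masks), function(nm) {
    absent <- v_in[[nm]] == 0
    d_t <- if (absent) NA_real_ else {
      organ_dose(slice_profile(dose, masks$masks[[nm]]))
    }
    v_tot <- masks$total_volumes[[nm]]
    d_full <- if (absent) 0 else rescale_full_volume(d_t, v_in[[nm]], v_tot)
    v_ref <- NA_real_
    d_refvol <- NA_real_
    if (!is.null(reference) && nm %in% reference$organ) {
      v_ref <- reference$volume_m3[match(nm, reference$organ)]
      d_refvol <- if (absent) 0 else {
        rescale_reference_volume(d_t, v_in[[nm]], v_ref)
      }
    }
    tibble::tibble(organ = nm, d_t = d_t, v_in_m3 = v_in[[nm]],
                   v_total_m3 = v_tot, d_full = d_full, v_ref_m3 = v_ref,
                   d_refvol = d_refvol, absent = absent)
  })
  dplyr::bind_rows(rows)
}
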