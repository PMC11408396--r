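sidecar_path <- function(path) paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")

#' Read and write voxel models as NIfTI with a JSON sidecar
#'
#' The HU grid goes into a NIfTI file (spacing in its header); patient
#' metadata (sex, height, weight) and the grid origin go into a JSON
#' sidecar next to it. Round trips are lossless up to floating-point
#' representation.
#'
#' @param model A `voxdose_model`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `write_voxel_model()` returns `path` invisibly;
#'   `read_voxel_model()` returns a `voxdose_model`.
#' @export
write_voxel_model <- function(model, path) {
  stopifnot(inherits(model, "voxdose_model"))
  img <- RNifti::asNifti(model$hu, pixdim = model$spacing)
  RNifti::writeNifti(img, path)
  jsonlite::write_json(
    list(type = "voxdose_model", sex = model$sex, height = model$height,
         weight = model$weight, origin = model$origin,
         spacing = model$spacing),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_voxel_model
#' @export
read_voxel_model <- function(path) {
  img <- RNifti::readNifti(path)
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  new_voxel_model(array(as.numeric(img), dim = dim(img)),
                  spacing = as.numeric(meta$spacing),
                  origin = as.numeric(meta$origin),
                  sex = meta$sex, height = meta$height, weight = meta$weight)
}

#' Read and write organ mask sets
#'
#' Masks are stored as one integer label volume (0 = background) plus a
#' JSON sidecar mapping labels to organ names and carrying the whole-body
#' `total_volumes`. Because masks are non-overlapping by construction a
#' single label volume is lossless.
#'
#' @param masks A `voxdose_masks`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param model Optional `voxdose_model` to check alignment against on read.
#' @return `write_masks()` returns `path` invisibly; `read_masks()` a
#'   `voxdose_masks`.
#' @export
write_masks <- function(masks, path) {
  stopifnot(inherits(masks, "voxdose_masks"))
  lab <- array(0L, dim = dim(masks$masks[[1]]))
  for (i in seq_along(masks$masks)) lab[masks$masks[[i]]] <- i
  img <- RNifti::asNifti(lab, pixdim = masks$spacing)
  RNifti::writeNifti(img, path)
  jsonlite::write_json(
    list(type = "voxdose_masks", labels = names(masks$masks),
         total_volumes = as.list(masks$total_volumes),
         origin = masks$origin, spacing = masks$spacing),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_masks
#' @export
read_masks <- function(path, model = NULL) {
  img <- RNifti::readNifti(path)
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  lab <- array(as.integer(img), dim = dim(img))
  masks <- lapply(seq_along(meta$labels), function(i) lab == i)
  names(masks) <- meta$labels
  out <- structure(list(masks = masks,
                        total_volumes = unlist(meta$total_volumes),
                        spacing = as.numeric(meta$spacing),
                        origin = as.numeric(meta$origin)),
                   class = "voxdose_masks")
  if (!is.null(model)) check_alignment(model, out)
  out
}

#' Read and write dose grids
#'
#' The dose array goes into NIfTI; the uncertainty array, unit, photon
#' budget and seed go into the JSON sidecar (uncertainty as a flat vector).
#'
#' @param grid A `voxdose_dose`.
#' @param path Output path.
#' @return `write_dose_grid()` returns `path` invisibly; `read_dose_grid()`
#'   a `voxdose_dose`.
#' @export
write_dose_grid <- function(grid, path) {
  stopifnot(inherits(grid, "voxdose_dose"))
  img <- RNifti::asNifti(grid$dose, pixdim = grid$spacing)
  RNifti::writeNifti(img, path)
  jsonlite::write_json(
    list(type = "voxdose_dose", unit = grid$unit,
         n_photons = grid$n_photons, seed = grid$seed,
         origin = grid$origin, spacing = grid$spacing,
         uncertainty = as.numeric(grid$uncertainty)),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_dose_grid
#' @export
read_dose_grid <- function(path) {
  img <- RNifti::readNifti(path)
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  dims <- dim(img)
  new_dose_grid(array(as.numeric(img), dims),
                array(as.numeric(meta$uncertainty), dims),
                spacing = as.numeric(meta$spacing),
                origin = as.numeric(meta$origin),
                n_photons = meta$n_photons,
                seed = if (is.null(meta$seed)) NA_integer_ else meta$seed,
                unit = meta$unit)
}

read_numeric_csv <- function(path, cols) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(cols %in% names(d))) {
    stop("malformed CSV ", path, ": expected columns ",
         paste(cols, collapse = ", "))
  }
  for (cn in cols) {
    v <- suppressWarnings(as.numeric(d[[cn]]))
    bad <- which(is.na(v) & !is.na(d[[cn]]))
    if (length(bad) > 0) {
      stop(sprintf("non-numeric value in column '%s' of %s at line %d",
                   cn, path, bad[1] + 1L))
    }
    d[[cn]] <- v
  }
  tibble::as_tibble(d[cols])
}

#' Read beam and protocol tables from CSV
#'
#' `read_tcm_csv()`: per-slice tube current table (`z` mm, `mas`);
#' `read_spectrum_csv()`: spectrum (`energy_kev`, `weight`);
#' `read_bowtie_profile_csv()`: lateral kerma profile (`distance_cm`,
#' `relative_kerma`). Malformed numeric cells are reported with their line
#' number.
#'
#' @param path CSV path.
#' @return A tibble (a `voxdose_spectrum` for the spectrum reader).
#' @export
read_tcm_csv <- function(path) read_numeric_csv(path, c("z", "mas"))

#' @rdname read_tcm_csv
#' @export
read_spectrum_csv <- function(path) {
  d <- read_numeric_csv(path, c("energy_kev", "weight"))
  new_spectrum(d$energy_kev, d$weight)
}

#' @rdname read_tcm_csv
#' @export
read_bowtie_profile_csv <- function(path) {
  read_numeric_csv(path, c("distance_cm", "relative_kerma"))
}

#' Load a study configuration
#'
#' A single YAML file describing a run: protocol parameters, engine
#' parameters (photon budget, cutoff, batches, seed) and cohort parameters
#' (n phantoms, jitter). Unknown keys are kept as-is; referenced file paths
#' are checked for existence.
#'
#' @param path YAML path.
#' @return A named list with defaults filled in.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  defaults <- list(protocol = "chest", tube_kv = 120, pitch = 0.7,
                   collimation = 19.2, scan_fov = 500,
                   focus_isocenter_distance = 595, overscan = 12,
                   photon_budget = 1e6, energy_cutoff = 10, n_batches = 10,
                   seed = 1L, n_phantoms = 5, jitter = 0.04,
                   grid_shape = c(64, 64, 180), spacing = c(4, 4, 6),
                   use_tcm = TRUE)
  cfg <- utils::modifyList(defaults, cfg)
  for (key in c("spectrum_csv", "bowtie_csv", "tcm_csv", "model_nii",
                "masks_nii")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]])) {
      stop("config references a missing file: ", key, " = ", cfg[[key]])
    }
  }
  cfg
}
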