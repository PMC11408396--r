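Package: voxdose
Title: Patient-Specific CT Organ Dose Simulation on Voxel Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Desk-scale Monte Carlo simulation of helical CT examinations on
    voxelized anatomical models, with organ dose aggregation from segmentation
    masks. Generates synthetic whole-body adult phantoms with labelled organ
    masks, models the CT source (equivalent x-ray spectrum matched to a first
    half-value layer, bowtie filter fitted from a lateral air-kerma profile,
    helical trajectory with tube current modulation), transports photons by
    Woodcock tracking with energy-deposition scoring, and quantifies how
    truncated voxel models, scatter from the rest of the body, helical
    overscan, and ICRP reference organ volumes affect organ dose estimates
    for chest and cardiac CT protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    RNifti,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
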