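Package: capria
Title: 4D Combined Angiography and Perfusion ASL: Simulation, Reconstruction and Repeatability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for 4D combined angiography and perfusion using radial
    imaging and arterial spin labeling (CAPRIA). Generates 3D golden-means
    ("koosh ball") radial spoke schedules, models the PCASL angiographic and
    Buxton perfusion difference signals under constant or quadratic
    variable-flip-angle excitation, optimizes flip-angle schedules over
    physiological transit-time ranges, simulates seeded multi-coil radial
    k-space from a dynamic digital phantom, reconstructs flexible-resolution
    dynamic difference images with CG-SENSE and locally-low-rank (POGM with
    cycle spinning) solvers built on a Kaiser-Bessel gridding non-uniform FFT,
    and quantifies image quality by split-scan repeatability (Pearson r,
    Fisher z) with empirical split-correction utilities.
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
    optparse
Config/testthat/edition: 3
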