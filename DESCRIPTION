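Package: motornet
Title: Graph-Theoretic Analysis of the Resting-State Motor Execution Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for graph-theoretic analysis of the
    21-node motor execution network from resting-state fMRI: simulation of
    synthetic two-group cohorts with planted connectivity effects, signal
    conditioning (detrending, Friston-24 and tissue nuisance regression,
    framewise-displacement spike regression, band-pass filtering), sphere-ROI
    network construction with significance-thresholded binary and weighted
    connectivity matrices, small-world and efficiency metrics normalized
    against degree-preserving rewired null ensembles, network-based-statistic
    (NBS) permutation inference with family-wise error control, and
    covariate-adjusted group statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    RNifti,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
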