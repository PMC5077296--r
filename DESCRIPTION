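Package: sparsegc
Title: Sparse Granule-Cell Activity Analysis for Juxtacellular Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for juxtacellular recordings and morphological
    reconstructions of dentate gyrus granule cells: spike-shoulder detection on
    average spike waveforms, waveform-based cell-class assignment (small
    feed-forward network with ADASYN class balancing and leave-one-out
    cross-validation), spatial rate maps with place-field segmentation and
    Skaggs spatial information, SWC-based dendritic branch-order morphometry,
    and a sparse (elastic-net) logistic classifier of active versus silent
    granule cells with nested leave-one-out cross-validation, the 1-SE rule and
    a label-permutation significance test. Includes synthetic generators for
    spike waveforms, open-field and annular-maze sessions with
    inhomogeneous-Poisson place-field spiking, and stochastic dendritic trees,
    so every stage of the pipeline can be exercised and validated without raw
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet
Config/testthat/edition: 3
RoxygenNote: 7.3.3
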