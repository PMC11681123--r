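Package: ribregions
Title: Regionalization Analysis of Axial Skeletons from 3D Rib Landmarks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies anatomical regionalization of the dorsal ribcage from
    per-rib three-dimensional landmark configurations. Provides TPS input and
    output, axial subsampling of elongate rib series, generalized Procrustes
    superimposition, principal-component shape spaces, segmented linear
    regression with corrected-AIC model selection and Akaike-weight region
    scores, decomposition of region boundaries into allometric and
    size-independent components, axial heterogeneity and disparity statistics
    with permutation tests, minimum-branch-length time-scaling of phylogenies
    from first-appearance dates, and Brownian-motion maximum-likelihood
    ancestral-state reconstruction. Includes a synthetic-data generator with
    known ground truth so every pipeline stage is testable without scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    phytools,
    vegan,
    withr
Config/testthat/edition: 3
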