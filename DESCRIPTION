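Package: budprofiler
Title: Unsupervised Profiling of Yeast Protein Expression from Two-Channel Micrographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for unsupervised analysis of budding-yeast
    protein expression in two-channel (RFP cell marker + GFP tag) fluorescence
    micrographs. Cells are segmented with a pseudo-2D hidden Markov model,
    clumps are split by robust ellipse regression combined with watershed
    basins, and every identified object receives a probabilistic cell
    confidence from a Normal-versus-uniform mixture over four shape and
    intensity quality measures. Six interpretable expression features per cell
    (a size-normalized GFP/RFP intensity ratio and five morphological
    log-ratio distances) are turned into cell-stage "time profiles" via
    confidence-weighted local regression against bud size, and profiles are
    grouped with maximum-likelihood agglomerative hierarchical clustering,
    compared with Bhattacharyya distances, and scored for annotation
    enrichment with hypergeometric scans and topology-preserving permutation
    nulls. A synthetic-scene generator with full ground truth makes every
    stage testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
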