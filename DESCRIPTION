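Package: merscreen
Title: Desk-Scale Simulation and Analysis of Image-Based Pooled CRISPR
    Screens with Error-Robust Barcoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for designing and analysing multiplexed error-robust
    FISH (MERFISH) screens read out by rolling-circle-amplified padlock
    probes. Builds constant-weight Hamming-distance-4 codebooks with
    single-bit error correction, designs ligatable padlock encoding probes
    under melting-temperature, GC, specificity and contaminant-homology
    filters, simulates ground-truthed zonated liver tissue carrying
    Poisson low-MOI CRISPR perturbations together with rendered bit-image
    stacks and Flex-style UMI tables, decodes amplicon spots with a
    blank-trained misidentification filter at an adaptive false-positive
    threshold, calls per-cell perturbations from imaging and sequencing
    counts, and provides the screen statistics used for such data:
    control-referenced z-scoring, energy-distance permutation tests,
    rank-sum differential expression, pseudobulk correlations, gene-set
    and zonation scores, and data-driven tissue zone segmentation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    Biostrings,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
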