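Package: refstab
Title: Reference Gene Stability Analysis for RT-qPCR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects stable reference (housekeeping) genes from RT-qPCR
    quantification-cycle (Ct) data. Implements the three classical stability
    algorithms - geNorm (pairwise-variation M values, stepwise elimination and
    the V(n/n+1) criterion for the optimal number of reference genes),
    NormFinder (model-based intra/intergroup variance decomposition yielding a
    stability value S) and BestKeeper (SD/CV of raw Ct, index and
    correlations) - together with a comprehensive rank-sum ranking that
    combines the three, 2^-ddCt relative quantification of a target gene under
    alternative reference sets, and a seeded synthetic Ct-data generator with
    known ground-truth stability structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
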