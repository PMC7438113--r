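Package: germchrom
Title: Quantifying Polycomb Domain Remodeling in the Drosophila Germline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how H3K27me3 chromatin is redistributed
    from a broad, non-canonical pattern in germline stem cells into focused
    Polycomb (PcG) domains during nurse-cell differentiation. Implements
    four-class chromatin-state simplification, overlapping genomic bins with
    single-class assignment and PRE flagging, spike-in normalized per-bin
    IP/Input ChIP enrichment, domain-level enrichment and sharing calls,
    TPM and median-of-ratios expression normalization with class-stratified
    fold-change trajectories, and a heat-shock reporter induction statistic
    with genotype contrasts. Ships a seeded synthetic-data generator with
    known ground truth (per-class enrichment multipliers, spike-in admixture,
    negative-binomial counts, noised fluorescence) so that every analysis
    stage can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    IRanges,
    S4Vectors,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
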