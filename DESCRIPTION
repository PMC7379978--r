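Package: dietrep
Title: Replication Effects in DNA Metabarcoding Diet Analysis
Version: 0.1.0
Authors@R:
    person("dietrep", "developers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how technical (PCR) and biological
    (sample) replication affect diet descriptors estimated from DNA
    metabarcoding presence/absence data. Implements a hierarchical
    detection data model (individual x pellet x PCR x taxon), a per-PCR
    relative-abundance read filter, per-individual sample-based
    rarefaction and Chao2 accumulation curves, Monte-Carlo pellet
    subsampling of frequency-of-occurrence (FO) estimates with error
    curves, pooled-versus-separate-sample comparisons, a three-level
    nested PERMANOVA with randomized residual permutation (RRPP)
    significance, beta-regression modelling of FO error rates, and a
    synthetic hierarchical data generator with ground truth for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
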