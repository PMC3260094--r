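Package: triadscan
Title: Family-Based Haplotype Association Analysis with Case-Parent Triads
    and Control-Mother Dyads
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quality control, likelihood-based estimation and candidate-gene
    scanning for family-based genetic association studies of birth outcomes.
    Implements a full-likelihood model that jointly estimates haplotype
    population frequencies and fetal and maternal relative risks from
    case-parent triads, alone or combined with control-mother dyads (the
    hybrid design), under random mating, mating symmetry and a multiplicative
    gene-dose model.  Includes sliding-window haplotype scans with gene-level
    min-p bootstrap p-values, Fisher-combination pathway tests against a
    candidate-gene resampling background, QQ-plot summaries with exact
    pointwise beta envelopes, and a synthetic-data generator that emulates
    the triad/dyad family structure so every stage of the pipeline can be
    validated against known truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ggplot2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
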