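Package: refstab
Title: Discovery and Validation of Invariant Reference Genes in Grouped
    Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identifies candidate endogenous reference (housekeeping) genes
    from grouped, normalized log2 expression matrices by a two-step
    probabilistic selection: a false-discovery-rate-corrected pairwise
    nondiscrimination filter followed by variability ranking, an intensity
    window, and an unadjusted t-test stability criterion. Provides
    validation-stage statistics for targeted assays on threshold-cycle (Ct)
    and median-fluorescence-intensity (MFI) scales, including limit-of-
    detection filtering, fold differences, exact Wilcoxon rank-sum and
    signed-rank tests, Kruskal-Wallis with Dunn's post hoc comparisons,
    all-pairs fold-difference and p-value comparison matrices for external
    grouped records, and seeded synthetic-data generators with planted
    ground truth for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
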