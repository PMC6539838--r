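#' Configuration of the reference-gene discovery walk
#'
#' Bundles every threshold of the two-step selection. Defaults reproduce
#' the published screen: pairwise nondiscrimination at FDR-adjusted
#' `alpha = 0.05`, retention of the `n_lowvar = 5000` lowest-variability
#' genes, a closed mean-intensity window of \[4, 11\] log2 units, a
#' stability criterion of all three unadjusted pairwise t-test p-values
#' above 0.5, and a target of `k_candidates = 5` genes.
#'
#' @param alpha significance level for the FDR-corrected nondiscrimination
#'   filter (a gene is discriminatory when any adjusted pairwise p <= alpha).
#' @param n_lowvar number of lowest-pooled-sd genes retained.
#' @param intensity_window closed interval (length-2 numeric) that every
#'   group mean log2 intensity must fall inside; both bounds inclusive.
#' @param stability_p lower bound that all three unadjusted pairwise
#'   p-values must exceed (strictly) for a gene to count as stable.
#' @param k_candidates number of candidates sought by the ascending-
#'   variability walk.
#' @param borderline_band half-open p-value interval `[lo, hi)` flagged
#'   "borderline"; a gene with exactly one borderline p and the others above
#'   `stability_p` is flagged (not selected) for manual adjudication.
#' @param ttest_flavor `"pooled"` (default, classical ANOVA-contrast
#'   behaviour) or `"welch"`.
#' @param fdr_scope `"per_pairing"` (BH across genes separately within each
#'   pairwise comparison; default) or `"omnibus"` (one BH across all genes
#'   and pairings jointly).
#' @return an object of class `discovery_config`.
#' @export
discovery_config <- function(alpha = 0.05,
                             n_lowvar = 5000L,
                             intensity_window = c(4, 11),
                             stability_p = 0.5,
                             k_candidates = 5L,
                             borderline_band = c(0.45, 0.5),
                             ttest_flavor = c("pooled", "welch"),
                             fdr_scope = c("per_pairing", "omnibus")) {
  ttest_flavor <- match.arg(ttest_flavor)
  fdr_scope <- match.arg(fdr_scope)
  stopifnot(alpha > 0, alpha < 1,
            stability_p > 0, stability_p < 1,
            length(intensity_window) == 2L,
            intensity_window[1L] < intensity_window[2L],
            length(borderline_band) == 2L,
            borderline_band[1L] <= borderline_band[2L],
            k_candidates >= 1L, n_lowvar >= k_candidates)
  structure(list(alpha = alpha,
                 n_lowvar = as.integer(n_lowvar),
                 intensity_window = as.numeric(intensity_window),
                 stability_p = stability_p,
                 k_candidates = as.integer(k_candidates),
                 borderline_band = as.numeric(borderline_band),
                 ttest_flavor = ttest_flavor,
                 fdr_scope = fdr_scope),
            class = "discovery_config")
}

#' @export
print.discovery_config <- function(x, ...) {
  cat("discovery_config:\n")
  cat(sprintf("  nondiscrimination: any BH-adjusted p <= %g (%s, %s t)\n",
              x$alpha, x$fdr_scope, x$ttest_flavor))
  cat(sprintf("  variability cut:   %d lowest pooled-sd genes\n", x$n_lowvar))
  cat(sprintf("  intensity window:  [%g, %g] log2 (all group means)\n",
              x$intensity_window[1L], x$intensity_window[2L]))
  cat(sprintf("  stability:         all raw p > %g; borderline [%g, %g)\n",
              x$stability_p, x$borderline_band[1L], x$borderline_band[2L]))
  cat(sprintf("  candidates sought: %d\n", x$k_candidates))
  invisible(x)
}
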