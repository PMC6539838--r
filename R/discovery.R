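## Two-step probabilistic selection of candidate reference genes from a
## three-group expression matrix:
##   1. nondiscrimination: drop genes where any FDR-adjusted pairwise t-test
##      p-value is <= alpha,
##   2. variability: keep the n_lowvar genes with lowest pooled sd,
##   3. intensity window: keep genes whose every group mean lies in [4, 11],
##   4. stability: walk the shortlist in ascending pooled sd, collecting
##      genes with all three unadjusted pairwise p-values > 0.5, until
##      k candidates are found.

## vectorized per-gene group means/variances and pairwise t p-values
.gene_group_stats <- function(values, design) {
  gs <- group_samples(design)
  groups <- design$group_order
  means <- vars <- matrix(NA_real_, nrow(values), length(groups),
                          dimnames = list(rownames(values), groups))
  for (g in groups) {
    sub <- values[, gs[[g]], drop = FALSE]
    m <- rowMeans(sub)
    means[, g] <- m
    vars[, g] <- rowSums((sub - m)^2) / (ncol(sub) - 1L)
  }
  n <- vapply(gs, length, integer(1L))
  list(means = means, vars = vars, n = n)
}

.pairings <- function(groups) {
  pr <- utils::combn(groups, 2L)
  stats::setNames(lapply(seq_len(ncol(pr)), function(i) pr[, i]),
                  paste(pr[1L, ], pr[2L, ], sep = "_vs_"))
}

## vectorized two-sided pairwise t tests over all genes; returns matrix
## genes x pairings of raw p-values
.pairwise_t_matrix <- function(gstats, flavor) {
  prs <- .pairings(colnames(gstats$means))
  p <- matrix(NA_real_, nrow(gstats$means), length(prs),
              dimnames = list(rownames(gstats$means), names(prs)))
  for (nm in names(prs)) {
    a <- prs[[nm]][1L]; b <- prs[[nm]][2L]
    na <- gstats$n[[a]]; nb <- gstats$n[[b]]
    dm <- gstats$means[, a] - gstats$means[, b]
    va <- gstats$vars[, a]; vb <- gstats$vars[, b]
    if (flavor == "pooled") {
      vp <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
      se <- sqrt(vp * (1 / na + 1 / nb))
      df <- rep(na + nb - 2, length(dm))
    } else {
      se <- sqrt(va / na + vb / nb)
      df <- (va / na + vb / nb)^2 /
        ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    }
    pv <- 2 * stats::pt(-abs(dm / se), df)
    # degenerate rows: zero variance in both groups
    zero <- se == 0
    pv[zero & dm == 0] <- 1
    pv[zero & dm != 0] <- .Machine$double.xmin
    p[, nm] <- pmin(pv, 1)
  }
  p
}

#' Per-gene pairwise nondiscrimination statistics
#'
#' For every complete gene, performs the three two-sample t tests between
#' the groups, adjusts the p-values by Benjamini-Hochberg (per pairing
#' across genes, or jointly, per `config$fdr_scope`), and flags a gene
#' discriminatory when any adjusted p-value is at or below `config$alpha`.
#'
#' @param x an [expr_matrix()] on the log2 intensity scale.
#' @param design a [group_design()] with exactly three groups, each with at
#'   least two samples.
#' @param config a [discovery_config()].
#' @return data frame with one row per complete gene: `gene`, `pooled_sd`,
#'   `mean_<group>` columns, `p_<pairing>` raw and `padj_<pairing>` adjusted
#'   p-values, and logical `discriminatory`.
#' @export
nondiscriminatory_filter <- function(x, design, config = discovery_config()) {
  stopifnot(inherits(x, "expr_matrix"), inherits(design, "group_design"),
            inherits(config, "discovery_config"))
  if (length(design$group_order) != 3L)
    stop("discovery requires exactly three groups, got ",
         length(design$group_order), call. = FALSE)
  gs <- group_samples(design)
  if (any(vapply(gs, length, integer(1L)) < 2L))
    stop("every group needs at least 2 samples", call. = FALSE)
  miss <- setdiff(unlist(gs), colnames(x))
  if (length(miss))
    stop("design samples absent from matrix: ",
         paste(miss, collapse = ", "), call. = FALSE)
  v <- unclass(x)[, unlist(gs), drop = FALSE]
  v <- v[complete_genes(x), , drop = FALSE]
  if (!nrow(v)) stop("no complete gene rows", call. = FALSE)
  gstats <- .gene_group_stats(v, design)
  praw <- .pairwise_t_matrix(gstats, config$ttest_flavor)
  padj <- praw
  if (config$fdr_scope == "per_pairing") {
    for (j in seq_len(ncol(praw))) padj[, j] <- bh_adjust(praw[, j])
  } else {
    padj[] <- bh_adjust(as.vector(praw))
  }
  pooled_sd <- sqrt(rowSums((v - rowMeans(v))^2) / (ncol(v) - 1L))
  out <- data.frame(gene = rownames(v), pooled_sd = pooled_sd,
                    stringsAsFactors = FALSE, row.names = NULL)
  for (g in design$group_order) out[[paste0("mean_", g)]] <- gstats$means[, g]
  for (nm in colnames(praw)) out[[paste0("p_", nm)]] <- praw[, nm]
  for (nm in colnames(padj)) out[[paste0("padj_", nm)]] <- padj[, nm]
  out$discriminatory <- apply(padj <= config$alpha, 1L, any)
  out
}

#' Rank genes by pooled standard deviation
#'
#' Pooled sd is the sample standard deviation (n - 1 denominator) of a
#' gene's values across all samples of all groups together — the global
#' variability estimator of the screen. Ties are broken lexicographically
#' by gene identifier for reproducibility.
#'
#' @param stats data frame with columns `gene` and `pooled_sd` (as produced
#'   by [nondiscriminatory_filter()]), typically already restricted to
#'   eligible (nondiscriminatory) genes.
#' @return the data frame sorted by ascending `pooled_sd` (ties by gene id).
#' @export
variability_rank <- function(stats) {
  stopifnot(all(c("gene", "pooled_sd") %in% names(stats)))
  stats[order(stats$pooled_sd, stats$gene, method = "radix"), ,
        drop = FALSE]
}

#' Intensity-window filter
#'
#' Keeps genes whose every per-group mean log2 intensity lies inside the
#' closed window (both bounds inclusive), excluding very low and very high
#' expressors.
#'
#' @param stats data frame with `mean_<group>` columns.
#' @param window closed interval, default taken from [discovery_config()].
#' @return `stats` with a logical `in_window` column, filtered to the genes
#'   inside the window.
#' @export
intensity_window_filter <- function(stats, window = c(4, 11)) {
  mcols <- grep("^mean_", names(stats), value = TRUE)
  stopifnot(length(mcols) >= 1L, length(window) == 2L)
  m <- as.matrix(stats[mcols])
  inside <- rowSums(m >= window[1L] & m <= window[2L]) == ncol(m)
  out <- stats[inside, , drop = FALSE]
  out$in_window <- TRUE
  out
}

#' Ascending-variability stability walk
#'
#' Walks the shortlist in ascending pooled-sd order, collecting genes whose
#' three unadjusted pairwise p-values all exceed `config$stability_p`,
#' until `config$k_candidates` are found or the list is exhausted. Genes
#' with exactly one p-value in the borderline band and the other two above
#' the threshold are flagged `borderline` (surfaced for manual
#' adjudication, never auto-selected).
#'
#' @param shortlist data frame sorted ascending by `pooled_sd`, with
#'   `p_<pairing>` columns (three pairings).
#' @param config a [discovery_config()].
#' @return `shortlist` with logical columns `stable`, `borderline`,
#'   `candidate`.
#' @export
stability_select <- function(shortlist, config = discovery_config()) {
  pcols <- grep("^p_", names(shortlist), value = TRUE)
  pcols <- setdiff(pcols, grep("^padj_", names(shortlist), value = TRUE))
  stopifnot(length(pcols) == 3L)
  if (!nrow(shortlist)) {
    warning("empty shortlist: no candidates can be selected", call. = FALSE)
    shortlist$stable <- shortlist$borderline <- shortlist$candidate <-
      logical(0)
    return(shortlist)
  }
  if (is.unsorted(shortlist$pooled_sd))
    shortlist <- variability_rank(shortlist)
  p <- as.matrix(shortlist[pcols])
  stable <- rowSums(p > config$stability_p) == 3L
  n_border <- rowSums(p >= config$borderline_band[1L] &
                        p < config$borderline_band[2L])
  borderline <- n_border == 1L & rowSums(p > config$stability_p) == 2L
  candidate <- stable & cumsum(stable) <= config$k_candidates
  shortlist$stable <- stable
  shortlist$borderline <- borderline
  shortlist$candidate <- candidate
  shortlist
}

#' Discover candidate reference genes
#'
#' Runs the full two-step probabilistic selection on a three-group log2
#' expression matrix: (1) exclusion of discriminatory genes (any
#' FDR-adjusted pairwise t-test p <= alpha), (2) retention of the
#' `n_lowvar` genes with lowest pooled standard deviation, (3) an intensity
#' window on all three group means, and (4) an ascending-variability walk
#' selecting up to `k_candidates` genes whose three unadjusted pairwise
#' p-values all exceed `stability_p`. Genes with missing values are
#' excluded up front; an optional user-supplied exclusion list (e.g. genes
#' without described function) is honoured before the walk.
#'
#' @param x an [expr_matrix()] of normalized log2 intensities.
#' @param design a [group_design()] with exactly three groups.
#' @param config a [discovery_config()].
#' @param exclude optional character vector of gene ids never to select.
#' @return an object of class `refgene_discovery` with components
#'   `stats` (per-gene statistics for all complete genes), `shortlist`
#'   (genes passing filters 1-3, ascending pooled sd, with stability
#'   flags), `candidates` (character vector, ascending pooled sd),
#'   `borderline` (character vector), `counts` (named integer vector of
#'   per-filter pass counts), `config`, and `call`.
#' @examples
#' sim <- nk_like_scenario(n_genes = 300, seed = 1)
#' fit <- discover_references(sim$matrix, sim$design)
#' fit
#' @export
discover_references <- function(x, design, config = discovery_config(),
                                exclude = NULL) {
  cl <- match.call()
  stats <- nondiscriminatory_filter(x, design, config)
  counts <- c(genes = nrow(x), complete = nrow(stats),
              nondiscriminatory = sum(!stats$discriminatory))
  keep <- stats[!stats$discriminatory, , drop = FALSE]
  keep <- variability_rank(keep)
  keep <- utils::head(keep, config$n_lowvar)
  counts["low_variability"] <- nrow(keep)
  keep <- intensity_window_filter(keep, config$intensity_window)
  counts["in_window"] <- nrow(keep)
  if (!is.null(exclude)) {
    keep <- keep[!keep$gene %in% exclude, , drop = FALSE]
    counts["after_exclusions"] <- nrow(keep)
  }
  shortlist <- stability_select(keep, config)
  counts["stable"] <- sum(shortlist$stable)
  counts["candidates"] <- sum(shortlist$candidate)
  # borderline genes are only surfaced over the stretch the walk actually
  # inspected (up to the k-th candidate, or the whole shortlist if fewer)
  walk_end <- if (any(shortlist$candidate) &&
                  sum(shortlist$candidate) == config$k_candidates)
    max(which(shortlist$candidate)) else nrow(shortlist)
  structure(list(stats = stats,
                 shortlist = shortlist,
                 candidates = shortlist$gene[shortlist$candidate],
                 borderline = shortlist$gene[shortlist$borderline &
                                               seq_len(max(nrow(shortlist), 1L)) <= walk_end],
                 counts = counts,
                 config = config,
                 call = cl),
            class = "refgene_discovery")
}

#' @export
print.refgene_discovery <- function(x, ...) {
  cat("Reference-gene discovery\n")
  cat(sprintf("  %d genes (%d complete) -> %d nondiscriminatory -> %d low-variability -> %d in window\n",
              x$counts[["genes"]], x$counts[["complete"]],
              x$counts[["nondiscriminatory"]], x$counts[["low_variability"]],
              x$counts[["in_window"]]))
  if (length(x$candidates)) {
    cat(sprintf("  candidates (%d, ascending pooled sd): %s\n",
                length(x$candidates), paste(x$candidates, collapse = ", ")))
  } else cat("  no candidates met the stability criterion\n")
  if (length(x$borderline))
    cat(sprintf("  borderline (manual adjudication): %s\n",
                paste(x$borderline, collapse = ", ")))
  invisible(x)
}

#' @export
summary.refgene_discovery <- function(object, n = 10L, ...) {
  cat("Reference-gene discovery summary\n\ncounts along the pipeline:\n")
  print(object$counts)
  cat(sprintf("\nshortlist pooled sd range: %.4g .. %.4g (%d genes)\n",
              min(object$shortlist$pooled_sd),
              max(object$shortlist$pooled_sd), nrow(object$shortlist)))
  cat(sprintf("\ntop %d shortlist genes (ascending pooled sd):\n",
              min(n, nrow(object$shortlist))))
  cols <- c("gene", "pooled_sd",
            grep("^mean_", names(object$shortlist), value = TRUE),
            grep("^p_", names(object$shortlist), value = TRUE),
            "stable", "borderline", "candidate")
  print(utils::head(object$shortlist[cols], n), digits = 3,
        row.names = FALSE)
  invisible(object)
}

#' Plot the shortlist of a discovery fit
#'
#' Shows the shortlist genes in ascending pooled-sd order against their
#' three unadjusted pairwise p-values, with the significance (0.05) and
#' stability (0.5) thresholds drawn; candidates are highlighted.
#'
#' @param x a `refgene_discovery` object.
#' @param n number of top shortlist genes displayed.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.refgene_discovery <- function(x, n = 50L, ...) {
  sl <- utils::head(x$shortlist, n)
  if (!nrow(sl)) {
    warning("empty shortlist, nothing to plot", call. = FALSE)
    return(invisible(x))
  }
  pcols <- setdiff(grep("^p_", names(sl), value = TRUE),
                   grep("^padj_", names(sl), value = TRUE))
  p <- as.matrix(sl[pcols])
  graphics::matplot(seq_len(nrow(sl)), p, pch = c(1, 2, 3), col = "grey30",
                    xlab = "shortlist rank (ascending pooled sd)",
                    ylab = "unadjusted pairwise t-test p-value",
                    ylim = c(0, 1), ...)
  graphics::abline(h = 0.05, col = "blue", lty = 2)
  graphics::abline(h = x$config$stability_p, col = "red", lty = 2)
  if (any(sl$candidate))
    graphics::points(which(sl$candidate),
                     rep(1.0, sum(sl$candidate)), pch = 25, bg = "red")
  graphics::legend("bottomright", legend = sub("^p_", "", pcols),
                   pch = c(1, 2, 3), bty = "n", cex = 0.8)
  invisible(x)
}
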