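## All-pairs comparison matrices for grouped single-gene records (e.g. GEO
## Profiles exports): mean fold differences above the diagonal, unadjusted
## t-test p-values below, with the convention that the group earlier in the
## group order is always the fold denominator.

#' All-pairs fold-difference / p-value comparison matrix
#'
#' For a single-gene record with grouped samples, computes for every group
#' pair the mean fold difference `mean(later group) / mean(earlier group)`
#' (the earlier group in `group_order` — the lower group number — is always
#' the denominator) and the unadjusted two-sample t-test p-value on the
#' per-sample values. Log2-scale inputs are exponentiated to the linear
#' scale first; folds are ratios of arithmetic group means.
#'
#' @param x an [expr_matrix()] with exactly one gene, or a named numeric
#'   vector of per-sample values (assumed linear scale).
#' @param design a [group_design()] with >= 2 groups.
#' @param flavor t-test flavor, `"pooled"` (default) or `"welch"`.
#' @return an object of class `comparison_matrix`: list with
#'   `group_order`, `n_per_group`, `fold` (full reciprocal matrix, unit
#'   diagonal) and `pvals` (symmetric). Pairings where a group has fewer
#'   than 2 samples carry `NA` p-values.
#' @examples
#' vals <- c(a1 = 100, a2 = 110, b1 = 200, b2 = 190, c1 = 400, c2 = 410)
#' des <- group_design(c(a1 = "A", a2 = "A", b1 = "B", b2 = "B",
#'                       c1 = "C", c2 = "C"))
#' pairwise_comparison_matrix(vals, des)
#' @export
pairwise_comparison_matrix <- function(x, design,
                                       flavor = c("pooled", "welch")) {
  flavor <- match.arg(flavor)
  stopifnot(inherits(design, "group_design"))
  if (inherits(x, "expr_matrix")) {
    if (nrow(x) != 1L)
      stop("comparison matrices are per gene: pass a 1-gene matrix",
           call. = FALSE)
    vals <- unclass(x)[1L, ]
    if (em_scale(x) == "log2_intensity") vals <- 2^vals
    if (em_scale(x) == "ct")
      stop("Ct-scale records are not supported here; convert to linear ",
           "quantities (2^-Ct) first", call. = FALSE)
  } else {
    vals <- x
    if (is.null(names(vals)))
      stop("'x' must be a named per-sample vector or a 1-gene expr_matrix",
           call. = FALSE)
  }
  vals <- vals[!is.na(vals)]
  groups <- design$group_order
  if (length(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  gs <- group_samples(design)
  per <- lapply(gs, function(s) vals[intersect(s, names(vals))])
  n <- vapply(per, length, integer(1L))
  g <- length(groups)
  fold <- matrix(1, g, g, dimnames = list(groups, groups))
  pv <- matrix(NA_real_, g, g, dimnames = list(groups, groups))
  diag(pv) <- 1
  for (a in seq_len(g - 1L)) for (b in (a + 1L):g) {
    ma <- mean(per[[a]]); mb <- mean(per[[b]])
    fold[a, b] <- mb / ma          # earlier group = denominator
    fold[b, a] <- ma / mb
    if (n[a] >= 2L && n[b] >= 2L) {
      pv[a, b] <- pv[b, a] <-
        two_sample_t(per[[b]], per[[a]], flavor)$p_value
    }
  }
  structure(list(group_order = groups,
                 n_per_group = stats::setNames(as.integer(n), groups),
                 fold = fold, pvals = pv),
            class = "comparison_matrix")
}

#' Render a comparison matrix in the published all-pairs layout
#'
#' Fixed-width text with the mean fold differences (2 decimals) in the
#' upper triangle and unadjusted t-test p-values (2 decimals, `<10^-3`
#' below 0.001) in the lower triangle.
#'
#' @param x a `comparison_matrix`.
#' @return character vector of lines.
#' @export
format_comparison_matrix <- function(x) {
  stopifnot(inherits(x, "comparison_matrix"))
  g <- length(x$group_order)
  fmt_p <- function(p) {
    if (is.na(p)) return("NA")
    if (p < 0.001) "<10^-3" else sprintf("%.2f", p)
  }
  cells <- matrix("", g, g)
  for (a in seq_len(g)) for (b in seq_len(g)) {
    cells[a, b] <- if (a == b) ""
    else if (a < b) sprintf("%.2f", x$fold[a, b])
    else fmt_p(x$pvals[a, b])
  }
  lab <- sprintf("%d %s (%d)", seq_len(g), x$group_order,
                 x$n_per_group)
  head <- c("Comparison Groups (n)", as.character(seq_len(g)))
  rows <- lapply(seq_len(g), function(a) c(lab[a], cells[a, ]))
  tab <- do.call(rbind, c(list(head), rows))
  widths <- apply(nchar(tab), 2L, max)
  apply(tab, 1L, function(r)
    paste(mapply(formatC, r, width = widths, flag = "-"), collapse = "  "))
}

#' @export
print.comparison_matrix <- function(x, ...) {
  cat("Mean fold differences (upper triangle) and unadjusted t-test",
      "p-values (lower triangle)\n")
  cat(format_comparison_matrix(x), sep = "\n")
  invisible(x)
}

#' Write a comparison matrix as TSV
#'
#' Upper triangle: folds to 2 decimals; lower triangle: p-values to 2
#' decimals with `<10^-3` substituted below 0.001; diagonal empty.
#'
#' @param x a `comparison_matrix`.
#' @param path output path.
#' @export
write_comparison_matrix <- function(x, path) {
  stopifnot(inherits(x, "comparison_matrix"))
  g <- length(x$group_order)
  fmt_p <- function(p) if (is.na(p)) "NA"
  else if (p < 0.001) "<10^-3" else sprintf("%.2f", p)
  lines <- paste(c("group_n", x$group_order), collapse = "\t")
  for (a in seq_len(g)) {
    cells <- vapply(seq_len(g), function(b) {
      if (a == b) ""
      else if (a < b) sprintf("%.2f", x$fold[a, b])
      else fmt_p(x$pvals[a, b])
    }, character(1L))
    lines <- c(lines,
               paste(c(sprintf("%s (%d)", x$group_order[a],
                               x$n_per_group[a]), cells),
                     collapse = "\t"))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
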