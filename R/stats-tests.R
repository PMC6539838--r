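## Statistical primitives used throughout the pipeline.
##
## Exact Wilcoxon modes enumerate the permutation null via a
## generating-function dynamic program on doubled midranks, so ties are
## handled exactly; the brute-force subset/sign enumerations live in the
## test suite as independent oracles.

test_result <- function(statistic, p_value, method, n_per_group,
                        df = NA_real_, degenerate = FALSE) {
  structure(list(statistic = unname(statistic),
                 p_value = unname(p_value),
                 method = method,
                 n_per_group = unname(n_per_group),
                 df = unname(df),
                 degenerate = degenerate),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g, p = %.6g (n = %s)%s\n",
              x$method, x$statistic, x$p_value,
              paste(x$n_per_group, collapse = "/"),
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}

#' Two-sample t test (pooled or Welch)
#'
#' Two-sided test of equal means. The pooled flavor uses the equal-variance
#' statistic on `nA + nB - 2` degrees of freedom; `welch` uses the
#' Welch-Satterthwaite approximation. Degenerate inputs follow fixed
#' conventions rather than erroring: when both groups are constant with
#' equal means, `p = 1`; when the pooled variance is zero but the means
#' differ, the smallest representable positive p is returned and the result
#' is flagged degenerate.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @param flavor `"pooled"` (default) or `"welch"`.
#' @return a `test_result` with fields `statistic`, `p_value`, `method`,
#'   `n_per_group`, `df`, `degenerate`.
#' @examples
#' two_sample_t(c(4.9, 5.0, 5.1), c(5.9, 6.0, 6.1))  # t = -12.25, df = 4
#' @export
two_sample_t <- function(x, y, flavor = c("pooled", "welch")) {
  flavor <- match.arg(flavor)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L)
    stop("each group needs at least 2 values", call. = FALSE)
  mx <- mean(x); my <- mean(y)
  vx <- stats::var(x); vy <- stats::var(y)
  method <- if (flavor == "pooled") "pooled_t" else "welch_t"
  if (flavor == "pooled") {
    vp <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    df <- nx + ny - 2
    se <- sqrt(vp * (1 / nx + 1 / ny))
  } else {
    se <- sqrt(vx / nx + vy / ny)
    df <- if (se > 0)
      (vx / nx + vy / ny)^2 /
        ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
    else NA_real_
  }
  if (se == 0) {
    if (mx == my)
      return(test_result(0, 1, method, c(nx, ny), df, degenerate = TRUE))
    return(test_result(sign(mx - my) * Inf, .Machine$double.xmin, method,
                       c(nx, ny), df, degenerate = TRUE))
  }
  t <- (mx - my) / se
  p <- 2 * stats::pt(-abs(t), df)
  test_result(t, min(p, 1), method, c(nx, ny), df)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Thin validating wrapper around `stats::p.adjust(method = "BH")`:
#' order-preserving, each adjusted value >= its raw value, capped at 1,
#' idempotent on its own output.
#'
#' @param pvals numeric vector of raw p-values in (0, 1].
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(pvals) {
  if (!length(pvals)) return(numeric(0))
  if (any(is.na(pvals)) || any(pvals <= 0) || any(pvals > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  stats::p.adjust(pvals, method = "BH")
}

## distribution of the rank-sum of a size-m subset of `ranks2` (doubled
## midranks, integers): returns named vector of counts over achievable sums.
.ranksum_null_counts <- function(ranks2, m) {
  total <- sum(ranks2)
  # dp[j + 1, s + 1] = number of size-j subsets with sum s
  dp <- matrix(0, nrow = m + 1L, ncol = total + 1L)
  dp[1L, 1L] <- 1
  for (r in ranks2) {
    jmax <- m
    for (j in jmax:1L) {
      nz <- which(dp[j, ] > 0)
      if (length(nz))
        dp[j + 1L, nz + r] <- dp[j + 1L, nz + r] + dp[j, nz]
    }
  }
  dp[m + 1L, ]
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided test. `exact` mode computes the permutation null of the
#' rank-sum statistic over all `choose(nA + nB, nA)` group assignments,
#' using midranks for ties (dynamic program, exact also under ties);
#' the two-sided p is `min(1, 2 * min(lower tail, upper tail))` with tails
#' including the observed value. `normal` mode uses the normal
#' approximation with continuity correction and tie-corrected variance.
#' `auto` selects exact when both groups have at most 12 values.
#'
#' @param x,y numeric vectors (each nonempty).
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @return a `test_result`; `statistic` is the rank sum of `x`.
#' @examples
#' wilcoxon_rank_sum(1:3, 4:6, mode = "exact")  # p = 0.1
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  nx <- length(x); ny <- length(y)
  if (!nx || !ny) stop("both groups must be nonempty", call. = FALSE)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(nx)])
  if (mode == "auto") mode <- if (nx <= 12L && ny <= 12L) "exact" else "normal"
  if (mode == "exact") {
    counts <- .ranksum_null_counts(as.integer(round(2 * r)), nx)
    tot <- sum(counts)
    w2 <- as.integer(round(2 * w))
    lo <- sum(counts[seq_len(w2 + 1L)]) / tot
    hi <- sum(counts[(w2 + 1L):length(counts)]) / tot
    p <- min(1, 2 * min(lo, hi))
    return(test_result(w, p, "wilcoxon_rank_sum_exact", c(nx, ny)))
  }
  n <- nx + ny
  mu <- nx * (n + 1) / 2
  ties <- table(r)
  tiecorr <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- nx * ny / 12 * ((n + 1) - tiecorr)
  if (sigma2 <= 0)
    return(test_result(w, 1, "wilcoxon_rank_sum_normal", c(nx, ny),
                       degenerate = TRUE))
  z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  test_result(w, p, "wilcoxon_rank_sum_normal", c(nx, ny))
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided test on paired differences `x - y`. Zero differences are
#' dropped (the classical convention). `exact` mode computes the null
#' distribution of the positive-rank sum over all `2^n` sign assignments
#' (dynamic program on doubled midranks of the absolute differences, exact
#' also under ties); used automatically for n <= 15 non-zero pairs, the
#' normal approximation with tie correction and continuity correction
#' otherwise. All differences zero gives `p = 1` with a degenerate flag.
#'
#' @param x,y equal-length paired numeric vectors.
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @return a `test_result`; `statistic` is the positive-rank sum.
#' @examples
#' wilcoxon_signed_rank(2:7 + 1, 2:7, mode = "exact")  # p = 2/64
#' @export
wilcoxon_signed_rank <- function(x, y = NULL,
                                 mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  d <- if (is.null(y)) x else {
    if (length(x) != length(y))
      stop("paired vectors must have equal length", call. = FALSE)
    x - y
  }
  d <- d[!is.na(d)]
  n_all <- length(d)
  d <- d[d != 0]
  n <- length(d)
  if (!n)
    return(test_result(0, 1, "signed_rank_exact", n_all, degenerate = TRUE))
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (mode == "auto") mode <- if (n <= 15L) "exact" else "normal"
  if (mode == "exact") {
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    g <- numeric(total + 1L)
    g[1L] <- 1
    for (rr in r2) {
      nz <- which(g > 0)
      gg <- g
      gg[nz + rr] <- gg[nz + rr] + g[nz]
      g <- gg
    }
    tot <- sum(g)
    v2 <- as.integer(round(2 * v))
    lo <- sum(g[seq_len(v2 + 1L)]) / tot
    hi <- sum(g[(v2 + 1L):length(g)]) / tot
    p <- min(1, 2 * min(lo, hi))
    return(test_result(v, p, "signed_rank_exact", n))
  }
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  if (sigma2 <= 0)
    return(test_result(v, 1, "signed_rank_normal", n, degenerate = TRUE))
  z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  test_result(v, p, "signed_rank_normal", n)
}

#' Kruskal-Wallis omnibus test with Dunn's post hoc pairwise comparisons
#'
#' The omnibus tie-corrected H statistic and chi-square p-value come from
#' `stats::kruskal.test`; Dunn's z statistics are computed on the pooled
#' midranks with the standard tie correction, and their two-sided normal
#' p-values are reported unadjusted (optionally Benjamini-Hochberg adjusted
#' across the pairings).
#'
#' @param groups named list of >= 3 numeric vectors, each of length >= 2.
#' @param adjust `"none"` (default) or `"BH"` for the Dunn p-values.
#' @return list with `omnibus` (a `test_result`) and `pairwise` (data frame
#'   with columns `group1`, `group2`, `z`, `p_value`, and `p_adj` when
#'   `adjust = "BH"`).
#' @examples
#' kruskal_dunn(list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9)))
#' @export
kruskal_dunn <- function(groups, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (length(groups) < 3L)
    stop("need at least 3 groups; use wilcoxon_rank_sum() for two",
         call. = FALSE)
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (any(lengths(groups) < 2L))
    stop("each group needs at least 2 values", call. = FALSE)
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  kw <- stats::kruskal.test(groups)
  omnibus <- test_result(unname(kw$statistic), unname(kw$p.value),
                         "kruskal_wallis", lengths(groups),
                         df = unname(kw$parameter))
  pooled <- unlist(groups, use.names = FALSE)
  N <- length(pooled)
  r <- rank(pooled)
  idx <- rep(seq_along(groups), lengths(groups))
  rbar <- tapply(r, idx, mean)
  ties <- table(r)
  tcorr <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(seq_along(groups), 2L)
  z <- apply(pairs, 2L, function(ab) {
    a <- ab[1L]; b <- ab[2L]
    se <- sqrt((N * (N + 1) / 12 - tcorr) *
                 (1 / length(groups[[a]]) + 1 / length(groups[[b]])))
    (rbar[[a]] - rbar[[b]]) / se
  })
  pw <- data.frame(group1 = names(groups)[pairs[1L, ]],
                   group2 = names(groups)[pairs[2L, ]],
                   z = z,
                   p_value = pmin(1, 2 * stats::pnorm(-abs(z))),
                   stringsAsFactors = FALSE)
  if (adjust == "BH") pw$p_adj <- bh_adjust(pw$p_value)
  list(omnibus = omnibus, pairwise = pw)
}
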