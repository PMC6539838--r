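# Brute-force enumeration oracles, independent of the package's DP-based
# exact Wilcoxon implementations.

# Two-sided exact rank-sum p by enumerating all C(nA+nB, nA) assignments.
oracle_rank_sum_p <- function(x, y) {
  r <- rank(c(x, y))
  nx <- length(x)
  w_obs <- sum(r[seq_len(nx)])
  subs <- utils::combn(length(r), nx)
  w_all <- apply(subs, 2L, function(idx) sum(r[idx]))
  eps <- 1e-9
  lo <- mean(w_all <= w_obs + eps)
  hi <- mean(w_all >= w_obs - eps)
  min(1, 2 * min(lo, hi))
}

# Two-sided exact signed-rank p by enumerating all 2^n sign patterns.
oracle_signed_rank_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (!n) return(1)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  v_all <- apply(signs, 1L, function(s) sum(r[s]))
  eps <- 1e-9
  lo <- mean(v_all <= v_obs + eps)
  hi <- mean(v_all >= v_obs - eps)
  min(1, 2 * min(lo, hi))
}

# small deterministic grouped matrix fixture
make_toy_matrix <- function(n_genes = 10, n_per_group = c(4, 4, 4),
                            seed = 1) {
  set.seed(seed)
  n <- sum(n_per_group)
  v <- matrix(rnorm(n_genes * n, mean = 7, sd = 0.5), n_genes, n,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n))))
  des <- group_design(setNames(rep(c("pre", "SIRS", "sepsis"),
                                   times = n_per_group),
                               colnames(v)),
                      group_order = c("pre", "SIRS", "sepsis"))
  list(matrix = expr_matrix(v, "log2_intensity"), design = des)
}
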