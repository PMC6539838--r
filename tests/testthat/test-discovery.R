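test_that("pairwise nondiscrimination statistics match per-gene t.test", {
  toy <- make_toy_matrix(n_genes = 8, seed = 4)
  cfg <- discovery_config()
  st <- nondiscriminatory_filter(toy$matrix, toy$design, cfg)
  v <- unclass(toy$matrix)
  gs <- group_samples(toy$design)
  for (i in seq_len(nrow(st))) {
    g <- st$gene[i]
    expect_equal(st$p_pre_vs_SIRS[i],
                 t.test(v[g, gs$pre], v[g, gs$SIRS],
                        var.equal = TRUE)$p.value)
    expect_equal(st$p_SIRS_vs_sepsis[i],
                 t.test(v[g, gs$SIRS], v[g, gs$sepsis],
                        var.equal = TRUE)$p.value)
    expect_equal(st$pooled_sd[i], sd(v[g, ]))
    expect_equal(st$mean_sepsis[i], mean(v[g, gs$sepsis]))
  }
  # adjusted p-values are the BH of each pairing's column
  expect_equal(st$padj_pre_vs_SIRS, bh_adjust(st$p_pre_vs_SIRS))
  # welch flavor is honoured
  stw <- nondiscriminatory_filter(toy$matrix, toy$design,
                                  discovery_config(ttest_flavor = "welch"))
  g <- st$gene[1]
  expect_equal(stw$p_pre_vs_SIRS[1],
               t.test(v[g, gs$pre], v[g, gs$SIRS])$p.value)
})

test_that("a strongly shifted gene is flagged discriminatory", {
  set.seed(8)
  n <- c(10, 10, 10)
  v <- matrix(rnorm(50 * 30, 7, 0.2), 50, 30,
              dimnames = list(sprintf("g%02d", 1:50), sprintf("s%02d", 1:30)))
  v["g01", 21:30] <- v["g01", 21:30] + 4  # 4-log2 shift in sepsis
  des <- group_design(setNames(rep(c("pre", "SIRS", "sepsis"), each = 10),
                               colnames(v)))
  st <- nondiscriminatory_filter(expr_matrix(v, "log2_intensity"), des)
  expect_true(st$discriminatory[st$gene == "g01"])
  # i.i.d. noise genes: nearly all nondiscriminatory
  expect_gte(mean(!st$discriminatory[st$gene != "g01"]), 0.99)
})

test_that("variability ranking: sd oracle, tie-break, scale equivariance", {
  df <- data.frame(gene = c("b", "a", "c"),
                   pooled_sd = c(1, 0, 1), stringsAsFactors = FALSE)
  rk <- variability_rank(df)
  expect_identical(rk$gene, c("a", "b", "c"))  # sd 0 first, ties by id

  x <- c(4, 5, 6)
  expect_equal(sd(x), 1)           # analytic
  expect_equal(sd(3 * x), 3 * sd(x))  # scale equivariance of the estimator
})

test_that("intensity window is closed and monotone in width", {
  df <- data.frame(gene = c("edge", "low", "mid"),
                   mean_a = c(4.0, 3.99, 7.5),
                   mean_b = c(7.5, 7.5, 7.5),
                   mean_c = c(11.0, 10.0, 7.5),
                   stringsAsFactors = FALSE)
  kept <- intensity_window_filter(df, c(4, 11))
  expect_identical(kept$gene, c("edge", "mid"))  # bounds inclusive
  wider <- intensity_window_filter(df, c(3, 12))
  expect_true(all(kept$gene %in% wider$gene))  # widening never removes
})

test_that("stability walk selects in ascending-sd order and is monotone in the threshold", {
  df <- data.frame(gene = sprintf("g%d", 1:6),
                   pooled_sd = c(0.10, 0.11, 0.12, 0.13, 0.14, 0.15),
                   p_a_vs_b = c(0.9, 0.2, 0.8, 0.47, 0.6, 0.7),
                   p_a_vs_c = c(0.8, 0.9, 0.7, 0.9, 0.55, 0.8),
                   p_b_vs_c = c(0.7, 0.9, 0.6, 0.8, 0.52, 0.9),
                   stringsAsFactors = FALSE)
  cfg <- discovery_config(k_candidates = 3)
  sel <- stability_select(df, cfg)
  expect_identical(sel$gene[sel$candidate], c("g1", "g3", "g5"))
  # g4 has exactly one p in [0.45, 0.5) and two above 0.5: borderline
  expect_identical(sel$gene[sel$borderline], "g4")
  # raising stability_p never adds a candidate
  sel7 <- stability_select(df, discovery_config(k_candidates = 3,
                                                stability_p = 0.7))
  expect_true(all(sel7$gene[sel7$candidate] %in% sel$gene[sel$candidate]))
  expect_warning(stability_select(df[0, ], cfg), "empty")
})

test_that("null genes pass the stability criterion at the dependent-pairing rate", {
  # Monte-Carlo-oracle value: with groups 19/16/10 the three pairwise t
  # statistics share group means, so P(all three p > 0.5) ~ 0.22, well
  # above the 0.5^3 = 0.125 independence approximation.
  sim <- simulate_microarray(n_genes = 2000, n_per_group = c(19, 16, 10),
                             frac_de = 0, n_invariant = 0, seed = 77)
  st <- nondiscriminatory_filter(sim$matrix, sim$design)
  stable <- rowSums(cbind(st$p_presurgical_vs_SIRS,
                          st$p_presurgical_vs_sepsis,
                          st$p_SIRS_vs_sepsis) > 0.5) == 3
  expect_gt(mean(stable), 0.19)
  expect_lt(mean(stable), 0.25)
})

test_that("full pipeline composes as set intersection with consistent counts", {
  sim <- nk_like_scenario(n_genes = 400, seed = 10)
  cfg <- discovery_config(n_lowvar = 200)
  fit <- discover_references(sim$matrix, sim$design, cfg)

  # counts never increase along the pipeline
  cn <- fit$counts
  expect_true(all(diff(cn[c("complete", "nondiscriminatory",
                            "low_variability", "in_window")]) <= 0))
  expect_lte(cn[["candidates"]], cfg$k_candidates)

  # each candidate passes every filter predicate in isolation
  st <- fit$stats
  for (g in fit$candidates) {
    row <- st[st$gene == g, ]
    expect_false(row$discriminatory)
    expect_lte(sum(st$pooled_sd < row$pooled_sd), cfg$n_lowvar)
    means <- as.numeric(row[grep("^mean_", names(row))])
    expect_true(all(means >= 4 & means <= 11))
    praw <- as.numeric(row[setdiff(grep("^p_", names(row)),
                                   grep("^padj_", names(row)))])
    expect_true(all(praw > cfg$stability_p))
  }
  # candidates ascend in pooled sd and are a subset of the shortlist
  sds <- st$pooled_sd[match(fit$candidates, st$gene)]
  expect_true(!is.unsorted(sds))
  expect_true(all(fit$candidates %in% fit$shortlist$gene))

  # determinism: identical inputs give identical reports
  fit2 <- discover_references(sim$matrix, sim$design, cfg)
  fit2$call <- fit$call
  expect_identical(fit, fit2)
})

test_that("user exclusion list removes genes from candidacy", {
  sim <- nk_like_scenario(n_genes = 400, seed = 11)
  fit <- discover_references(sim$matrix, sim$design)
  first <- fit$candidates[1]
  fit2 <- discover_references(sim$matrix, sim$design, exclude = first)
  expect_false(first %in% fit2$candidates)
})

test_that("planted invariants are recovered as top candidates", {
  sim <- nk_like_scenario(n_genes = 1500, seed = 12)
  fit <- discover_references(sim$matrix, sim$design)
  cls <- setNames(sim$truth$class, sim$truth$gene)
  expect_length(fit$candidates, 5)
  # every candidate has truly equal group means (non-DE)
  expect_true(all(cls[fit$candidates] != "de"))
})

test_that("print/summary/plot methods run cleanly", {
  sim <- nk_like_scenario(n_genes = 300, seed = 13)
  fit <- discover_references(sim$matrix, sim$design)
  expect_output(print(fit), "candidates")
  expect_output(summary(fit), "pooled sd range")
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
})
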