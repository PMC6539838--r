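make_mfi_table <- function(values_by_gene, design, lod = 50,
                           replicate_count = 2) {
  rows <- lapply(names(values_by_gene), function(g) {
    v <- values_by_gene[[g]]
    data.frame(gene = g, sample = rep(names(v), each = replicate_count),
               replicate = rep(seq_len(replicate_count), times = length(v)),
               value = rep(v, each = replicate_count),
               stringsAsFactors = FALSE)
  })
  assay_table(do.call(rbind, rows), "mfi", design, lod = lod)
}

two_group_design <- function(n1 = 4, n2 = 4) {
  sams <- sprintf("p%02d", seq_len(n1 + n2))
  group_design(setNames(rep(c("SIRS", "sepsis"), c(n1, n2)), sams))
}

test_that("detectability filter reproduces undetectable/half-detected exclusions", {
  des <- two_group_design(20, 20)
  sams <- names(des$assignment)
  vals <- list(
    none  = setNames(rep(10, 40), sams),             # 0/40 above LOD
    half  = setNames(rep(c(10, 100), 20), sams),     # 20/40 above LOD
    all   = setNames(rep(200, 40), sams))
  at <- make_mfi_table(vals, des, lod = 50)
  det <- detectability_filter(at, max_below_frac = 0.5)
  expect_false(det$keep[det$gene == "none"])  # undetectable
  expect_false(det$keep[det$gene == "half"])  # boundary is inclusive: drop
  expect_true(det$keep[det$gene == "all"])
  expect_equal(det$frac_below[det$gene == "half"], 0.5)
  # missing LOD is an instructive error
  at2 <- at; at2$lod <- NULL
  expect_error(detectability_filter(at2), "limit of detection")
})

test_that("fold differences follow Ct and MFI semantics", {
  des <- two_group_design(3, 3)
  sams <- names(des$assignment)
  # Ct: group SIRS at 23 cycles, sepsis at 20 -> sepsis has 8-fold more
  d <- expand.grid(gene = "g", sample = sams, replicate = 1:3,
                   stringsAsFactors = FALSE)
  d$value <- ifelse(des$assignment[d$sample] == "SIRS", 23, 20)
  ct <- assay_table(d, "ct", des)
  fd <- group_fold_difference(ct, "g", group_num = "sepsis",
                              group_den = "SIRS")
  expect_equal(fd$fold, 8)
  # reciprocal direction
  fd_rev <- group_fold_difference(ct, "g", group_num = "SIRS",
                                  group_den = "sepsis")
  expect_equal(fd$fold * fd_rev$fold, 1)

  # MFI: means 140 vs 100 -> fold 1.4
  vals <- list(g = setNames(ifelse(des$assignment[sams] == "SIRS",
                                   100, 140), sams))
  mfi <- make_mfi_table(vals, des)
  fm <- group_fold_difference(mfi, "g", "sepsis", "SIRS")
  expect_equal(fm$fold, 1.4)

  # identical groups: fold 1, p 1
  vals_eq <- list(g = setNames(rep(100, 6), sams))
  feq <- group_fold_difference(make_mfi_table(vals_eq, des), "g",
                               "sepsis", "SIRS")
  expect_equal(feq$fold, 1)
  expect_equal(feq$test$p_value, 1)
})

test_that("Ct pathway agrees with the linear pathway under geometric means", {
  set.seed(31)
  des <- two_group_design(5, 5)
  sams <- names(des$assignment)
  ctv <- setNames(runif(10, 20, 26), sams)
  d <- data.frame(gene = "g", sample = sams, replicate = 1L, value = ctv,
                  stringsAsFactors = FALSE)
  ct <- assay_table(d, "ct", des)
  lin <- d; lin$value <- 2^(-d$value)
  linat <- assay_table(lin, "mfi", des)
  f_ct <- group_fold_difference(ct, "g", "sepsis", "SIRS")$fold
  f_geo <- group_fold_difference(linat, "g", "sepsis", "SIRS",
                                 aggregate = "geometric")$fold
  expect_equal(f_ct, f_geo, tolerance = 1e-9)
  # arithmetic aggregation differs in general (documented caveat)
  f_ari <- group_fold_difference(linat, "g", "sepsis", "SIRS")$fold
  expect_false(isTRUE(all.equal(f_ct, f_ari, tolerance = 1e-9)))
})

test_that("paired stimulation analysis matches the enumeration construction", {
  des <- group_design(setNames(rep("donors", 6), sprintf("d%d", 1:6)))
  sams <- sprintf("d%d", 1:6)
  mk <- function(ct) {
    d <- expand.grid(gene = "g", sample = sams, replicate = 1:3,
                     stringsAsFactors = FALSE)
    d$value <- ct[d$sample]
    assay_table(d, "ct", des)
  }
  base <- setNames(runif(6, 24, 26), sams)
  before <- mk(base)
  after <- mk(base - 2.828)  # every donor drops 2.828 cycles
  res <- paired_stimulation_analysis(before, after)
  expect_equal(res$fold, 2^2.828, tolerance = 1e-6)  # ~7.1
  expect_equal(res$p_value, 2 / 64)
  expect_identical(res$verdict, "unstable")

  # unchanged expression: fold 1, p 1, stable
  res0 <- paired_stimulation_analysis(before, before)
  expect_equal(res0$fold, 1)
  expect_equal(res0$p_value, 1)
  expect_identical(res0$verdict, "stable")

  # modest decrease (per-donor folds 0.7-1.1 averaging ~0.9): stable
  folds <- c(0.7, 0.8, 0.9, 0.95, 1.0, 1.1)
  after_mild <- mk(base - log2(setNames(folds, sams)))
  resm <- paired_stimulation_analysis(before, after_mild)
  expect_equal(resm$fold, 2^mean(log2(folds)), tolerance = 1e-6)
  expect_gte(resm$p_value, 0.05)
  expect_identical(resm$verdict, "stable")

  # donor sets must match
  des5 <- group_design(setNames(rep("donors", 5), sprintf("d%d", 1:5)))
  short <- mk(base)
  short$data <- short$data[short$data$sample != "d6", ]
  short$design <- des5
  expect_error(paired_stimulation_analysis(before, short), "donor sets")
})

test_that("confirm_candidates verdicts: planted effect, nulls, missing gene", {
  sim <- simulate_targeted_assay(paste0("g", 1:6),
                                 planted_folds = c(g1 = 1.5),
                                 seed = 41)
  res <- confirm_candidates(sim$table, c(paste0("g", 1:6), "absent"))
  expect_identical(res$verdict[res$gene == "absent"], "missing")
  expect_identical(res$verdict[res$gene == "g1"], "unstable")
  expect_gte(mean(res$verdict[res$gene %in% paste0("g", 2:6)] == "stable"),
             0.8)
  # report preserves candidate order
  expect_identical(res$gene, c(paste0("g", 1:6), "absent"))
})

test_that("verdicts are monotone in planted effect size at fixed seed", {
  verdict_for <- function(fold) {
    sim <- simulate_targeted_assay(c("g1", "g2"),
                                   planted_folds = c(g1 = fold), seed = 55)
    confirm_candidates(sim$table, "g1")$verdict
  }
  v <- vapply(c(1, 1.3, 1.6, 2, 3, 5), verdict_for, character(1))
  # once unstable, larger planted folds never flip back to stable
  first_unstable <- match("unstable", v)
  if (!is.na(first_unstable))
    expect_true(all(v[first_unstable:length(v)] == "unstable"))
})

test_that("a gene planted below the limit of detection is dropped", {
  sim <- simulate_targeted_assay(c("lowg", "okg"),
                                 base_level = c(lowg = 25, okg = 800),
                                 lod = 50, seed = 61)
  det <- detectability_filter(sim$table)
  expect_false(det$keep[det$gene == "lowg"])
  expect_true(det$keep[det$gene == "okg"])
  res <- confirm_candidates(sim$table, c("lowg", "okg"))
  expect_identical(res$verdict[res$gene == "lowg"], "undetectable")
})
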