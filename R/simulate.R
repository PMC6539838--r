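## Seeded generators with planted ground truth. They emulate the
## statistical structure the discovery and validation stages assume:
## three-group log2-normal expression matrices with a configurable DE
## fraction and planted invariant genes, Ct-scale tables with triplicate
## technical noise, and MFI-scale tables with a background floor so
## limit-of-detection censoring occurs.

.rtrunc_offset <- function(n, sd, min_abs) {
  out <- stats::rnorm(n, 0, sd)
  bad <- abs(out) < min_abs
  while (any(bad)) {
    out[bad] <- stats::rnorm(sum(bad), 0, sd)
    bad <- abs(out) < min_abs
  }
  out
}

#' Simulate a grouped log2 expression matrix with planted truth
#'
#' Generates a three-group genes x samples matrix of log2 intensities:
#' per-gene baselines, group-specific offsets for differentially expressed
#' (DE) genes, Gaussian noise on the log2 scale with per-gene noise sd
#' drawn from a lognormal distribution, and `n_invariant` planted
#' invariant genes (equal group means inside the intensity window, low
#' fixed sd). Baseline placement options encode different transcriptome
#' states: `"uniform"` over the whole intensity range; `"centered"`
#' (normal around the window midpoint — a quiescent cell type whose
#' expressed genes sit at intermediate intensity); `"edge_heavy"`
#' (non-DE, non-planted genes pushed to the background floor or
#' saturation — a strongly reprogrammed cell type whose invariant
#' expressed transcriptome is nearly empty). `de_placement = "expressed"`
#' draws DE baselines inside the window.
#'
#' @param n_genes number of genes.
#' @param n_per_group integer triple of group sizes.
#' @param group_labels labels for the three groups.
#' @param frac_de fraction of genes differentially expressed, in \[0, 1).
#' @param de_effect named vector `c(sd=, min_abs=)`: group offsets are
#'   drawn from a centred normal with this sd, resampled until
#'   `|offset| >= min_abs` (log2 units).
#' @param n_invariant number of planted invariant genes.
#' @param invariant_sd fixed noise sd of the planted invariants.
#' @param intensity_range support of the baseline log2 intensities.
#' @param invariant_range baseline range of planted invariants (inside the
#'   default \[4, 11\] window with margin).
#' @param noise_sd named vector `c(meanlog=, sdlog=)` of the lognormal
#'   per-gene noise sd distribution.
#' @param baseline baseline placement: `"uniform"`, `"centered"`,
#'   `"edge_heavy"`.
#' @param de_placement `"anywhere"` (baselines as the bulk) or
#'   `"expressed"` (DE baselines drawn inside the window).
#' @param seed integer seed; the output is a pure function of the
#'   arguments and the seed.
#' @return list with `matrix` (an [expr_matrix()]), `design`
#'   (a [group_design()]) and `truth` (data frame: `gene`, `class` in
#'   `{invariant_in_window, de, high_variance_null}`, `base`, true
#'   `mean_<group>` columns, true noise `sd`).
#' @export
simulate_microarray <- function(n_genes = 25000L,
                                n_per_group = c(19L, 16L, 10L),
                                group_labels = c("presurgical", "SIRS",
                                                 "sepsis"),
                                frac_de = 0.005,
                                de_effect = c(sd = 0.8, min_abs = 0.3),
                                n_invariant = 20L,
                                invariant_sd = 0.10,
                                intensity_range = c(2, 14),
                                invariant_range = c(4.3, 10.7),
                                noise_sd = c(meanlog = log(0.25),
                                             sdlog = 0.25),
                                baseline = c("uniform", "centered",
                                             "edge_heavy"),
                                de_placement = c("anywhere", "expressed"),
                                seed = NULL) {
  baseline <- match.arg(baseline)
  de_placement <- match.arg(de_placement)
  stopifnot(n_genes >= 1L, length(n_per_group) == 3L, all(n_per_group > 0),
            frac_de >= 0, frac_de < 1)
  if (n_invariant > n_genes)
    stop("n_invariant exceeds n_genes", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n_de <- round(frac_de * n_genes)
  if (n_invariant + n_de > n_genes)
    stop("n_invariant + DE genes exceed n_genes", call. = FALSE)
  gid <- sprintf("gene%05d", seq_len(n_genes))
  cls <- rep("high_variance_null", n_genes)
  cls[seq_len(n_invariant)] <- "invariant_in_window"
  if (n_de > 0) cls[n_invariant + seq_len(n_de)] <- "de"

  base <- numeric(n_genes)
  draw_bulk <- function(n) switch(baseline,
    uniform = stats::runif(n, intensity_range[1L], intensity_range[2L]),
    centered = pmin(pmax(stats::rnorm(n, mean(c(4, 11)), 2.2),
                         intensity_range[1L]), intensity_range[2L]),
    edge_heavy = {
      lowmass <- stats::runif(n) < 0.6
      ifelse(lowmass,
             stats::runif(n, intensity_range[1L], 3.8),
             stats::runif(n, 11.2, intensity_range[2L]))
    })
  inv <- cls == "invariant_in_window"
  de <- cls == "de"
  base[inv] <- stats::runif(sum(inv), invariant_range[1L],
                            invariant_range[2L])
  base[de] <- if (de_placement == "expressed")
    stats::runif(sum(de), invariant_range[1L], invariant_range[2L])
  else draw_bulk(sum(de))
  base[!inv & !de] <- draw_bulk(sum(!inv & !de))

  sds <- stats::rlnorm(n_genes, noise_sd[["meanlog"]], noise_sd[["sdlog"]])
  sds[inv] <- invariant_sd

  offsets <- matrix(0, n_genes, 3L)
  if (any(de)) {
    offsets[de, 2L] <- .rtrunc_offset(sum(de), de_effect[["sd"]],
                                      de_effect[["min_abs"]])
    offsets[de, 3L] <- .rtrunc_offset(sum(de), de_effect[["sd"]],
                                      de_effect[["min_abs"]])
  }

  sid <- sprintf("s%03d", seq_len(sum(n_per_group)))
  grp <- rep(group_labels, times = n_per_group)
  values <- matrix(NA_real_, n_genes, length(sid),
                   dimnames = list(gid, sid))
  for (g in 1:3) {
    cols <- grp == group_labels[g]
    mu <- base + offsets[, g]
    values[, cols] <- mu +
      stats::rnorm(n_genes * sum(cols), 0, sds)
  }
  truth <- data.frame(gene = gid, class = cls, base = base, sd = sds,
                      stringsAsFactors = FALSE)
  for (g in 1:3)
    truth[[paste0("mean_", group_labels[g])]] <- base + offsets[, g]
  list(matrix = expr_matrix(values, "log2_intensity"),
       design = group_design(stats::setNames(grp, sid),
                             group_order = group_labels),
       truth = truth)
}

#' NK-cell-like discovery scenario
#'
#' A quiescent transcriptome: 0.5% of genes differentially expressed,
#' baselines centred at intermediate intensity, group sizes 19/16/10.
#'
#' @param n_genes number of genes (desk-scale default 5000).
#' @param seed integer seed.
#' @param ... passed on to [simulate_microarray()].
#' @return as [simulate_microarray()].
#' @export
nk_like_scenario <- function(n_genes = 5000L, seed = NULL, ...) {
  simulate_microarray(n_genes = n_genes,
                      n_per_group = c(19L, 16L, 10L),
                      frac_de = 0.005,
                      baseline = "centered",
                      de_placement = "anywhere",
                      seed = seed, ...)
}

#' Granulocyte-like discovery scenario
#'
#' A strongly reprogrammed transcriptome under systemic inflammation: 28%
#' of genes differentially expressed and concentrated in the expressed
#' (in-window) intensity range, remaining non-DE genes at the background
#' floor or saturation, group sizes 11/16/15. Under the default
#' configuration this collapses the post-filter shortlist to little more
#' than the planted invariants.
#'
#' @inheritParams nk_like_scenario
#' @return as [simulate_microarray()].
#' @export
granulocyte_like_scenario <- function(n_genes = 5000L, seed = NULL, ...) {
  simulate_microarray(n_genes = n_genes,
                      n_per_group = c(11L, 16L, 15L),
                      frac_de = 0.28,
                      baseline = "edge_heavy",
                      de_placement = "expressed",
                      seed = seed, ...)
}

#' Simulate a two-group targeted assay table (Ct or MFI scale)
#'
#' MFI scale: per-sample true levels are lognormal around the group mean
#' (the second group's mean is the first group's scaled by the planted
#' fold), replicates carry multiplicative noise, and values are floored at
#' the background so limit-of-detection censoring occurs. Ct scale:
#' per-sample true Ct is the gene's base cycle, shifted by `-log2(fold)`
#' in the second group, with per-sample biological variation and additive
#' replicate noise.
#'
#' @param genes character vector of gene ids.
#' @param n_per_group named integer pair, e.g. `c(SIRS = 22, sepsis = 18)`;
#'   names become the group labels (first = comparison denominator).
#' @param scale `"mfi"` or `"ct"`.
#' @param planted_folds named numeric vector of true fold effects
#'   (second group vs first); genes not named have fold 1.
#' @param base_level optional named vector of per-gene base levels (MFI
#'   units, or Ct cycles); drawn at random otherwise (MFI lognormal over
#'   ~128-2048; Ct uniform 22-30).
#' @param biological_sd per-sample biological variation: log2 units for
#'   MFI (default 0.25), cycles for Ct (default 0.5).
#' @param replicate_sd technical replicate noise: log2 units for MFI
#'   (default 0.1), cycles for Ct (default 0.15).
#' @param replicate_count replicates per (gene, sample); defaults to 2 for
#'   MFI (duplicates) and 3 for Ct (triplicates).
#' @param lod limit of detection carried by the MFI table (default 50).
#' @param background MFI floor (default 1).
#' @param seed integer seed.
#' @return list with `table` (an [assay_table()]) and `truth` (data frame
#'   `gene`, `fold`, `base_level`).
#' @export
simulate_targeted_assay <- function(genes,
                                    n_per_group = c(SIRS = 22L,
                                                    sepsis = 18L),
                                    scale = c("mfi", "ct"),
                                    planted_folds = NULL,
                                    base_level = NULL,
                                    biological_sd = NULL,
                                    replicate_sd = NULL,
                                    replicate_count = NULL,
                                    lod = 50,
                                    background = 1,
                                    seed = NULL) {
  scale <- match.arg(scale)
  stopifnot(length(n_per_group) == 2L, !is.null(names(n_per_group)))
  if (!is.null(planted_folds)) {
    if (is.null(names(planted_folds)))
      stop("'planted_folds' must be named by gene", call. = FALSE)
    if (any(planted_folds <= 0))
      stop("planted folds must be positive", call. = FALSE)
  }
  if (is.null(biological_sd)) biological_sd <- if (scale == "mfi") 0.25 else 0.5
  if (is.null(replicate_sd)) replicate_sd <- if (scale == "mfi") 0.1 else 0.15
  if (is.null(replicate_count)) replicate_count <- if (scale == "mfi") 2L else 3L
  if (replicate_count < 1L)
    stop("replicate_count must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  groups <- names(n_per_group)
  sid <- sprintf("v%03d", seq_len(sum(n_per_group)))
  grp <- rep(groups, times = n_per_group)
  design <- group_design(stats::setNames(grp, sid), group_order = groups)
  folds <- stats::setNames(rep(1, length(genes)), genes)
  if (!is.null(planted_folds))
    folds[intersect(names(planted_folds), genes)] <-
      planted_folds[intersect(names(planted_folds), genes)]
  if (is.null(base_level)) {
    base_level <- if (scale == "mfi")
      stats::setNames(2^stats::runif(length(genes), 7, 11), genes)
    else stats::setNames(stats::runif(length(genes), 22, 30), genes)
  } else {
    stopifnot(all(genes %in% names(base_level)))
    base_level <- base_level[genes]
  }
  rows <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    g <- genes[i]
    if (scale == "mfi") {
      gmean <- ifelse(grp == groups[2L], base_level[[g]] * folds[[g]],
                      base_level[[g]])
      true_s <- gmean * 2^stats::rnorm(length(sid), 0, biological_sd)
      rep_v <- rep(true_s, each = replicate_count) *
        2^stats::rnorm(length(sid) * replicate_count, 0, replicate_sd)
      rep_v <- pmax(rep_v, background)
    } else {
      gct <- ifelse(grp == groups[2L],
                    base_level[[g]] - log2(folds[[g]]), base_level[[g]])
      true_s <- gct + stats::rnorm(length(sid), 0, biological_sd)
      rep_v <- rep(true_s, each = replicate_count) +
        stats::rnorm(length(sid) * replicate_count, 0, replicate_sd)
      rep_v <- pmin(pmax(rep_v, 0.1), 45)
    }
    rows[[i]] <- data.frame(gene = g,
                            sample = rep(sid, each = replicate_count),
                            replicate = rep(seq_len(replicate_count),
                                            times = length(sid)),
                            value = rep_v, stringsAsFactors = FALSE)
  }
  tab <- assay_table(do.call(rbind, rows), scale, design,
                     lod = if (scale == "mfi") lod else NULL)
  list(table = tab,
       truth = data.frame(gene = genes, fold = unname(folds),
                          base_level = unname(base_level),
                          stringsAsFactors = FALSE))
}

#' Simulate paired before/after stimulation tables (Ct scale)
#'
#' Donor baseline Ct values are shared between the two arms; the
#' stimulated arm is shifted by `-log2(fold)` cycles plus donor-level
#' response noise, emulating an ex vivo challenge of cells from the same
#' donors.
#'
#' @param genes character vector of gene ids.
#' @param n_donors number of donors (>= 3).
#' @param planted_folds named numeric vector of true stimulation folds
#'   (unnamed genes get fold 1).
#' @param base_ct optional named per-gene base cycles (drawn uniform 20-28
#'   otherwise).
#' @param donor_sd sd of donor baseline Ct (cycles, default 1).
#' @param response_sd sd of donor-level response noise (cycles,
#'   default 0.5 — inter-donor variability of ex vivo responses).
#' @param replicate_sd technical replicate noise (cycles, default 0.15).
#' @param replicate_count replicates per cell (default 3).
#' @param seed integer seed.
#' @return list with `control` and `treated` [assay_table()]s over the
#'   same donors, and `truth` (data frame `gene`, `fold`).
#' @export
simulate_paired_stimulation <- function(genes, n_donors = 6L,
                                        planted_folds = NULL,
                                        base_ct = NULL,
                                        donor_sd = 1,
                                        response_sd = 0.5,
                                        replicate_sd = 0.15,
                                        replicate_count = 3L,
                                        seed = NULL) {
  if (n_donors < 3L) stop("need at least 3 donors", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  donors <- sprintf("donor%02d", seq_len(n_donors))
  design <- group_design(stats::setNames(rep("donors", n_donors), donors))
  folds <- stats::setNames(rep(1, length(genes)), genes)
  if (!is.null(planted_folds))
    folds[intersect(names(planted_folds), genes)] <-
      planted_folds[intersect(names(planted_folds), genes)]
  if (is.null(base_ct))
    base_ct <- stats::setNames(stats::runif(length(genes), 20, 28), genes)
  mk_rows <- function(gene, ct_per_donor) {
    data.frame(gene = gene,
               sample = rep(donors, each = replicate_count),
               replicate = rep(seq_len(replicate_count), times = n_donors),
               value = pmin(pmax(
                 rep(ct_per_donor, each = replicate_count) +
                   stats::rnorm(n_donors * replicate_count, 0,
                                replicate_sd), 0.1), 45),
               stringsAsFactors = FALSE)
  }
  ctrl <- trt <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    g <- genes[i]
    baseline <- base_ct[[g]] + stats::rnorm(n_donors, 0, donor_sd)
    shifted <- baseline - log2(folds[[g]]) +
      stats::rnorm(n_donors, 0, response_sd)
    ctrl[[i]] <- mk_rows(g, baseline)
    trt[[i]] <- mk_rows(g, shifted)
  }
  list(control = assay_table(do.call(rbind, ctrl), "ct", design),
       treated = assay_table(do.call(rbind, trt), "ct", design),
       truth = data.frame(gene = genes, fold = unname(folds),
                          stringsAsFactors = FALSE))
}
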