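#' Targeted-assay replicate table (RT-PCR Ct or QuantiGene Plex MFI)
#'
#' Long-format container for replicate measurements per gene and sample.
#' Ct values are threshold cycles, inversely proportional to log2 transcript
#' quantity, restricted to (0, 45]; MFI values are background-corrected
#' median fluorescence intensities, nonnegative. An optional limit of
#' detection (global or per gene) supports detectability filtering.
#'
#' @param data data frame with columns `gene`, `sample`, `replicate`,
#'   `value` (one row per replicate measurement).
#' @param scale `"ct"` or `"mfi"`.
#' @param design a [group_design()] covering the samples.
#' @param lod optional limit of detection: a single number or a named
#'   vector (per gene), on the measurement scale.
#' @return an object of class `assay_table`.
#' @export
assay_table <- function(data, scale = c("ct", "mfi"), design, lod = NULL) {
  scale <- match.arg(scale)
  stopifnot(is.data.frame(data),
            all(c("gene", "sample", "replicate", "value") %in% names(data)),
            inherits(design, "group_design"))
  v <- data$value
  if (scale == "ct" && any(v <= 0 | v > 45, na.rm = TRUE))
    stop("Ct replicates must lie in (0, 45]", call. = FALSE)
  if (scale == "mfi" && any(v < 0, na.rm = TRUE))
    stop("MFI replicates must be >= 0", call. = FALSE)
  unknown <- setdiff(unique(data$sample), names(design$assignment))
  if (length(unknown))
    stop("sample(s) missing from design: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  cnt <- table(data$gene, data$sample)
  if (any(cnt == 0))
    stop("every (gene, sample) cell needs at least one replicate",
         call. = FALSE)
  if (!is.null(lod)) {
    if (length(lod) > 1L && is.null(names(lod)))
      stop("per-gene 'lod' must be named", call. = FALSE)
    if (length(lod) > 1L &&
        !all(unique(data$gene) %in% names(lod)))
      stop("per-gene 'lod' must cover every gene", call. = FALSE)
  }
  structure(list(data = data[c("gene", "sample", "replicate", "value")],
                 scale = scale, design = design, lod = lod),
            class = "assay_table")
}

#' @export
print.assay_table <- function(x, ...) {
  cat(sprintf("assay_table (%s): %d genes x %d samples, %d replicate rows%s\n",
              x$scale, length(unique(x$data$gene)),
              length(unique(x$data$sample)), nrow(x$data),
              if (is.null(x$lod)) "" else ", LOD set"))
  print(x$design)
  invisible(x)
}

#' Genes present in an assay table
#' @param x an [assay_table()].
#' @export
assay_genes <- function(x) unique(x$data$gene)

#' Per-sample replicate means of one gene
#'
#' Technical replicates (Ct triplicates, MFI duplicates) are averaged
#' arithmetically per sample first; all downstream statistics operate on
#' these per-sample values, i.e. on biological units only.
#'
#' @param x an [assay_table()].
#' @param gene gene identifier.
#' @return named numeric vector (sample -> mean value).
#' @export
sample_means <- function(x, gene) {
  stopifnot(inherits(x, "assay_table"))
  d <- x$data[x$data$gene == gene, , drop = FALSE]
  if (!nrow(d)) stop("gene '", gene, "' not in table", call. = FALSE)
  out <- tapply(d$value, d$sample, mean)
  stats::setNames(as.numeric(out), names(out))
}

.gene_lod <- function(x, gene) {
  if (is.null(x$lod)) return(NULL)
  if (length(x$lod) == 1L && is.null(names(x$lod))) return(unname(x$lod))
  if (!is.null(names(x$lod)) && gene %in% names(x$lod))
    return(unname(x$lod[[gene]]))
  if (length(x$lod) == 1L) return(unname(x$lod))
  NULL
}

#' Read a long-format assay table from TSV
#'
#' Expected columns (with header): `gene`, `sample`, `replicate`, `value`.
#'
#' @param path path to the TSV file.
#' @inheritParams assay_table
#' @return an [assay_table()].
#' @export
read_assay_table <- function(path, scale = c("ct", "mfi"), design,
                             lod = NULL) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  need <- c("gene", "sample", "replicate", "value")
  if (!all(need %in% names(d)))
    stop("'", path, "' must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  d$value <- as.numeric(d$value)
  assay_table(d, scale, design, lod)
}

#' Write an assay table to TSV
#' @param x an [assay_table()].
#' @param path output path.
#' @export
write_assay_table <- function(x, path) {
  stopifnot(inherits(x, "assay_table"))
  utils::write.table(x$data, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
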