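#' Expression matrix container
#'
#' Wraps a dense genes x samples numeric matrix together with an explicit
#' measurement scale. The scale is always declared, never inferred, because
#' the same pipeline serves log2 microarray intensities, RT-PCR threshold
#' cycles (Ct) and branched-DNA median fluorescence intensities (MFI), whose
#' fold-change semantics differ.
#'
#' @param values numeric matrix with unique, non-empty rownames (gene
#'   identifiers) and colnames (sample identifiers). Missing values are
#'   allowed and tracked; downstream discovery excludes incomplete rows.
#' @param scale one of `"log2_intensity"`, `"linear"`, `"ct"`, `"mfi"`.
#' @return an object of class `expr_matrix`: the matrix with a `scale`
#'   attribute.
#' @examples
#' m <- matrix(rnorm(12, 7), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' em <- expr_matrix(m, "log2_intensity")
#' @export
expr_matrix <- function(values,
                        scale = c("log2_intensity", "linear", "ct", "mfi")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  gid <- rownames(values)
  sid <- colnames(values)
  if (is.null(gid) || is.null(sid))
    stop("'values' must have rownames (genes) and colnames (samples)",
         call. = FALSE)
  if (anyDuplicated(gid))
    stop("duplicated gene identifiers: ",
         paste(unique(gid[duplicated(gid)]), collapse = ", "), call. = FALSE)
  if (anyDuplicated(sid))
    stop("duplicated sample identifiers: ",
         paste(unique(sid[duplicated(sid)]), collapse = ", "), call. = FALSE)
  if (scale %in% c("ct", "mfi") && any(values < 0, na.rm = TRUE))
    stop("negative values are invalid on the '", scale, "' scale",
         call. = FALSE)
  structure(values, scale = scale, class = c("expr_matrix", "matrix", "array"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples, scale = %s\n",
              nrow(x), ncol(x), attr(x, "scale")))
  n <- min(nrow(x), 6L)
  m <- min(ncol(x), 6L)
  print(unclass(x)[seq_len(n), seq_len(m), drop = FALSE])
  if (nrow(x) > n || ncol(x) > m)
    cat(sprintf("... (%d rows, %d cols not shown)\n",
                nrow(x) - n, ncol(x) - m))
  invisible(x)
}

#' @rdname expr_matrix
#' @param x an `expr_matrix`.
#' @export
em_scale <- function(x) attr(x, "scale")

#' Genes with complete (non-missing) rows
#' @param x an `expr_matrix`.
#' @return logical vector, one entry per gene.
#' @export
complete_genes <- function(x) !apply(is.na(unclass(x)), 1L, any)

#' Read an expression matrix from a TSV file
#'
#' File dialect: tab-separated UTF-8; first column gene identifiers, header
#' row holds sample identifiers; empty cells or `"NA"` encode missing
#' values. Row and column order is preserved exactly as in the file.
#'
#' @param path path to the TSV file.
#' @param scale declared measurement scale (see [expr_matrix()]).
#' @return an [expr_matrix()].
#' @export
read_expression_matrix <- function(path,
                                   scale = c("log2_intensity", "linear",
                                             "ct", "mfi")) {
  scale <- match.arg(scale)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L)
    stop("malformed file '", path, "': need a header and at least one row",
         call. = FALSE)
  hdr <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (length(hdr) < 2L)
    stop("malformed header in '", path, "': no sample columns", call. = FALSE)
  sid <- hdr[-1L]
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  nfield <- lengths(body)
  # trailing empty fields are dropped by strsplit; pad them back
  body <- lapply(body, function(f) c(f, rep("", length(hdr) - length(f))))
  if (any(nfield > length(hdr)))
    stop("row ", which(nfield > length(hdr))[1L] + 1L, " of '", path,
         "' has more fields than the header", call. = FALSE)
  gid <- vapply(body, `[[`, character(1L), 1L)
  if (anyDuplicated(gid))
    stop("duplicated gene identifier(s) in '", path, "': ",
         paste(unique(gid[duplicated(gid)]), collapse = ", "), call. = FALSE)
  cells <- vapply(body, function(f) f[-1L], character(length(sid)))
  cells <- matrix(cells, nrow = length(sid))  # samples x genes
  miss <- cells == "" | cells == "NA"
  num <- suppressWarnings(as.numeric(cells))
  bad <- is.na(num) & !miss
  if (any(bad)) {
    idx <- which(bad)[1L]
    stop(sprintf("non-numeric value '%s' in '%s' at gene '%s', sample '%s'",
                 cells[idx], path,
                 gid[(idx - 1L) %/% length(sid) + 1L],
                 sid[(idx - 1L) %% length(sid) + 1L]), call. = FALSE)
  }
  num[miss] <- NA_real_
  values <- t(matrix(num, nrow = length(sid),
                     dimnames = list(sid, gid)))
  expr_matrix(values, scale)
}

#' Write an expression matrix to a TSV file
#'
#' Values are serialized with 17 significant digits so that a
#' write/read round trip reproduces every double bit-for-bit.
#'
#' @param x an [expr_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  v <- unclass(x)
  fmt <- function(z) ifelse(is.na(z), "NA", sprintf("%.17g", z))
  rows <- vapply(seq_len(nrow(v)), function(i)
    paste(c(rownames(v)[i], fmt(v[i, ])), collapse = "\t"), character(1L))
  writeLines(c(paste(c("gene", colnames(v)), collapse = "\t"), rows), path,
             useBytes = TRUE)
  invisible(path)
}

#' Sample-to-group assignment
#'
#' @param assignment named character vector mapping sample id to group label.
#' @param group_order optional ordered vector of group labels; defaults to
#'   first-appearance order in `assignment`. Order matters: the earlier
#'   group in a pairwise comparison is the fold-difference denominator.
#' @return an object of class `group_design`.
#' @export
group_design <- function(assignment, group_order = NULL) {
  if (is.null(names(assignment)) || any(!nzchar(names(assignment))))
    stop("'assignment' must be a named vector (sample -> group)",
         call. = FALSE)
  if (anyDuplicated(names(assignment)))
    stop("sample(s) assigned more than once: ",
         paste(unique(names(assignment)[duplicated(names(assignment))]),
               collapse = ", "), call. = FALSE)
  assignment <- vapply(assignment, as.character, character(1L))
  if (is.null(group_order)) group_order <- unique(unname(assignment))
  if (!all(assignment %in% group_order))
    stop("group label(s) missing from 'group_order': ",
         paste(setdiff(assignment, group_order), collapse = ", "),
         call. = FALSE)
  structure(list(assignment = assignment,
                 group_order = as.character(group_order)),
            class = "group_design")
}

#' @export
print.group_design <- function(x, ...) {
  cnt <- table(factor(x$assignment, levels = x$group_order))
  cat("group_design:",
      paste(sprintf("%s (n=%d)", names(cnt), as.integer(cnt)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Samples belonging to each group, in design order
#' @param design a [group_design()].
#' @return named list of sample-id vectors.
#' @export
group_samples <- function(design) {
  stopifnot(inherits(design, "group_design"))
  lapply(stats::setNames(design$group_order, design$group_order),
         function(g) names(design$assignment)[design$assignment == g])
}

#' Read a sample-to-group design from a two-column TSV
#'
#' Columns: sample id, group label. A header line is detected (and skipped)
#' when its first field is `"sample"`. Group order defaults to first
#' appearance in the file.
#'
#' @param path path to the TSV file.
#' @param group_order optional explicit group order.
#' @return a [group_design()].
#' @export
read_group_design <- function(path, group_order = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty design file '", path, "'", call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2L))
    stop("line ", which(lengths(fields) < 2L)[1L], " of '", path,
         "' does not have two tab-separated fields", call. = FALSE)
  if (tolower(fields[[1L]][1L]) == "sample") fields <- fields[-1L]
  if (!length(fields)) stop("no assignments in '", path, "'", call. = FALSE)
  sam <- vapply(fields, `[[`, character(1L), 1L)
  grp <- vapply(fields, `[[`, character(1L), 2L)
  dup <- duplicated(sam)
  if (any(dup)) {
    clash <- sam[dup]
    stop("sample(s) assigned twice in '", path, "': ",
         paste(unique(clash), collapse = ", "), call. = FALSE)
  }
  group_design(stats::setNames(grp, sam), group_order = group_order)
}

#' Write a group design to a two-column TSV
#' @param design a [group_design()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_group_design <- function(design, path) {
  stopifnot(inherits(design, "group_design"))
  writeLines(c("sample\tgroup",
               paste(names(design$assignment), design$assignment,
                     sep = "\t")), path, useBytes = TRUE)
  invisible(path)
}

#' Read a grouped single- or multi-gene record in GEO-Profiles-export style
#'
#' Dialect-tolerant reader for the tabular exports served for curated
#' expression records: either (a) a series-matrix-style table whose header
#' starts with an identifier column (`ID_REF`, `IDENTIFIER`, `gene`, ...)
#' followed by sample columns, or (b) a two-column `sample<TAB>value` export
#' of a single record, in which case `gene` names the resulting row.
#' Samples absent from `design` are dropped with a warning; it is an error
#' when no sample overlaps.
#'
#' @param path path to the export.
#' @param design a [group_design()] mapping the record's samples to groups.
#' @param scale declared scale of the stored values (GEO Profiles records
#'   are typically linear-scale summaries; declare `"log2_intensity"` for
#'   log-transformed records and downstream fold computations will
#'   exponentiate).
#' @param gene row name used for the two-column dialect.
#' @return an [expr_matrix()] restricted to the mapped samples.
#' @export
read_geo_profile_export <- function(path, design,
                                    scale = c("linear", "log2_intensity"),
                                    gene = "record") {
  scale <- match.arg(scale)
  stopifnot(inherits(design, "group_design"))
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "!")]
  if (!length(lines)) stop("no data lines in '", path, "'", call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (all(lengths(fields) == 2L)) {
    if (tolower(fields[[1L]][1L]) %in% c("sample", "id_ref"))
      fields <- fields[-1L]
    sam <- vapply(fields, `[[`, character(1L), 1L)
    val <- as.numeric(vapply(fields, `[[`, character(1L), 2L))
    m <- matrix(val, nrow = 1L, dimnames = list(gene, sam))
  } else {
    tmp <- read_expression_matrix(path, scale)
    m <- unclass(tmp)
  }
  keep <- colnames(m) %in% names(design$assignment)
  if (!any(keep))
    stop("no overlap between samples in '", path,
         "' and the group design", call. = FALSE)
  if (any(!keep))
    warning("dropping ", sum(!keep), " unmapped sample(s): ",
            paste(colnames(m)[!keep], collapse = ", "), call. = FALSE)
  expr_matrix(m[, keep, drop = FALSE], scale)
}
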