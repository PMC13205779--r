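# Expression-matrix container and the normalization / dichotomization
# primitives used throughout the pipeline.

#' Construct an ExpressionMatrix
#'
#' The central container of the package: a nonnegative gene-by-sample value
#' matrix together with a gene-class annotation (`"snoRNA"` or `"mRNA"`) and
#' an optional tumor/normal sample grouping. Identifiers are case-sensitive
#' opaque strings and must be unique.
#'
#' @param values numeric matrix, genes in rows, samples in columns; dimnames
#'   required. All values must be finite and `>= 0`.
#' @param gene_class named character vector mapping every gene id to
#'   `"snoRNA"` or `"mRNA"`.
#' @param sample_group optional named character vector mapping sample ids to
#'   `"tumor"` or `"normal"`.
#' @return an object of class `ExpressionMatrix` with fields `values`,
#'   `gene_class`, `sample_group`.
#' @export
expression_matrix <- function(values, gene_class, sample_group = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stopf("`values` must be a numeric matrix")
  gid <- rownames(values); sid <- colnames(values)
  if (is.null(gid) || is.null(sid))
    stopf("`values` must have gene row names and sample column names")
  if (anyDuplicated(gid))
    stopf("duplicate gene identifiers: %s",
          paste(unique(gid[duplicated(gid)]), collapse = ", "))
  if (anyDuplicated(sid))
    stopf("duplicate sample identifiers: %s",
          paste(unique(sid[duplicated(sid)]), collapse = ", "))
  if (any(!is.finite(values)))
    stopf("non-finite expression values present")
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    stopf("negative expression value at gene '%s', sample '%s'",
          gid[bad[1]], sid[bad[2]])
  }
  missing <- setdiff(gid, names(gene_class))
  if (length(missing))
    stopf("genes missing from the class map: %s",
          paste(missing, collapse = ", "))
  gene_class <- gene_class[gid]
  if (!all(gene_class %in% c("snoRNA", "mRNA")))
    stopf("gene classes must be 'snoRNA' or 'mRNA'")
  if (!is.null(sample_group)) {
    sample_group <- sample_group[sid]
    if (anyNA(sample_group))
      stopf("sample_group does not cover all samples")
    if (!all(sample_group %in% c("tumor", "normal")))
      stopf("sample groups must be 'tumor' or 'normal'")
  }
  structure(list(values = values, gene_class = gene_class,
                 sample_group = sample_group),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples (%d snoRNA, %d mRNA)\n",
              nrow(x$values), ncol(x$values),
              sum(x$gene_class == "snoRNA"), sum(x$gene_class == "mRNA")))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

read_table_auto <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    quote = "", comment.char = "", stringsAsFactors = FALSE,
                    colClasses = NA)
}

#' Read an expression matrix and its gene-class map from disk
#'
#' The expression file is TSV (or CSV, by extension) with a header row of
#' sample ids and gene ids in the first column. The class map is a two-column
#' TSV (gene id, class); a header line is tolerated.
#'
#' @param path expression matrix file.
#' @param class_map_path two-column gene-class TSV.
#' @param sample_group optional named character vector (see
#'   [expression_matrix()]).
#' @return an [expression_matrix()] object; identifiers keep file order.
#' @export
read_expression <- function(path, class_map_path, sample_group = NULL) {
  tab <- read_table_auto(path)
  gid <- as.character(tab[[1]])
  if (anyDuplicated(gid))
    stopf("duplicate gene identifiers in '%s': %s", path,
          paste(unique(gid[duplicated(gid)]), collapse = ", "))
  vals <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(is.na(suppressWarnings(apply(tab[, -1, drop = FALSE], 2,
                                              as.numeric))), arr.ind = TRUE)
    stopf("non-numeric expression cell at row %d, column %d of '%s'",
          bad[1, 1], bad[1, 2] + 1L, path)
  }
  rownames(vals) <- gid
  cm <- utils::read.table(class_map_path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  if (ncol(cm) < 2) stopf("class map '%s' must have two columns", class_map_path)
  if (!cm[1, 2] %in% c("snoRNA", "mRNA")) cm <- cm[-1, , drop = FALSE]
  gene_class <- stats::setNames(as.character(cm[[2]]), as.character(cm[[1]]))
  expression_matrix(vals, gene_class, sample_group)
}

#' Write an ExpressionMatrix (and optionally its class map) to TSV
#'
#' Values are serialized with 17 significant digits so that a
#' write/read round trip is bitwise lossless.
#'
#' @param m an [expression_matrix()] object.
#' @param path output TSV path for the values.
#' @param class_map_path optional path for the two-column class map.
#' @export
write_expression <- function(m, path, class_map_path = NULL) {
  vals <- m$values
  chr <- matrix(sprintf("%.17g", vals), nrow(vals),
                dimnames = dimnames(vals))
  out <- cbind(gene_id = rownames(vals), as.data.frame(chr, check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(class_map_path))
    utils::write.table(data.frame(names(m$gene_class), unname(m$gene_class)),
                       class_map_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Log-transform and quantile-normalize an expression matrix
#'
#' Applies `log2(x + 1)` followed by quantile normalization, the standard
#' preprocessing for the association analyses in this package. The reference
#' distribution is the row-wise mean of the column-sorted values; ties within
#' a column receive the mean of the reference values they span. After
#' normalization every column holds an identical multiset of values and
#' within-column rank order is preserved.
#'
#' With a single sample quantile normalization is undefined; only the log
#' transform is applied and a notice is emitted.
#'
#' @param m an [expression_matrix()] object with nonnegative values.
#' @param log2_transform apply the `log2(x + 1)` step first (disable when the
#'   input is already on log scale).
#' @return an [expression_matrix()] with normalized values.
#' @export
log_quantile_normalize <- function(m, log2_transform = TRUE) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  v <- m$values
  if (log2_transform) v <- log2(v + 1)
  if (ncol(v) == 1L) {
    message("single sample: quantile normalization skipped, log transform only")
  } else {
    dn <- dimnames(v)
    v <- limma::normalizeQuantiles(v, ties = TRUE)
    dimnames(v) <- dn
  }
  expression_matrix(pmax(v, 0), m$gene_class, m$sample_group)
}

#' Subset an ExpressionMatrix by samples and/or genes
#'
#' @param m an [expression_matrix()] object.
#' @param samples sample ids to keep (default all, in given order).
#' @param genes gene ids to keep (default all).
#' @return an [expression_matrix()] restricted to the selection.
#' @export
subset_samples <- function(m, samples = NULL, genes = NULL) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (is.null(samples)) samples <- colnames(m$values)
  if (is.null(genes)) genes <- rownames(m$values)
  expression_matrix(m$values[genes, samples, drop = FALSE],
                    m$gene_class[genes],
                    if (!is.null(m$sample_group)) m$sample_group[samples])
}

#' Split samples into high/low groups at a gene's median expression
#'
#' Samples with expression strictly above the gene's median are `"high"`;
#' samples at or below the median are `"low"` (ties at the median go low,
#' making the split deterministic).
#'
#' @param m an [expression_matrix()] object with at least 4 samples.
#' @param gene gene id present in `m`.
#' @return named factor over samples with levels `low`, `high`.
#' @export
dichotomize_by_median <- function(m, gene) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (!gene %in% rownames(m$values)) stopf("gene '%s' not present", gene)
  x <- m$values[gene, ]
  if (length(x) < 4L) stopf("need at least 4 samples to dichotomize")
  med <- stats::median(x)
  grp <- factor(ifelse(x > med, "high", "low"), levels = c("low", "high"))
  names(grp) <- colnames(m$values)
  if (!all(c("low", "high") %in% grp))
    stopf("degenerate dichotomization for gene '%s'", gene)
  grp
}
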