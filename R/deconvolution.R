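# Cell-type-specific snoRNA expression by constrained least squares: bulk
# expression is modeled as a cell-fraction-weighted mixture of cell-type
# profiles, B[g, s] = sum_c beta[g, c] * X[c, s], solved per gene under
# nonnegativity.

#' Construct a cell-fraction matrix
#'
#' Cell types (including `"tumor"`) in rows, samples in columns; every
#' column must sum to 1 within 1e-3. When a purity vector is supplied and
#' the tumor row disagrees with it by more than 0.01 anywhere, the tumor row
#' is set to the purity and the immune rows are rescaled to `1 - purity`
#' (with a message).
#'
#' @param fractions numeric matrix in `[0, 1]`, dimnames required, one row
#'   named `"tumor"`.
#' @param purity optional named purity vector.
#' @return an object of class `CellFractionMatrix` (list with `fractions`).
#' @export
cell_fraction_matrix <- function(fractions, purity = NULL) {
  if (!is.matrix(fractions) || is.null(rownames(fractions)) ||
      is.null(colnames(fractions)))
    stopf("`fractions` must be a matrix with celltype and sample names")
  if (!"tumor" %in% rownames(fractions)) stopf("a 'tumor' row is required")
  if (any(fractions < 0) || any(fractions > 1))
    stopf("fractions must lie in [0, 1]")
  cs <- colSums(fractions)
  if (any(cs < 0.999 | cs > 1.001))
    stopf("column sums must be within [0.999, 1.001]; worst: %.4f",
          cs[which.max(abs(cs - 1))])
  if (!is.null(purity)) {
    p <- purity[colnames(fractions)]
    if (anyNA(p)) stopf("purity must cover all samples")
    if (any(abs(fractions["tumor", ] - p) > 0.01)) {
      message("tumor row disagrees with supplied purity by > 0.01; ",
              "rescaling immune fractions to 1 - purity")
      imm <- setdiff(rownames(fractions), "tumor")
      immsum <- colSums(fractions[imm, , drop = FALSE])
      scale <- ifelse(immsum > 0, (1 - p) / immsum, 0)
      fractions[imm, ] <- sweep(fractions[imm, , drop = FALSE], 2, scale, "*")
      fractions["tumor", ] <- p
    }
  }
  structure(list(fractions = fractions), class = "CellFractionMatrix")
}

#' @export
print.CellFractionMatrix <- function(x, ...) {
  cat(sprintf("CellFractionMatrix: %d cell types x %d samples\n",
              nrow(x$fractions), ncol(x$fractions)))
  invisible(x)
}

#' Infer cell-type-specific expression by non-negative least squares
#'
#' Per gene `g`, solves `min || B[g, ] - beta %*% X ||^2` over `beta >= 0`
#' (active-set NNLS via `pracma::lsqnonneg`), where `X` is the cell-fraction
#' matrix. Bulk values enter on the linear (unlogged) scale so that the
#' additive mixture model holds. Nonnegativity reflects that expression
#' levels are nonnegative by definition.
#'
#' @param bulk an [expression_matrix()] with linear-scale values, or a plain
#'   numeric matrix with dimnames.
#' @param X a [cell_fraction_matrix()] over the same samples; requires
#'   `n_samples > n_celltypes` and full row rank.
#' @return object of class `CellTypeExpression`: list with `beta` (genes x
#'   cell types, `>= 0`) and `residual_rmse` (per gene).
#' @export
infer_celltype_expression <- function(bulk, X) {
  stopifnot(inherits(X, "CellFractionMatrix"))
  V <- if (inherits(bulk, "ExpressionMatrix")) bulk$values else bulk
  fr <- X$fractions
  if (!all(colnames(V) %in% colnames(fr)))
    stopf("fraction matrix does not cover all samples")
  fr <- fr[, colnames(V), drop = FALSE]
  K <- nrow(fr); n <- ncol(fr)
  if (n <= K) stopf("need more samples than cell types")
  qrX <- qr(t(fr))
  if (qrX$rank < K) {
    dep <- rownames(fr)[qrX$pivot[(qrX$rank + 1):K]]
    stopf("fraction matrix is rank deficient; collinear cell type(s): %s",
          paste(dep, collapse = ", "))
  }
  A <- t(fr)
  beta <- matrix(0, nrow(V), K, dimnames = list(rownames(V), rownames(fr)))
  rmse <- numeric(nrow(V))
  for (g in seq_len(nrow(V))) {
    fit <- pracma::lsqnonneg(A, V[g, ])
    beta[g, ] <- fit$x
    rmse[g] <- sqrt(sum(fit$resid.norm) / n)
  }
  structure(list(beta = beta,
                 residual_rmse = stats::setNames(rmse, rownames(V))),
            class = "CellTypeExpression")
}

#' @export
print.CellTypeExpression <- function(x, ...) {
  cat(sprintf("CellTypeExpression: %d genes x %d cell types (median RMSE %.3g)\n",
              nrow(x$beta), ncol(x$beta), stats::median(x$residual_rmse)))
  invisible(x)
}

#' Compare inferred expression of immune-related vs other snoRNAs
#'
#' For one cell type, computes `log10` of the ratio of mean inferred
#' expression of immune-related snoRNAs to that of all other snoRNAs, and a
#' two-sided Wilcoxon rank-sum p-value on the per-gene values. A zero
#' denominator mean leaves the ratio `NA` (flagged); the p-value is still
#' computed.
#'
#' @param ct a [infer_celltype_expression()] result.
#' @param gene_class named class vector (only snoRNA-class genes compared).
#' @param immune_set character vector of immune-related snoRNA ids.
#' @param celltype column of `ct$beta`.
#' @return list with `log10_ratio`, `p_wilcoxon`, `n_immune`, `n_other`,
#'   `flagged`.
#' @export
compare_immune_vs_other <- function(ct, gene_class, immune_set, celltype) {
  stopifnot(inherits(ct, "CellTypeExpression"))
  if (!celltype %in% colnames(ct$beta)) stopf("unknown cell type '%s'", celltype)
  snos <- intersect(rownames(ct$beta),
                    names(gene_class)[gene_class == "snoRNA"])
  imm <- intersect(snos, immune_set)
  oth <- setdiff(snos, immune_set)
  if (!length(imm) || !length(oth))
    stopf("both immune and other snoRNA groups must be nonempty")
  bi <- ct$beta[imm, celltype]; bo <- ct$beta[oth, celltype]
  flagged <- mean(bo) == 0
  ratio <- if (flagged) NA_real_ else log10(mean(bi) / mean(bo))
  p <- stats::wilcox.test(bi, bo, exact = FALSE)$p.value
  list(log10_ratio = ratio, p_wilcoxon = p,
       n_immune = length(imm), n_other = length(oth), flagged = flagged)
}
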