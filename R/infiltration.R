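# Correlation of snoRNAs with immune-cell infiltration, enrichment of
# infiltration-related snoRNAs among the immune-related set, and
# cross-estimator overlap testing.

#' Spearman correlation of snoRNAs with immune-cell abundances
#'
#' For every (snoRNA, immune cell type) pair: tie-corrected Spearman rho
#' (Pearson correlation of mid-ranks) with a two-sided p-value from the t
#' approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees
#' of freedom (the large-sample approximation, not the exact permutation
#' distribution). A pair is `related` when the correlation criterion and
#' `p < p_max` both hold; `mode = "absolute"` uses `|rho| >= rho_min` (the
#' criterion feeding subtype feature selection), `mode = "signed"` uses
#' `rho >= rho_min`. The absolute-mode call set always contains the
#' signed-mode set.
#'
#' No multiple-testing correction is applied at this stage; the calls are
#' exploratory.
#'
#' Constant abundance rows yield `NA` rho and are flagged, not errored.
#'
#' @param m a normalized [expression_matrix()] (>= 10 samples).
#' @param X a [cell_fraction_matrix()]; the tumor row is excluded.
#' @param snos snoRNA ids to test (default: all snoRNA-class genes).
#' @param rho_min,p_max call thresholds (defaults 0.3, 0.05).
#' @param mode `"absolute"` (default) or `"signed"`.
#' @return data.frame with columns `sno`, `celltype`, `rho`, `p`, `related`,
#'   `flagged`.
#' @export
spearman_infiltration <- function(m, X, snos = NULL, rho_min = 0.3,
                                  p_max = 0.05,
                                  mode = c("absolute", "signed")) {
  mode <- match.arg(mode)
  stopifnot(inherits(m, "ExpressionMatrix"), inherits(X, "CellFractionMatrix"))
  sid <- colnames(m$values)
  if (length(sid) < 10) stopf("need at least 10 samples")
  if (!all(sid %in% colnames(X$fractions)))
    stopf("fraction matrix does not cover all samples")
  if (is.null(snos)) snos <- names(m$gene_class)[m$gene_class == "snoRNA"]
  cts <- setdiff(rownames(X$fractions), "tumor")
  fr <- X$fractions[cts, sid, drop = FALSE]

  rank_rows <- function(mm) t(apply(mm, 1, rank))
  E <- rank_rows(m$values[snos, sid, drop = FALSE])
  const_ct <- apply(fr, 1, function(v) stats::sd(v) == 0)
  Fr <- rank_rows(fr)
  n <- length(sid)
  e_ok <- matrixStats_rowSds(E) > 0
  R <- matrix(NA_real_, length(snos), length(cts),
              dimnames = list(snos, cts))
  if (any(e_ok) && any(!const_ct))
    R[e_ok, !const_ct] <- tcrossprod(unit_rows(E[e_ok, , drop = FALSE]),
                                     unit_rows(Fr[!const_ct, , drop = FALSE]))
  R <- pmin(pmax(R, -1), 1)
  P <- 2 * stats::pt(-abs(R * sqrt((n - 2) / pmax(1 - R^2, 1e-300))), n - 2)
  P[!is.na(R) & abs(R) == 1] <- 0
  crit <- if (mode == "absolute") abs(R) >= rho_min else R >= rho_min
  out <- data.frame(sno = rep(snos, times = length(cts)),
                    celltype = rep(cts, each = length(snos)),
                    rho = as.vector(R), p = as.vector(P),
                    related = as.vector(crit & P < p_max),
                    flagged = as.vector(is.na(R)),
                    stringsAsFactors = FALSE)
  out$related[is.na(out$related)] <- FALSE
  out
}

#' Enrichment of infiltration-related snoRNAs among the immune-related set
#'
#' Same 2x2 Fisher machinery as [dysregulation_enrichment()].
#'
#' @param immune_set,related_set,universe character vectors; sets must be
#'   subsets of `universe`.
#' @return list with `odds_ratio`, `ci95`, `p`, `table`, `degenerate`.
#' @export
infiltration_enrichment <- function(immune_set, related_set, universe) {
  dysregulation_enrichment(immune_set, related_set, universe)
}

#' Hypergeometric overlap test between two call sets
#'
#' Upper-tail hypergeometric probability of an overlap at least as large as
#' observed, given the two set sizes and the universe size — the
#' consistency check between infiltration calls derived from different
#' fraction estimators. Reported p-values are floored at the smallest
#' positive double and flagged when the floor binds.
#'
#' @param calls_a,calls_b,universe character vectors; calls must be subsets
#'   of `universe`.
#' @return list with `p`, `overlap`, `underflow`.
#' @export
estimator_overlap_test <- function(calls_a, calls_b, universe) {
  if (!length(universe)) stopf("empty universe")
  if (length(setdiff(calls_a, universe)) || length(setdiff(calls_b, universe)))
    stopf("calls must be subsets of the universe")
  k <- length(intersect(calls_a, calls_b))
  p <- stats::phyper(k - 1, length(calls_a),
                     length(universe) - length(calls_a), length(calls_b),
                     lower.tail = FALSE)
  underflow <- p < .Machine$double.xmin
  list(p = max(p, .Machine$double.xmin), overlap = k, underflow = underflow)
}
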