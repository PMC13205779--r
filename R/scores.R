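# Formula-defined immune scores (MHC, CYT, arbitrary signature panels) and
# the threshold-sensitivity framework for the identification pipeline.

#' Canonical MHC-I gene panel
#'
#' Antigen-presentation machinery: HLA class I heavy chains, the TAP peptide
#' transporters, NLRC5 (the MHC-I transactivator), immunoproteasome
#' subunits and beta-2-microglobulin.
#' @return character vector of gene symbols.
#' @export
mhc_panel <- function() {
  c("HLA-A", "HLA-B", "HLA-C", "TAP1", "TAP2", "NLRC5", "PSMB9", "PSMB8",
    "B2M")
}

#' Cytolytic activity (CYT) gene panel
#' @return character vector: granzyme A and perforin.
#' @export
cyt_panel <- function() c("GZMA", "PRF1")

#' Mean median-centered panel score per sample
#'
#' Expression (assumed log-transformed upstream) of each panel gene is
#' centered by its median across samples; a sample's score is the mean of
#' the centered values over the measured panel genes. Unmeasured panel
#' genes are dropped; if none is measured, an error lists them.
#'
#' @param m a log-scale [expression_matrix()].
#' @param genes panel gene ids.
#' @return named numeric vector of per-sample scores.
#' @export
gene_panel_score <- function(m, genes) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  measured <- intersect(genes, rownames(m$values))
  if (!length(measured))
    stopf("no panel gene measured; missing: %s", paste(genes, collapse = ", "))
  V <- m$values[measured, , drop = FALSE]
  colMeans(V - apply(V, 1, stats::median))
}

#' MHC score per sample
#' @param m a log-scale [expression_matrix()].
#' @param panel override the default [mhc_panel()].
#' @return named numeric vector.
#' @export
mhc_score <- function(m, panel = mhc_panel()) gene_panel_score(m, panel)

#' Cytolytic activity score per sample
#' @param m a log-scale [expression_matrix()].
#' @param panel override the default [cyt_panel()].
#' @return named numeric vector.
#' @export
cyt_score <- function(m, panel = cyt_panel()) gene_panel_score(m, panel)

#' Score a collection of signatures
#'
#' Applies the same median-centered mean rule per signature.
#'
#' @param m a log-scale [expression_matrix()].
#' @param gsc a [gene_set_collection()].
#' @return numeric matrix, signatures x samples.
#' @export
signature_scores <- function(m, gsc) {
  stopifnot(inherits(gsc, "GeneSetCollection"))
  t(vapply(gsc$sets, function(s) gene_panel_score(m, s),
           numeric(ncol(m$values))))
}

#' Jaccard similarity of two sets
#'
#' `|a intersect b| / |a union b|`; two empty sets score 1 by convention
#' (with a message).
#' @param a,b vectors treated as sets.
#' @return number in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (!length(a) && !length(b)) {
    message("both sets empty; Jaccard = 1 by convention")
    return(1)
  }
  length(intersect(a, b)) / length(union(a, b))
}

#' Retention of the top-ranked baseline pairs in a new set
#'
#' Fraction of the first `min(n, length(baseline_ranked))` baseline pairs
#' (already ordered by ascending original p-value, ties by pair id) that
#' survive in `new_set`.
#'
#' @param baseline_ranked character vector of pair ids in baseline rank
#'   order (nonempty).
#' @param new_set character vector of pair ids.
#' @param n how many top pairs to track (default 100).
#' @return retention rate in `[0, 1]`.
#' @export
top_retention <- function(baseline_ranked, new_set, n = 100) {
  if (!length(baseline_ranked)) stopf("empty baseline")
  top <- utils::head(baseline_ranked, n)
  mean(top %in% new_set)
}

pair_id <- function(pairs) paste(pairs$sno, pairs$gene, sep = "|")

filter_pairs <- function(pairs, r_min, fdr_max, p_max) {
  keep <- !is.na(pairs$fdr_empirical) &
    abs(pairs$r_partial) > r_min &
    pairs$fdr_empirical < fdr_max &
    pairs$p_nominal < p_max
  pair_id(pairs)[keep]
}

#' Default one-at-a-time sensitivity grids
#'
#' The grid values scanned for the three identification thresholds: the
#' absolute partial-correlation cutoff, the empirical-FDR cutoff and the
#' nominal p-value cutoff.
#' @return named list of numeric vectors (`r_min`, `fdr_max`, `p_max`).
#' @export
default_sensitivity_grids <- function() {
  list(r_min = c(0.00, 0.02, 0.05, 0.08, 0.10, 0.12, 0.15, 0.20, 0.25, 0.30),
       fdr_max = c(0.01, 0.05, 0.10, 0.15, 0.20, 0.25, 0.30, 0.40, 0.50),
       p_max = c(0.001, 0.005, 0.01, 0.02, 0.05, 0.10, 0.15, 0.20, 0.30))
}

#' One-at-a-time threshold sensitivity of the pair-level identification
#'
#' Varies one threshold along its grid while holding the other two at their
#' baseline values, and reports for each grid point the number of robust
#' snoRNA-immune-gene pairs, the Jaccard similarity with the baseline pair
#' set, and the retention of the `n_top` most significant baseline pairs
#' (by nominal p-value, ties by pair id). Deterministic given the pair
#' table. An empty baseline set is reported with `NA` Jaccard (flagged).
#'
#' @param pairs pair table from [add_empirical_fdr()].
#' @param grids per-parameter grids ([default_sensitivity_grids()]).
#' @param baseline named vector/list with `r_min`, `fdr_max`, `p_max`
#'   (defaults 0.2, 0.25, 0.05).
#' @param n_top top-pair count for the retention metric (default 100).
#' @return data.frame with columns `parameter`, `value`, `n_pairs`,
#'   `jaccard_vs_baseline`, `top_retention`; attribute `baseline_empty`.
#' @export
sensitivity_grid <- function(pairs, grids = default_sensitivity_grids(),
                             baseline = c(r_min = 0.2, fdr_max = 0.25,
                                          p_max = 0.05),
                             n_top = 100) {
  baseline <- as.list(baseline)
  base_set <- filter_pairs(pairs, baseline$r_min, baseline$fdr_max,
                           baseline$p_max)
  base_empty <- !length(base_set)
  cand <- pairs[!is.na(pairs$fdr_empirical), , drop = FALSE]
  ranked <- pair_id(cand)[order(cand$p_nominal, pair_id(cand))]
  rows <- lapply(names(grids), function(param) {
    do.call(rbind, lapply(grids[[param]], function(v) {
      th <- baseline; th[[param]] <- v
      set <- filter_pairs(pairs, th$r_min, th$fdr_max, th$p_max)
      data.frame(parameter = param, value = v, n_pairs = length(set),
                 jaccard_vs_baseline = if (base_empty) NA_real_
                                       else jaccard(set, base_set),
                 top_retention = if (length(ranked))
                   top_retention(ranked, set, n_top) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  attr(out, "baseline_empty") <- base_empty
  out
}
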