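# Median-split GSEA arm: weighted Kolmogorov-Smirnov enrichment score with a
# phenotype-label permutation null.

# Vectorized Welch t statistics for genes x samples matrix V and a logical
# high-group indicator. Non-finite statistics (zero variance in both groups)
# become 0 so they rank neutrally.
welch_t_stats <- function(V, is_high) {
  n1 <- sum(is_high); n2 <- sum(!is_high)
  m1 <- rowMeans(V[, is_high, drop = FALSE])
  m2 <- rowMeans(V[, !is_high, drop = FALSE])
  v1 <- matrixStats_rowSds(V[, is_high, drop = FALSE])^2
  v2 <- matrixStats_rowSds(V[, !is_high, drop = FALSE])^2
  tt <- (m1 - m2) / sqrt(v1 / n1 + v2 / n2)
  tt[!is.finite(tt)] <- 0
  tt
}

# Welch t statistics for B label permutations at once. P1 is an n x B 0/1
# matrix of permuted high-group indicators (column sums all n1).
welch_t_stats_perm <- function(V, P1, n1) {
  n <- ncol(V); n2 <- n - n1
  S <- rowSums(V); S2 <- rowSums(V * V)
  M1 <- (V %*% P1) / n1
  Q1 <- (V * V) %*% P1
  M2 <- (S - n1 * M1) / n2
  v1 <- (Q1 - n1 * M1 * M1) / (n1 - 1)
  v2 <- ((S2 - Q1) - n2 * M2 * M2) / (n2 - 1)
  tt <- (M1 - M2) / sqrt(v1 / n1 + v2 / n2)
  tt[!is.finite(tt)] <- 0
  tt
}

#' Rank mRNAs by the signed Welch t statistic between two sample groups
#'
#' The ranking metric feeding GSEA: genes are ordered by decreasing t
#' statistic of high-group versus low-group expression; ties break by gene
#' id for determinism.
#'
#' @param m an [expression_matrix()].
#' @param groups factor from [dichotomize_by_median()] (levels low, high).
#' @param genes gene ids to rank (default: all mRNA-class genes).
#' @return named numeric vector of t statistics, in ranked (descending) order.
#' @export
rank_genes_by_welch_t <- function(m, groups, genes = NULL) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (is.null(genes)) genes <- names(m$gene_class)[m$gene_class == "mRNA"]
  V <- m$values[genes, names(groups), drop = FALSE]
  tt <- welch_t_stats(V, groups == "high")
  names(tt) <- genes
  tt[order(-tt, names(tt))]
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Classic GSEA running sum with weight exponent 1: walking down the ranked
#' list, hits increment by `|stat| / sum(|stat| over hits)` and misses
#' decrement by `1 / (N - N_hit)`; the enrichment score is the running sum's
#' signed maximum deviation from zero. When every hit has zero weight the
#' hit increments fall back to equal steps.
#'
#' @param ranked named numeric vector of ranking statistics, already in list
#'   order (use [rank_genes_by_welch_t()]); names are unique gene ids.
#' @param gene_set character vector of member gene ids.
#' @return the enrichment score in `[-1, 1]`.
#' @export
gsea_enrichment_score <- function(ranked, gene_set) {
  if (anyDuplicated(names(ranked))) stopf("ranked list has duplicate genes")
  hit <- names(ranked) %in% gene_set
  n_hit <- sum(hit)
  if (n_hit == 0L || n_hit == length(ranked))
    stopf("gene set is empty or spans the whole list after intersection")
  w <- abs(ranked)
  wsum <- sum(w[hit])
  inc <- if (wsum > 0) w / wsum else rep(1 / n_hit, length(ranked))
  step <- ifelse(hit, inc, -1 / (length(ranked) - n_hit))
  running <- cumsum(step)
  unname(running[which.max(abs(running))])
}

# Enrichment scores of several sets against one ordering; memb is a logical
# genes x sets matrix aligned to the unranked gene universe, ord the ranking
# permutation, w the |stat| weights in ranked order.
es_multi <- function(memb, ord, w) {
  N <- length(ord)
  vapply(seq_len(ncol(memb)), function(j) {
    hit <- memb[ord, j]
    n_hit <- sum(hit)
    wsum <- sum(w[hit])
    inc <- if (wsum > 0) w / wsum else rep(1 / n_hit, N)
    running <- cumsum(ifelse(hit, inc, -1 / (N - n_hit)))
    running[which.max(abs(running))]
  }, 0)
}

#' Median-split GSEA of one snoRNA against a pathway collection
#'
#' Samples are dichotomized at the snoRNA's median expression
#' ([dichotomize_by_median()]); mRNAs are ranked by the signed Welch t
#' statistic between the high and low groups, and each pathway is scored by
#' the weighted KS enrichment score. The null distribution comes from
#' `n_perm` phenotype-label permutations (group labels reshuffled, gene-gene
#' correlation preserved); per pathway,
#' `NES = ES / mean(|null ES| of matching sign)` and the permutation p-value
#' is the two-sided magnitude test `(b + 1) / (B + 1)` with
#' `b = #{|null ES| >= |ES|}`, which is uniform under label exchange and
#' keeps full `1/(B+1)` resolution. BH q-values
#' are computed across the pathways of this snoRNA; both the `q < q_max` and
#' `q < padj_max` thresholds of the identification arm are applied to this
#' one BH value downstream.
#'
#' Pathways whose effective size (after intersection with the measured mRNA
#' universe) falls outside `[min_gs, max_gs]` are skipped with a message;
#' a failed dichotomization skips the snoRNA (empty result).
#'
#' @param m a normalized [expression_matrix()].
#' @param sno snoRNA-class gene id.
#' @param sets a [gene_set_collection()].
#' @param thresholds an [id_thresholds()] (uses `n_perm`, `min_gs`, `max_gs`).
#' @param seed run seed; the snoRNA's permutation stream is derived from it.
#' @return data.frame with columns `sno`, `pathway`, `es`, `nes`, `p_perm`,
#'   `q_bh`, `set_size_effective` (zero rows if the snoRNA was skipped).
#' @export
gsea_for_sno <- function(m, sno, sets, thresholds = id_thresholds(), seed = 1) {
  stopifnot(inherits(m, "ExpressionMatrix"), inherits(sets, "GeneSetCollection"))
  if (!identical(unname(m$gene_class[sno]), "snoRNA"))
    stopf("'%s' is not a snoRNA-class gene", sno)
  empty <- data.frame(sno = character(), pathway = character(), es = numeric(),
                      nes = numeric(), p_perm = numeric(), q_bh = numeric(),
                      set_size_effective = integer(), stringsAsFactors = FALSE)
  groups <- tryCatch(dichotomize_by_median(m, sno), error = function(e) {
    message(sprintf("skipping %s: %s", sno, conditionMessage(e)))
    NULL
  })
  if (is.null(groups)) return(empty)

  universe <- names(m$gene_class)[m$gene_class == "mRNA"]
  if (length(universe) < thresholds$min_gs)
    stopf("mRNA universe smaller than min_gs")
  sizes <- effective_set_sizes(sets, universe)
  keep <- sizes >= thresholds$min_gs & sizes <= thresholds$max_gs
  if (any(!keep))
    message(sprintf("skipping %d pathway(s) outside size bounds [%d, %d]: %s",
                    sum(!keep), thresholds$min_gs, thresholds$max_gs,
                    paste(names(sizes)[!keep], collapse = ", ")))
  if (!any(keep)) return(empty)
  set_names <- names(sets$sets)[keep]

  V <- m$values[universe, names(groups), drop = FALSE]
  is_high <- groups == "high"
  memb <- vapply(sets$sets[set_names], function(s) universe %in% s,
                 logical(length(universe)))
  t_obs <- welch_t_stats(V, is_high)
  ord_obs <- order(-t_obs, universe)
  es_obs <- es_multi(memb, ord_obs, abs(t_obs)[ord_obs])

  B <- thresholds$n_perm
  n <- length(is_high); n1 <- sum(is_high)
  null_es <- with_seed(derive_seed(seed, "gsea", sno), {
    P1 <- matrix(0, n, B)
    for (b in seq_len(B)) P1[sample.int(n, n1), b] <- 1
    Tperm <- welch_t_stats_perm(V, P1, n1)
    out <- matrix(0, B, length(set_names))
    for (b in seq_len(B)) {
      tb <- Tperm[, b]
      ob <- order(-tb, universe)
      out[b, ] <- es_multi(memb, ob, abs(tb)[ob])
    }
    out
  })

  nes <- p_perm <- numeric(length(set_names))
  for (j in seq_along(set_names)) {
    same_sign <- if (es_obs[j] >= 0) null_es[, j] >= 0 else null_es[, j] < 0
    nulls <- null_es[same_sign, j]
    nes[j] <- if (length(nulls) && mean(abs(nulls)) > 0)
      es_obs[j] / mean(abs(nulls)) else NA_real_
    # two-sided magnitude test over all null draws: |ES| is exchangeable
    # under label permutation, so this p is uniform under the null and its
    # resolution is 1/(B+1) (a sign-split tail would floor at ~2/B)
    p_perm[j] <- (sum(abs(null_es[, j]) >= abs(es_obs[j])) + 1) / (B + 1)
  }
  data.frame(sno = sno, pathway = set_names, es = es_obs, nes = nes,
             p_perm = p_perm, q_bh = bh_fdr(p_perm),
             set_size_effective = as.integer(sizes[keep]),
             stringsAsFactors = FALSE, row.names = NULL)
}
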