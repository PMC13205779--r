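# Final identification of immune-related snoRNAs: intersection of the
# purity-adjusted partial-correlation arm and the GSEA arm.

#' Thresholds for the identification pipeline
#'
#' Defaults: partial-correlation arm `|r| > 0.2`, nominal `p < 0.05`,
#' empirical FDR `< 0.25`; GSEA arm `q < 0.25` and adjusted `p < 0.05` (both
#' applied to the per-snoRNA BH q-value); 1000 permutations; pathway size
#' bounds `[10, 500]`. Every value can be overridden.
#'
#' @param r_min,p_max,fdr_max partial-correlation arm thresholds.
#' @param gsea_q_max,gsea_padj_max GSEA arm thresholds.
#' @param n_perm permutations for both permutation stages.
#' @param min_gs,max_gs effective pathway size bounds.
#' @return an `id_thresholds` list.
#' @export
id_thresholds <- function(r_min = 0.2, p_max = 0.05, fdr_max = 0.25,
                          gsea_q_max = 0.25, gsea_padj_max = 0.05,
                          n_perm = 1000, min_gs = 10, max_gs = 500) {
  if (r_min < 0 || r_min > 1) stopf("r_min must be in [0, 1]")
  for (v in c(p_max, fdr_max, gsea_q_max, gsea_padj_max))
    if (v <= 0 || v > 1) stopf("probability thresholds must be in (0, 1]")
  if (n_perm < 1) stopf("n_perm must be >= 1")
  if (min_gs < 1 || max_gs < min_gs) stopf("invalid pathway size bounds")
  structure(list(r_min = r_min, p_max = p_max, fdr_max = fdr_max,
                 gsea_q_max = gsea_q_max, gsea_padj_max = gsea_padj_max,
                 n_perm = n_perm, min_gs = min_gs, max_gs = max_gs),
            class = "id_thresholds")
}

#' Intersect the two identification arms
#'
#' A snoRNA is immune-related when it has (i) at least one immune-gene pair
#' with nominal `p < p_max`, `|r_partial| > r_min` and empirical FDR
#' `< fdr_max`, and (ii) at least one pathway GSEA record with BH q below
#' both `gsea_q_max` and `gsea_padj_max`. "Any pathway" semantics: the two
#' arms need not agree on the pathway.
#'
#' @param pairs pair table from [add_empirical_fdr()].
#' @param gsea GSEA table ([gsea_for_sno()] rows, possibly many snoRNAs).
#' @param thresholds an [id_thresholds()].
#' @return sorted character vector of immune-related snoRNA ids.
#' @export
identify_immune_snoRNAs <- function(pairs, gsea, thresholds = id_thresholds()) {
  th <- thresholds
  arm1 <- unique(pairs$sno[
    !is.na(pairs$fdr_empirical) &
      pairs$p_nominal < th$p_max &
      abs(pairs$r_partial) > th$r_min &
      pairs$fdr_empirical < th$fdr_max])
  arm2 <- unique(gsea$sno[gsea$q_bh < th$gsea_q_max &
                            gsea$q_bh < th$gsea_padj_max])
  sort(intersect(arm1, arm2))
}

#' Run the full identification pipeline on one cohort
#'
#' Scans all snoRNA x immune-gene partial correlations controlling for
#' tumor purity, attaches permutation empirical FDR to the screened
#' candidate pairs, runs median-split GSEA for the snoRNAs that pass the
#' partial-correlation arm (computing it for the remaining snoRNAs cannot
#' change the intersection), and intersects the two arms.
#'
#' @param m a normalized [expression_matrix()].
#' @param purity named purity vector over the samples of `m`.
#' @param sets immune pathway [gene_set_collection()].
#' @param thresholds an [id_thresholds()].
#' @param seed run seed controlling both permutation stages.
#' @param gsea_all also run GSEA for snoRNAs failing arm 1 (slower; the
#'   identified set is identical).
#' @return list with `pairs` (pair table incl. empirical FDR), `gsea`
#'   (GSEA records), `immune_sno` (identified set) and `arm1_sno`.
#' @export
run_identification <- function(m, purity, sets,
                               thresholds = id_thresholds(), seed = 1,
                               gsea_all = FALSE) {
  immune_genes <- unique(unlist(sets$sets))
  pairs <- partial_correlation_scan(m, purity, immune_genes)
  pairs <- add_empirical_fdr(pairs, m, purity, B = thresholds$n_perm,
                             seed = seed, p_screen = thresholds$p_max)
  th <- thresholds
  arm1 <- sort(unique(pairs$sno[
    !is.na(pairs$fdr_empirical) &
      pairs$p_nominal < th$p_max &
      abs(pairs$r_partial) > th$r_min &
      pairs$fdr_empirical < th$fdr_max]))
  gsea_snos <- if (gsea_all)
    sort(unique(names(m$gene_class)[m$gene_class == "snoRNA"])) else arm1
  gsea <- do.call(rbind, lapply(gsea_snos, function(s)
    gsea_for_sno(m, s, sets, thresholds, seed = seed)))
  if (is.null(gsea))
    gsea <- data.frame(sno = character(), pathway = character(),
                       es = numeric(), nes = numeric(), p_perm = numeric(),
                       q_bh = numeric(), set_size_effective = integer())
  list(pairs = pairs, gsea = gsea,
       immune_sno = identify_immune_snoRNAs(pairs, gsea, thresholds),
       arm1_sno = arm1)
}
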