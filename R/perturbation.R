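# Tumor-vs-normal dysregulation, including the zero-inflation-aware On/Off
# procedure, and Fisher enrichment of dysregulation among immune-related
# snoRNAs.

#' Choose the differential-expression mode for one gene
#'
#' Genes with a zero-expression rate of at least 30% across all samples (on
#' the `log2(TPM + 1)` scale, i.e. TPM exactly 0) are tested by the On/Off
#' procedure; the rest by a t test. The boundary belongs to On/Off: exactly
#' 30% zeros selects `"onoff"`.
#'
#' @param values numeric vector over all samples (>= 10).
#' @return `"ttest"` or `"onoff"`.
#' @export
classify_de_mode <- function(values) {
  if (length(values) < 10) stopf("need at least 10 samples")
  if (mean(values == 0) >= 0.30) "onoff" else "ttest"
}

#' Two-sided unpaired t test for tumor-vs-normal expression
#'
#' Welch's unequal-variance t test by default (`var_equal = TRUE` restores
#' the pooled-variance Student flavor). Effect is `mean(tumor) -
#' mean(normal)` on the normalized scale. Two zero-variance groups yield
#' `p = 1` when the means agree and `p = 0` otherwise.
#'
#' @param tumor,normal numeric vectors, each with >= 5 samples.
#' @param var_equal pooled-variance (Student) flavor.
#' @return list with `effect` and `p`.
#' @export
ttest_de <- function(tumor, normal, var_equal = FALSE) {
  if (length(tumor) < 5 || length(normal) < 5)
    stopf("each group needs at least 5 samples")
  effect <- mean(tumor) - mean(normal)
  if (stats::sd(tumor) == 0 && stats::sd(normal) == 0)
    return(list(effect = effect, p = if (effect == 0) 1 else 0))
  p <- stats::t.test(tumor, normal, var.equal = var_equal)$p.value
  list(effect = effect, p = p)
}

# Shared 2x2 Fisher machinery: two-sided exact p, sample odds ratio with
# Haldane 0.5 correction when any cell is zero, Woolf-logit 95% CI.
fisher_2x2 <- function(a, b, c, d) {
  tab <- matrix(c(a, b, c, d), 2, byrow = TRUE)
  p <- stats::fisher.test(tab)$p.value
  cells <- c(a, b, c, d)
  if (any(cells == 0)) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  ci <- exp(log(or) + c(-1, 1) * stats::qnorm(0.975) * se)
  list(odds_ratio = or, ci95 = ci, p = p)
}

#' On/Off differential expression by Fisher's exact test
#'
#' Compares the proportion of samples with nonzero expression ("On")
#' between tumor and normal by the two-sided Fisher exact test. The
#' reported odds ratio is the sample odds ratio, with the Haldane 0.5
#' correction when any cell of the 2x2 table is zero.
#'
#' @param tumor_on,tumor_total,normal_on,normal_total counts
#'   (`total >= on >= 0`, totals positive).
#' @return list with `odds_ratio` and `p`.
#' @export
onoff_fisher <- function(tumor_on, tumor_total, normal_on, normal_total) {
  if (tumor_total <= 0 || normal_total <= 0) stopf("zero-total group")
  if (tumor_on < 0 || normal_on < 0 || tumor_on > tumor_total ||
      normal_on > normal_total) stopf("counts must satisfy total >= on >= 0")
  f <- fisher_2x2(tumor_on, tumor_total - tumor_on,
                  normal_on, normal_total - normal_on)
  list(odds_ratio = f$odds_ratio, p = f$p)
}

#' Tumor-vs-normal differential expression over a cohort
#'
#' Applies [classify_de_mode()] per gene: t-test genes are compared on the
#' normalized values ([ttest_de()]; effect = log2 mean difference), On/Off
#' genes by [onoff_fisher()] (effect = On-proportion difference). P-values
#' from both modes are pooled into a single BH pass; `dysregulated` means
#' `fdr < fdr_max`.
#'
#' @param m a normalized [expression_matrix()] whose `sample_group` labels
#'   tumor and normal samples (>= 5 each).
#' @param genes gene ids to test (default: snoRNA-class genes).
#' @param fdr_max significance threshold on the BH FDR (default 0.05).
#' @param var_equal see [ttest_de()].
#' @return data.frame with columns `gene`, `mode`, `effect`, `p`, `fdr`,
#'   `dysregulated`.
#' @export
differential_expression <- function(m, genes = NULL, fdr_max = 0.05,
                                    var_equal = FALSE) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (is.null(m$sample_group)) stopf("sample_group required")
  if (is.null(genes)) genes <- names(m$gene_class)[m$gene_class == "snoRNA"]
  tum <- m$sample_group == "tumor"
  nrm <- m$sample_group == "normal"
  if (sum(tum) < 5 || sum(nrm) < 5)
    stopf("need at least 5 tumor and 5 normal samples")
  res <- lapply(genes, function(g) {
    v <- m$values[g, ]
    mode <- classify_de_mode(v)
    if (mode == "ttest") {
      r <- ttest_de(v[tum], v[nrm], var_equal = var_equal)
      data.frame(gene = g, mode = mode, effect = r$effect, p = r$p)
    } else {
      on_t <- sum(v[tum] > 0); on_n <- sum(v[nrm] > 0)
      r <- onoff_fisher(on_t, sum(tum), on_n, sum(nrm))
      data.frame(gene = g, mode = mode,
                 effect = on_t / sum(tum) - on_n / sum(nrm), p = r$p)
    }
  })
  out <- do.call(rbind, res)
  out$fdr <- bh_fdr(pmin(pmax(out$p, .Machine$double.xmin), 1))
  out$dysregulated <- out$fdr < fdr_max
  out
}

#' Enrichment of dysregulation among immune-related snoRNAs
#'
#' Two-sided Fisher exact test on the 2x2 table (immune-related vs other) x
#' (dysregulated vs not) over a gene universe, with a Woolf-logit 95%
#' confidence interval (Haldane correction on zero cells). A table with an
#' empty margin is flagged (odds ratio `NA`) rather than errored.
#'
#' @param immune_set,dysregulated_set,universe character vectors; the sets
#'   must be subsets of `universe`.
#' @return list with `odds_ratio`, `ci95`, `p`, `table`, `degenerate`.
#' @export
dysregulation_enrichment <- function(immune_set, dysregulated_set, universe) {
  if (!length(universe)) stopf("empty universe")
  if (length(setdiff(immune_set, universe)) ||
      length(setdiff(dysregulated_set, universe)))
    stopf("sets must be subsets of the universe")
  imm <- universe %in% immune_set
  dys <- universe %in% dysregulated_set
  a <- sum(imm & dys); b <- sum(imm & !dys)
  c <- sum(!imm & dys); d <- sum(!imm & !dys)
  degenerate <- (a + b == 0) || (c + d == 0) || (a + c == 0) || (b + d == 0)
  f <- fisher_2x2(a, b, c, d)
  if (degenerate) {
    f$odds_ratio <- NA_real_
    f$ci95 <- c(NA_real_, NA_real_)
  }
  list(odds_ratio = f$odds_ratio, ci95 = f$ci95, p = f$p,
       table = matrix(c(a, b, c, d), 2, byrow = TRUE,
                      dimnames = list(c("immune", "other"),
                                      c("dysregulated", "not"))),
       degenerate = degenerate)
}
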