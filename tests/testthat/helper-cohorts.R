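# Shared fixtures, all generated in code and memoised for the session.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# The default synthetic cohort: the study conditions every planted-recovery
# check runs under.
default_cohort <- function() memo("default_cohort",
  generate_cohort(cohort_config(seed = 101)))

# Normalized tumor-sample expression matrix and purity of the default cohort.
default_tumor_norm <- function() memo("default_tumor_norm", {
  co <- default_cohort()
  tum <- names(co$purity)[co$expr$sample_group == "tumor"]
  list(m = log_quantile_normalize(subset_samples(co$expr, tum)),
       purity = co$purity[tum])
})

# Full identification run (scan + permutation FDR + GSEA + intersection) on
# the default cohort at 200 permutations.
default_identification <- function() memo("default_identification", {
  co <- default_cohort()
  tn <- default_tumor_norm()
  run_identification(tn$m, tn$purity, co$sets,
                     thresholds = id_thresholds(n_perm = 200), seed = 101)
})

# A small cohort for cheap structural tests.
small_cohort <- function() memo("small_cohort",
  generate_cohort(cohort_config(n_tumor = 80, n_normal = 10, n_snoRNA = 40,
                                n_immune_genes = 120, n_other_mRNA = 120,
                                n_subtypes = 1, seed = 7)))

# A random ExpressionMatrix with given dimensions (log-scale-like values).
random_expr <- function(n_gene, n_sample, seed = 1, n_sno = 0) {
  set.seed(seed)
  gid <- sprintf("G%03d", seq_len(n_gene))
  v <- matrix(stats::rexp(n_gene * n_sample), n_gene,
              dimnames = list(gid, sprintf("S%03d", seq_len(n_sample))))
  cls <- stats::setNames(rep(c("snoRNA", "mRNA"),
                             c(n_sno, n_gene - n_sno)), gid)
  expression_matrix(v, cls)
}
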