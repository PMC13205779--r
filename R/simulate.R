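# Synthetic cohort generator: a cell-type mixture model with tumor purity as
# confounder and exported ground truth, so every downstream stage of the
# pipeline can be tested against planted structure.

#' Configuration for a synthetic cohort
#'
#' Defaults describe a mid-sized bulk tumor cohort: 300 tumors plus 30
#' adjacent normals, 400 snoRNAs (a quarter genuinely immune-related), 300
#' immune-pathway genes and 700 background mRNAs, seven cell types (tumor
#' plus six immune types), three latent tumor subtypes, Beta(5, 2) tumor
#' purity, 15% snoRNA dropout, 0.4 log2 multiplicative noise and a 1.5 log2
#' planted effect size.
#'
#' @param n_tumor,n_normal tumor / adjacent-normal sample counts.
#' @param n_snoRNA,n_immune_genes,n_other_mRNA gene counts per class.
#' @param n_celltypes number of cell types including tumor.
#' @param n_subtypes number of latent tumor subtypes (1 = none planted).
#' @param frac_true_immune_sno fraction of snoRNAs planted as genuinely
#'   immune-related (co-expressed with immune pathways beyond purity).
#' @param purity_beta_params length-2 Beta parameters for tumor purity.
#' @param dropout_rate probability a (snoRNA, sample) value is zeroed.
#' @param noise_sd_log2 sd of multiplicative lognormal noise, log2 scale.
#' @param effect_size_log2 planted elevation, log2 scale.
#' @param seed mandatory integer seed.
#' @return a validated `cohort_config` list.
#' @export
cohort_config <- function(n_tumor = 300, n_normal = 30, n_snoRNA = 400,
                          n_immune_genes = 300, n_other_mRNA = 700,
                          n_celltypes = 7, n_subtypes = 3,
                          frac_true_immune_sno = 0.25,
                          purity_beta_params = c(5, 2),
                          dropout_rate = 0.15, noise_sd_log2 = 0.4,
                          effect_size_log2 = 1.5, seed) {
  if (missing(seed)) stopf("`seed` is mandatory")
  counts <- c(n_tumor = n_tumor, n_snoRNA = n_snoRNA,
              n_immune_genes = n_immune_genes, n_other_mRNA = n_other_mRNA,
              n_celltypes = n_celltypes, n_subtypes = n_subtypes)
  if (any(counts < 1)) stopf("all counts must be >= 1 (n_normal may be 0)")
  if (n_normal < 0) stopf("n_normal must be >= 0")
  if (n_celltypes < 2) stopf("need at least tumor plus one immune cell type")
  if (frac_true_immune_sno < 0 || frac_true_immune_sno > 1 ||
      dropout_rate < 0 || dropout_rate >= 1)
    stopf("proportions out of range")
  if (length(purity_beta_params) != 2 || any(purity_beta_params <= 0))
    stopf("purity_beta_params must be two positive numbers")
  if (round(frac_true_immune_sno * n_snoRNA) < 1)
    stopf("frac_true_immune_sno * n_snoRNA must round to at least 1")
  structure(as.list(environment()), class = "cohort_config")
}

rdirichlet <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              nrow = length(alpha))
  sweep(x, 2, colSums(x), "/")
}

# Depth (log2) of off-target depletion for cell-type-restricted marker genes,
# and the milder immune-cell depletion of tumor-enriched decoy snoRNAs.
MARKER_FLOOR_LOG2 <- 6
DECOY_IMMUNE_DEPLETION_LOG2 <- 2

#' Generate a synthetic cohort with planted ground truth
#'
#' Samples are mixtures of cell types: tumor purity is drawn from
#' `Beta(purity_beta_params)` (normals from Beta(2, 38), i.e. near 0.05 and
#' immune-dominated) and immune-cell fractions follow a uniform Dirichlet
#' rescaled to `1 - purity`. Per-gene cell-type log2 expression profiles
#' `beta` define bulk values `B = 2^beta %*% X` under multiplicative
#' lognormal noise, with dropout applied to snoRNAs.
#'
#' Planted structure:
#' * immune-pathway genes and *true* immune snoRNAs are cell-type-restricted
#'   markers of one immune cell type (off-target expression floored 6 log2
#'   units below baseline) elevated by `effect_size_log2` on the expressing
#'   type -- their shared dependence on immune-cell composition creates
#'   co-expression beyond purity;
#' * the remaining *decoy* snoRNAs are tumor-enriched: elevated by the same
#'   amount in tumor cells and mildly depleted (2 log2 units) in immune
#'   cells, so they correlate with immune genes through purity but carry no
#'   immune-composition signal;
#' * when `n_subtypes > 1`, disjoint blocks of decoy snoRNAs (up to 15 per
#'   subtype) are further shifted by `effect_size_log2` in the tumor cells of
#'   their subtype, planting a sample partition.
#'
#' Immune pathways are emitted as one gene set per immune cell type
#' (genes assigned to that type).
#'
#' `truth$beta` is the base linear-scale profile; the subtype shift sits on
#' top of it, so `expr == beta %*% fractions` holds exactly in the
#' noiseless/dropout-free limit only when `n_subtypes == 1`.
#'
#' @param cfg a [cohort_config()].
#' @return an object of class `synthetic_cohort`: list with `expr`
#'   ([expression_matrix()]), `purity` (named vector), `fractions`
#'   ([cell_fraction_matrix()]), `sets` ([gene_set_collection()]), and
#'   `truth` (list: `immune_sno`, `subtype`, `subtype_genes`, `beta`,
#'   `sno_home`, `gene_home`), plus the `config`.
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  with_seed(cfg$seed, {
    K <- cfg$n_celltypes
    imm_types <- if (K == 7) {
      c("B_cell", "CD8_Tcell", "CD4_Tcell", "Macrophage", "Neutrophil",
        "Dendritic")
    } else paste0("immune_", seq_len(K - 1))
    celltypes <- c("tumor", imm_types)

    n <- cfg$n_tumor + cfg$n_normal
    sid <- c(sprintf("T%04d", seq_len(cfg$n_tumor)),
             if (cfg$n_normal > 0) sprintf("N%04d", seq_len(cfg$n_normal)))
    group <- stats::setNames(rep(c("tumor", "normal"),
                                 c(cfg$n_tumor, cfg$n_normal)), sid)

    purity <- c(stats::rbeta(cfg$n_tumor, cfg$purity_beta_params[1],
                             cfg$purity_beta_params[2]),
                if (cfg$n_normal > 0) stats::rbeta(cfg$n_normal, 2, 38))
    comp <- rdirichlet(n, rep(1, K - 1))
    X <- rbind(purity, sweep(comp, 2, 1 - purity, "*"))
    dimnames(X) <- list(celltypes, sid)

    sno_ids <- sprintf("SNO%04d", seq_len(cfg$n_snoRNA))
    imm_ids <- sprintf("IMM%04d", seq_len(cfg$n_immune_genes))
    mrna_ids <- sprintf("MRNA%04d", seq_len(cfg$n_other_mRNA))
    gid <- c(sno_ids, imm_ids, mrna_ids)
    gene_class <- stats::setNames(
      rep(c("snoRNA", "mRNA"),
          c(cfg$n_snoRNA, cfg$n_immune_genes + cfg$n_other_mRNA)), gid)

    n_true <- round(cfg$frac_true_immune_sno * cfg$n_snoRNA)
    true_sno <- sort(sample(sno_ids, n_true))
    decoy_sno <- setdiff(sno_ids, true_sno)
    sno_home <- stats::setNames(sample(imm_types, n_true, replace = TRUE),
                                true_sno)
    gene_home <- stats::setNames(
      sample(imm_types, cfg$n_immune_genes, replace = TRUE), imm_ids)

    base <- stats::setNames(stats::runif(length(gid), 4, 9), gid)
    eff <- cfg$effect_size_log2
    beta <- matrix(rep(base, K), length(gid), K,
                   dimnames = list(gid, celltypes))
    # background mRNAs: broad with mild cell-type jitter
    beta[mrna_ids, ] <- beta[mrna_ids, ] +
      matrix(stats::rnorm(length(mrna_ids) * K, 0, 0.25), length(mrna_ids), K)
    # immune markers: restricted to the home immune type
    for (g in imm_ids) {
      beta[g, ] <- base[g] - MARKER_FLOOR_LOG2
      beta[g, gene_home[g]] <- base[g] + eff
    }
    for (g in true_sno) {
      beta[g, ] <- base[g] - MARKER_FLOOR_LOG2
      beta[g, sno_home[g]] <- base[g] + eff
    }
    # decoys: tumor-enriched -- elevated in tumor cells, mildly depleted in
    # immune cells (their purity-driven confound stays smooth in purity)
    beta[decoy_sno, ] <- beta[decoy_sno, ] - DECOY_IMMUNE_DEPLETION_LOG2
    beta[decoy_sno, "tumor"] <- base[decoy_sno] + eff

    bulk <- 2^beta %*% X

    subtype <- NULL
    subtype_genes <- list()
    if (cfg$n_subtypes > 1) {
      tum <- sid[group == "tumor"]
      subtype <- stats::setNames(
        sample(rep_len(seq_len(cfg$n_subtypes), length(tum))), tum)
      blk <- min(15L, length(decoy_sno) %/% cfg$n_subtypes)
      if (blk >= 1) {
        pool <- sample(decoy_sno, blk * cfg$n_subtypes)
        subtype_genes <- split(pool, rep(seq_len(cfg$n_subtypes), each = blk))
        names(subtype_genes) <- paste0("subtype", seq_len(cfg$n_subtypes))
        for (k in seq_len(cfg$n_subtypes)) {
          gk <- subtype_genes[[k]]
          sk <- names(subtype)[subtype == k]
          bulk[gk, sk] <- bulk[gk, sk] +
            (2^eff - 1) * tcrossprod(2^beta[gk, "tumor"], X["tumor", sk])
        }
      }
    }

    if (cfg$noise_sd_log2 > 0)
      bulk <- bulk * 2^matrix(stats::rnorm(length(bulk), 0, cfg$noise_sd_log2),
                              nrow(bulk))
    if (cfg$dropout_rate > 0) {
      mask <- matrix(stats::runif(cfg$n_snoRNA * n) < cfg$dropout_rate,
                     cfg$n_snoRNA)
      bulk[sno_ids, ][mask] <- 0
    }

    sets <- gene_set_collection(
      split(imm_ids, factor(gene_home, levels = imm_types))[
        lengths(split(imm_ids, factor(gene_home, levels = imm_types))) > 0],
      provenance = "synthetic immune pathways (one per immune cell type)")
    names(sets$sets) <- paste0("IMMUNE_", names(sets$sets))

    structure(list(
      expr = expression_matrix(bulk, gene_class, group),
      purity = stats::setNames(purity, sid),
      fractions = cell_fraction_matrix(X),
      sets = sets,
      truth = list(immune_sno = true_sno, subtype = subtype,
                   subtype_genes = subtype_genes, beta = 2^beta,
                   sno_home = sno_home, gene_home = gene_home),
      config = cfg), class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(paste0("synthetic_cohort: %d tumor + %d normal samples, ",
                     "%d snoRNAs (%d true immune), %d cell types\n"),
              x$config$n_tumor, x$config$n_normal, x$config$n_snoRNA,
              length(x$truth$immune_sno), x$config$n_celltypes))
  invisible(x)
}

#' Export a synthetic cohort as plain-text files
#'
#' Writes the expression matrix, gene-class map, purity vector, cell-fraction
#' matrix, immune pathway GMT and the ground-truth files into `dir`, in the
#' formats consumed by [read_expression()], [read_gmt()] and friends.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @param force overwrite existing files.
#' @return invisibly, the named vector of written paths.
#' @export
export_cohort <- function(cohort, dir, force = FALSE) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(expression = "expression.tsv", classes = "gene_classes.tsv",
             purity = "purity.tsv", fractions = "fractions.tsv",
             gmt = "pathways.gmt", truth_sno = "truth_immune_sno.txt",
             truth_subtype = "truth_subtype.tsv",
             truth_subtype_genes = "truth_subtype_genes.tsv",
             truth_beta = "truth_beta.tsv")
  paths <- stats::setNames(file.path(dir, paths), names(paths))
  exists_already <- paths[file.exists(paths)]
  if (length(exists_already) && !force)
    stopf("refusing to overwrite existing files (use force = TRUE): %s",
          paste(basename(exists_already), collapse = ", "))

  write_expression(cohort$expr, paths["expression"], paths["classes"])
  utils::write.table(
    data.frame(sample_id = names(cohort$purity),
               purity = sprintf("%.17g", cohort$purity)),
    paths["purity"], sep = "\t", quote = FALSE, row.names = FALSE)
  fr <- cohort$fractions$fractions
  utils::write.table(
    cbind(celltype = rownames(fr),
          as.data.frame(matrix(sprintf("%.17g", fr), nrow(fr),
                               dimnames = dimnames(fr)),
                        check.names = FALSE)),
    paths["fractions"], sep = "\t", quote = FALSE, row.names = FALSE)
  write_gmt(cohort$sets, paths["gmt"])
  writeLines(cohort$truth$immune_sno, paths["truth_sno"])
  if (!is.null(cohort$truth$subtype))
    utils::write.table(
      data.frame(sample_id = names(cohort$truth$subtype),
                 subtype = unname(cohort$truth$subtype)),
      paths["truth_subtype"], sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(cohort$truth$subtype_genes))
    utils::write.table(
      data.frame(
        subtype = rep(names(cohort$truth$subtype_genes),
                      lengths(cohort$truth$subtype_genes)),
        gene_id = unlist(cohort$truth$subtype_genes, use.names = FALSE)),
      paths["truth_subtype_genes"], sep = "\t", quote = FALSE,
      row.names = FALSE)
  tb <- cohort$truth$beta
  utils::write.table(
    cbind(gene_id = rownames(tb),
          as.data.frame(matrix(sprintf("%.17g", tb), nrow(tb),
                               dimnames = dimnames(tb)),
                        check.names = FALSE)),
    paths["truth_beta"], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
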