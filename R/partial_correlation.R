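# Purity-adjusted partial correlation, its permutation null, and the
# empirical-FDR machinery of the identification pipeline's first arm.

#' First-order partial correlation controlling for one covariate
#'
#' Computes the Pearson partial correlation of `x` and `y` given `z`,
#' \deqn{r_{xy.z} = (r_{xy} - r_{xz} r_{yz}) / \sqrt{(1-r_{xz}^2)(1-r_{yz}^2)},}
#' with the two-sided p-value from the t statistic
#' \eqn{r\sqrt{(n-3)/(1-r^2)}} on `n - 3` degrees of freedom. In this
#' pipeline `z` is tumor purity: the correlation between a snoRNA and an
#' immune gene after removing the linear effect of tumor-cell content, the
#' quantity that separates genuine immune co-expression from
#' purity-driven confounding.
#'
#' @param x,y,z equal-length numeric vectors, `n >= 5`, each non-constant.
#' @return list with `r_partial` and `p_nominal`.
#' @export
partial_correlation <- function(x, y, z) {
  n <- length(x)
  if (length(y) != n || length(z) != n) stopf("x, y, z must have equal length")
  if (n < 5) stopf("need at least 5 observations")
  for (v in list(x = x, y = y, z = z))
    if (stats::sd(v) == 0) stopf("constant vector supplied")
  rxy <- stats::cor(x, y); rxz <- stats::cor(x, z); ryz <- stats::cor(y, z)
  if (abs(rxz) >= 1 - 1e-12 || abs(ryz) >= 1 - 1e-12)
    stopf("covariate collinear")
  r <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  r <- max(-1, min(1, r))
  df <- n - 3
  p <- if (abs(r) >= 1) 0 else 2 * stats::pt(-abs(r * sqrt(df / (1 - r^2))), df)
  list(r_partial = r, p_nominal = p)
}

# Schafer-Strimmer linear shrinkage of the 3x3 correlation matrix toward the
# identity, then the partial correlation from its inverse. Used only as the
# optional permutation-null estimator.
shrinkage_partial_r <- function(x, y, z) {
  n <- length(x)
  W <- scale(cbind(x, y, z))            # unit-variance columns (denominator n-1)
  R <- stats::cor(W)
  off <- R[upper.tri(R)]
  # unbiased variance estimate of each off-diagonal correlation
  var_r <- vapply(list(c(1, 2), c(1, 3), c(2, 3)), function(ij) {
    w <- W[, ij[1]] * W[, ij[2]]
    n / (n - 1)^3 * sum((w - mean(w))^2)
  }, 0)
  lambda <- min(1, max(0, sum(var_r) / sum(off^2)))
  Rs <- (1 - lambda) * R
  diag(Rs) <- 1
  P <- solve(Rs)
  -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
}

#' Permutation empirical p-value for a partial correlation
#'
#' The snoRNA vector `x` is permuted `B` times while the immune-gene vector
#' `y` and the purity covariate `z` stay fixed; the partial correlation is
#' recomputed for each shuffle and the empirical p-value is
#' `(# permutations with |r*| >= |r_observed| + 1) / (B + 1)`.
#'
#' By default the permuted statistics use the same plain estimator as the
#' observed one, keeping the null exchangeable. `estimator = "shrinkage"`
#' instead recomputes the permuted statistics with a linear-shrinkage
#' estimator of the 3x3 correlation matrix (Schafer-Strimmer intensity);
#' with a single covariate the shrinkage target is negligible, and the mode
#' exists for fidelity checks only.
#'
#' Permuted draws with a degenerate correlation structure are counted with
#' statistic 0. Errors on the observed data propagate.
#'
#' @param x,y,z as [partial_correlation()].
#' @param B number of permutations (>= 1).
#' @param seed integer seed; the draw is reproducible.
#' @param estimator `"plain"` (default) or `"shrinkage"` for the null
#'   statistics.
#' @return list with `p_empirical` and `null_stats` (length `B`).
#' @export
permutation_empirical_p <- function(x, y, z, B = 1000, seed = 1,
                                    estimator = c("plain", "shrinkage")) {
  estimator <- match.arg(estimator)
  if (B < 1) stopf("B must be >= 1")
  obs <- partial_correlation(x, y, z)   # validates; errors propagate
  n <- length(x)
  null_stats <- with_seed(seed, {
    if (estimator == "shrinkage") {
      vapply(seq_len(B), function(b) {
        xp <- x[sample.int(n)]
        r <- tryCatch(shrinkage_partial_r(xp, y, z), error = function(e) 0)
        if (!is.finite(r)) 0 else r
      }, 0)
    } else {
      xs <- (x - mean(x)) / sqrt(sum((x - mean(x))^2))
      ys <- (y - mean(y)) / sqrt(sum((y - mean(y))^2))
      zs <- (z - mean(z)) / sqrt(sum((z - mean(z))^2))
      ryz <- sum(ys * zs)
      idx <- matrix(0L, n, B)
      for (b in seq_len(B)) idx[, b] <- sample.int(n)
      Xp <- matrix(xs[idx], n, B)
      rxy <- as.vector(crossprod(Xp, ys))
      rxz <- as.vector(crossprod(Xp, zs))
      denom2 <- (1 - rxz^2) * (1 - ryz^2)
      r <- ifelse(denom2 <= 0, 0, (rxy - rxz * ryz) / sqrt(pmax(denom2, 0)))
      r[!is.finite(r)] <- 0
      r
    }
  })
  p <- (sum(abs(null_stats) >= abs(obs$r_partial)) + 1) / (B + 1)
  list(p_empirical = p, null_stats = null_stats)
}

#' Benjamini-Hochberg false discovery rates
#'
#' Thin wrapper over `stats::p.adjust(method = "BH")` with the input checks
#' this pipeline relies on (p in (0, 1]; empty in, empty out).
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return BH-adjusted q-values, same order as `p`.
#' @export
bh_fdr <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stopf("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' All snoRNA x immune-gene partial correlations for one cohort
#'
#' Vectorized first-order partial correlation (identical to
#' [partial_correlation()] pair by pair): rows are residualized against the
#' purity covariate and cross-correlated. Constant rows (e.g. all-zero after
#' dropout) are dropped with a message.
#'
#' @param m a normalized [expression_matrix()].
#' @param purity named numeric vector over the samples of `m`.
#' @param immune_genes character vector of immune-pathway gene ids; the scan
#'   uses their intersection with the measured mRNA-class genes.
#' @return data.frame with columns `sno`, `gene`, `r_partial`, `p_nominal`.
#' @export
partial_correlation_scan <- function(m, purity, immune_genes) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  sid <- colnames(m$values)
  if (is.null(names(purity)) || !all(sid %in% names(purity)))
    stopf("purity must be named and cover all samples")
  z <- purity[sid]
  snos <- names(m$gene_class)[m$gene_class == "snoRNA"]
  genes <- intersect(immune_genes,
                     names(m$gene_class)[m$gene_class == "mRNA"])
  if (!length(snos) || !length(genes))
    stopf("need at least one snoRNA and one measured immune gene")

  keep_nonconstant <- function(ids) {
    v <- m$values[ids, , drop = FALSE]
    ok <- matrixStats_rowSds(v) > 0
    if (any(!ok))
      message(sprintf("dropping %d constant row(s) from the scan", sum(!ok)))
    ids[ok]
  }
  snos <- keep_nonconstant(snos)
  genes <- keep_nonconstant(genes)

  zc <- z - mean(z)
  resid_unit <- function(ids) {
    V <- m$values[ids, , drop = FALSE]
    Vc <- V - rowMeans(V)
    b <- (Vc %*% zc) / sum(zc^2)
    unit_rows(Vc - tcrossprod(b, zc))
  }
  R <- tcrossprod(resid_unit(snos), resid_unit(genes))
  R <- pmin(pmax(R, -1), 1)
  df <- length(z) - 3
  P <- 2 * stats::pt(-abs(R * sqrt(df / pmax(1 - R^2, 1e-300))), df)
  data.frame(sno = rep(snos, times = length(genes)),
             gene = rep(genes, each = length(snos)),
             r_partial = as.vector(R), p_nominal = as.vector(P),
             stringsAsFactors = FALSE)
}

matrixStats_rowSds <- function(v) {
  mu <- rowMeans(v)
  sqrt(rowSums((v - mu)^2) / max(1, ncol(v) - 1))
}

#' Attach permutation empirical p-values and empirical FDR to a pair table
#'
#' Pairs enter the permutation stage only when their nominal partial
#' correlation p-value passes the screening threshold (a prioritization
#' step, not a global FDR). Each candidate pair gets its own RNG stream,
#' seeded by hashing the run seed with the pair identifiers, and its
#' empirical p-value from [permutation_empirical_p()]. The empirical FDR is
#' Benjamini-Hochberg across all candidate pairs of the run; non-candidates
#' carry `NA`.
#'
#' @param pairs result of [partial_correlation_scan()].
#' @param m,purity as in [partial_correlation_scan()].
#' @param B permutations per pair.
#' @param seed run seed.
#' @param p_screen nominal-p screening threshold (default 0.05).
#' @param estimator permutation-null estimator, see
#'   [permutation_empirical_p()].
#' @return `pairs` with `p_empirical` and `fdr_empirical` columns added.
#' @export
add_empirical_fdr <- function(pairs, m, purity, B = 1000, seed = 1,
                              p_screen = 0.05,
                              estimator = c("plain", "shrinkage")) {
  estimator <- match.arg(estimator)
  sid <- colnames(m$values)
  z <- purity[sid]
  n <- length(z)
  cand <- which(pairs$p_nominal < p_screen)
  p_emp <- rep(NA_real_, nrow(pairs))
  if (length(cand)) {
    zs <- (z - mean(z)) / sqrt(sum((z - mean(z))^2))
    V <- m$values
    us <- function(v) (v - mean(v)) / sqrt(sum((v - mean(v))^2))
    # per-sno cache of the standardized snoRNA vector
    cand_by_sno <- split(cand, pairs$sno[cand])
    for (sno in names(cand_by_sno)) {
      xs <- us(V[sno, sid])
      for (i in cand_by_sno[[sno]]) {
        gene <- pairs$gene[i]
        if (estimator == "shrinkage") {
          p_emp[i] <- permutation_empirical_p(
            V[sno, sid], V[gene, sid], z, B = B,
            seed = derive_seed(seed, sno, gene),
            estimator = "shrinkage")$p_empirical
          next
        }
        ys <- us(V[gene, sid])
        ryz <- sum(ys * zs)
        null_r <- with_seed(derive_seed(seed, sno, gene), {
          idx <- matrix(0L, n, B)
          for (b in seq_len(B)) idx[, b] <- sample.int(n)
          Xp <- matrix(xs[idx], n, B)
          rxy <- as.vector(crossprod(Xp, ys))
          rxz <- as.vector(crossprod(Xp, zs))
          denom2 <- (1 - rxz^2) * (1 - ryz^2)
          r <- ifelse(denom2 <= 0, 0, (rxy - rxz * ryz) / sqrt(pmax(denom2, 0)))
          r[!is.finite(r)] <- 0
          r
        })
        p_emp[i] <- (sum(abs(null_r) >= abs(pairs$r_partial[i])) + 1) / (B + 1)
      }
    }
  }
  pairs$p_empirical <- p_emp
  pairs$fdr_empirical <- rep(NA_real_, nrow(pairs))
  if (length(cand)) pairs$fdr_empirical[cand] <- bh_fdr(p_emp[cand])
  pairs
}
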