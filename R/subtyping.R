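# Immune-snoRNA-based molecular subtyping: MAD feature selection, consensus
# clustering over subsampled hierarchical runs with CDF/delta-area k
# selection, and Monte-Carlo centroid cross-validation scored by the
# adjusted Rand index.

#' Select and center clustering features by median absolute deviation
#'
#' Candidate genes are log10-transformed (`log10(x + 1)`, disable when the
#' matrix is already on log scale), ranked by raw MAD (median absolute
#' deviation about the median, no 1.4826 consistency constant) in
#' descending order, the top `n_top` kept (default: all candidates), and
#' each kept row centered by subtracting its median (no scaling).
#'
#' @param m an [expression_matrix()].
#' @param candidate_set candidate gene ids (must intersect `m`).
#' @param n_top number of features to keep; `NULL` keeps all. A value larger
#'   than the candidate count warns and keeps all.
#' @param log10_transform apply `log10(x + 1)` first.
#' @return numeric feature matrix (features x samples), rows in decreasing
#'   MAD order, each row median-centered.
#' @export
select_features <- function(m, candidate_set, n_top = NULL,
                            log10_transform = TRUE) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  cand <- intersect(candidate_set, rownames(m$values))
  if (!length(cand)) stopf("candidate set is empty in the matrix")
  V <- m$values[cand, , drop = FALSE]
  if (log10_transform) V <- log10(V + 1)
  mads <- apply(V, 1, stats::mad, constant = 1)
  ord <- order(-mads, cand)
  if (!is.null(n_top)) {
    if (n_top > length(cand)) {
      warning(sprintf("n_top = %d exceeds %d candidates; keeping all",
                      n_top, length(cand)))
      n_top <- length(cand)
    }
    ord <- ord[seq_len(n_top)]
  }
  V <- V[ord, , drop = FALSE]
  V - apply(V, 1, stats::median)
}

# 1 - Spearman correlation between sample columns, as a dist-convertible
# matrix. Ranks are taken within each sample's feature vector, so the full
# matrix can be computed once and subset per consensus iteration.
spearman_dist_matrix <- function(features) {
  ranks <- apply(features, 2, rank)   # features x samples, ranked per sample
  U <- unit_rows(t(ranks))            # samples x features, unit rows
  D <- 1 - tcrossprod(U)
  D[D < 0] <- 0
  D
}

#' Consensus clustering over subsampled hierarchical runs
#'
#' Per iteration, `ceil(p_item * n)` samples are drawn without replacement,
#' pairwise distances are `1 - Spearman correlation` between sample feature
#' vectors, and average-linkage hierarchical clustering is cut at every `k`
#' in `k_range`. The consensus matrix entry for a sample pair is its
#' co-clustering count divided by its co-sampling count. Final labels come
#' from average-linkage clustering of `1 - consensus` at each `k`; the
#' empirical CDF of the consensus entries and the delta-area statistic
#' (relative gain in area under the CDF, with `delta_area(k_min) =
#' area(k_min)`) support the choice of `k`.
#'
#' @param features feature matrix from [select_features()] (>= 2 rows).
#' @param k_range integer vector of cluster numbers (default 2:6); needs at
#'   least `3 * max(k_range)` samples.
#' @param iters subsampling iterations (default 1000).
#' @param p_item sample subsampling proportion (default 0.8).
#' @param seed integer seed; runs are bitwise reproducible.
#' @param linkage hierarchical linkage (default `"average"`), used for both
#'   the inner runs and the final consensus clustering.
#' @return object of class `consensus_result_set`: per-`k` list of results
#'   (`k`, `consensus`, `labels`, `cdf`, `area`) plus a `delta_area`
#'   data.frame with columns `k`, `area`, `delta`.
#' @export
consensus_cluster <- function(features, k_range = 2:6, iters = 1000,
                              p_item = 0.8, seed = 1, linkage = "average") {
  if (nrow(features) < 2) stopf("need at least 2 features")
  n <- ncol(features)
  k_range <- sort(unique(as.integer(k_range)))
  if (n < 3 * max(k_range))
    stopf("need at least %d samples for k up to %d", 3 * max(k_range),
          max(k_range))
  sid <- colnames(features)
  D <- spearman_dist_matrix(features)
  n_sub <- ceiling(p_item * n)

  co_cluster <- lapply(k_range, function(k) matrix(0, n, n))
  names(co_cluster) <- as.character(k_range)
  co_sample <- matrix(0, n, n)
  with_seed(seed, {
    for (it in seq_len(iters)) {
      sub <- sort(sample.int(n, n_sub))
      co_sample[sub, sub] <- co_sample[sub, sub] + 1
      hc <- stats::hclust(stats::as.dist(D[sub, sub]), method = linkage)
      for (k in k_range) {
        cl <- stats::cutree(hc, k = k)
        Mk <- outer(cl, cl, "==")
        kk <- as.character(k)
        co_cluster[[kk]][sub, sub] <- co_cluster[[kk]][sub, sub] + Mk
      }
    }
  })

  results <- lapply(k_range, function(k) {
    cons <- co_cluster[[as.character(k)]] / pmax(co_sample, 1)
    cons[co_sample == 0] <- 0
    diag(cons) <- 1
    dimnames(cons) <- list(sid, sid)
    hc <- stats::hclust(stats::as.dist(1 - cons), method = linkage)
    labels <- stats::setNames(stats::cutree(hc, k = k), sid)
    vals <- sort(cons[upper.tri(cons)])
    cdf <- stats::ecdf(vals)
    u <- unique(c(0, vals, 1))
    area <- sum(diff(u) * cdf(u[-length(u)]))
    list(k = k, consensus = cons, labels = labels, cdf = cdf, area = area)
  })
  names(results) <- as.character(k_range)
  areas <- vapply(results, `[[`, 0, "area")
  delta <- c(areas[1], diff(areas) / utils::head(areas, -1))
  structure(list(results = results,
                 delta_area = data.frame(k = k_range, area = unname(areas),
                                         delta = unname(delta))),
            class = "consensus_result_set")
}

#' @export
print.consensus_result_set <- function(x, ...) {
  cat("consensus_result_set\n")
  print(x$delta_area, row.names = FALSE)
  invisible(x)
}

#' Choose the number of clusters from the delta-area profile
#'
#' Default rule: the smallest `k` whose relative area gain at `k + 1` falls
#' below `threshold` (0.1). If no `k` qualifies the CDF shows no dominant
#' elbow and the smallest `k` is returned with a "no structure" rationale.
#' The full area/delta table is attached so the choice is auditable.
#'
#' @param cc a [consensus_cluster()] result (>= 2 values of k).
#' @param threshold relative delta-area elbow threshold (default 0.1).
#' @return list with `k`, `rationale`, `delta_area`.
#' @export
choose_k <- function(cc, threshold = 0.1) {
  stopifnot(inherits(cc, "consensus_result_set"))
  da <- cc$delta_area
  if (nrow(da) < 2) stopf("need at least two values of k")
  for (i in seq_len(nrow(da) - 1)) {
    if (da$delta[i + 1] < threshold) {
      return(list(k = da$k[i],
                  rationale = sprintf(
                    "relative delta-area gain at k = %d is %.3f < %.2f",
                    da$k[i + 1], da$delta[i + 1], threshold),
                  delta_area = da))
    }
  }
  list(k = da$k[1],
       rationale = "no k shows a dominant consensus gain (no structure); defaulting to smallest k",
       delta_area = da)
}

#' Adjusted Rand index between two labelings
#'
#' Hubert-Arabie chance-corrected agreement from the contingency table:
#' `(sum C(n_ij,2) - E) / (0.5 * (sum C(a_i,2) + sum C(b_j,2)) - E)` with
#' `E = sum C(a_i,2) * sum C(b_j,2) / C(n,2)`. 1 means identical
#' partitions, about 0 chance-level agreement.
#'
#' @param a,b label vectors over the same samples (length >= 2).
#' @return the ARI, a number `<= 1`.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stopf("labelings must cover the same samples")
  n <- length(a)
  if (n < 2) stopf("need at least two samples")
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  expected <- sum_a * sum_b / ch2(n)
  denom <- (sum_a + sum_b) / 2 - expected
  if (denom == 0) return(if (sum_ij == expected) 1 else 0)
  (sum_ij - expected) / denom
}

#' Monte-Carlo cross-validation of a consensus subtyping
#'
#' Repeated 80/20 train-test splits: consensus clustering at fixed `k` on
#' the training samples, per-cluster centroids as feature-wise medians, each
#' test sample assigned to the centroid with the highest Spearman
#' correlation, and the predicted test labels compared with the
#' full-dataset reference labels (restricted to the test samples) by the
#' adjusted Rand index. Iterations that fail (e.g. a degenerate training
#' fold) are excluded and counted.
#'
#' @param features feature matrix from [select_features()].
#' @param k fixed number of clusters.
#' @param reference_labels named full-data labels (e.g. from the full
#'   [consensus_cluster()] run).
#' @param iterations number of random splits (default 100).
#' @param split training fraction (default 0.8).
#' @param seed integer seed.
#' @param cc_iters,p_item,linkage consensus-clustering settings for the
#'   training runs.
#' @return object of class `cv_report`: list with `ari_per_iter`,
#'   `ari_mean`, `ci95` (normal approximation over iterations), `n_failed`.
#' @export
monte_carlo_cv <- function(features, k, reference_labels, iterations = 100,
                           split = 0.8, seed = 1, cc_iters = 200,
                           p_item = 0.8, linkage = "average") {
  n <- ncol(features)
  sid <- colnames(features)
  if (is.null(names(reference_labels)) || !all(sid %in% names(reference_labels)))
    stopf("reference_labels must be named and cover all samples")
  n_train <- floor(split * n)
  aris <- rep(NA_real_, iterations)
  for (it in seq_len(iterations)) {
    res <- tryCatch({
      train <- with_seed(derive_seed(seed, "cv-split", it),
                         sort(sample.int(n, n_train)))
      test <- setdiff(seq_len(n), train)
      cc <- consensus_cluster(features[, train, drop = FALSE], k_range = k,
                              iters = cc_iters, p_item = p_item,
                              seed = derive_seed(seed, "cv-cc", it),
                              linkage = linkage)
      train_labels <- cc$results[[as.character(k)]]$labels
      if (length(unique(train_labels)) < k) stopf("training fold lost a cluster")
      centroids <- vapply(seq_len(k), function(cl)
        apply(features[, train[train_labels == cl], drop = FALSE], 1,
              stats::median), numeric(nrow(features)))
      Ur <- unit_rows(t(apply(centroids, 2, rank)))
      Ut <- unit_rows(t(apply(features[, test, drop = FALSE], 2, rank)))
      sim <- tcrossprod(Ut, Ur)
      pred <- max.col(sim, ties.method = "first")
      adjusted_rand_index(pred, reference_labels[sid[test]])
    }, error = function(e) NA_real_)
    aris[it] <- res
  }
  n_failed <- sum(is.na(aris))
  if (n_failed)
    message(sprintf("%d of %d CV iterations failed and were excluded",
                    n_failed, iterations))
  ok <- aris[!is.na(aris)]
  ari_mean <- mean(ok)
  ci <- if (length(ok) > 1) {
    se <- stats::sd(ok) / sqrt(length(ok))
    ari_mean + c(-1, 1) * stats::qnorm(0.975) * se
  } else {
    message("single CV iteration: confidence interval collapses to the value")
    c(ari_mean, ari_mean)
  }
  structure(list(ari_per_iter = aris, ari_mean = ari_mean, ci95 = ci,
                 n_failed = n_failed), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cv_report: mean ARI %.3f (95%% CI %.3f-%.3f), %d failed\n",
              x$ari_mean, x$ci95[1], x$ci95[2], x$n_failed))
  invisible(x)
}
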