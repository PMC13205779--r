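test_that("MAD feature selection ranks, truncates, and centers", {
  vals <- rbind(flat = rep(3, 6),
                wide = c(0, 0, 10, 10, 40, 40),
                mid = c(1, 2, 3, 4, 5, 6))
  colnames(vals) <- paste0("s", 1:6)
  m <- expression_matrix(vals, setNames(rep("snoRNA", 3), rownames(vals)))
  f <- select_features(m, rownames(vals), log10_transform = FALSE)
  # raw MAD (constant 1): wide 10, mid 1.5, flat 0
  expect_equal(rownames(f), c("wide", "mid", "flat"))
  expect_equal(apply(f, 1, median), c(wide = 0, mid = 0, flat = 0))
  expect_warning(f2 <- select_features(m, rownames(vals), n_top = 10,
                                       log10_transform = FALSE), "keeping all")
  expect_equal(nrow(f2), 3)
  f1 <- select_features(m, rownames(vals), n_top = 1, log10_transform = FALSE)
  expect_equal(rownames(f1), "wide")
  # raw MAD is outlier-blind: (1,2,3,100) ties with (1,2,3,4)
  expect_equal(stats::mad(c(1, 2, 3, 100), constant = 1),
               stats::mad(c(1, 2, 3, 4), constant = 1))
})

test_that("ARI matches hand computation, the pair-counting oracle, and mclust", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(adjusted_rand_index(c("a", "b", "a", "b"), c("b", "a", "b", "a")), 1)
  expect_equal(adjusted_rand_index(rep(1, 6), 1:6), 0)
  # {1,1,2,2,3,3} vs {1,1,1,2,2,2}: contingency-table formula by hand
  a <- c(1, 1, 2, 2, 3, 3); b <- c(1, 1, 1, 2, 2, 2)
  expect_equal(adjusted_rand_index(a, b), (2 - 1.2) / (4.5 - 1.2))
  expect_equal(adjusted_rand_index(a, b), pair_count_ari(a, b))
  set.seed(1)
  for (i in 1:20) {
    n <- sample(c(10, 50, 200), 1)
    x <- sample(1:4, n, TRUE); y <- sample(1:3, n, TRUE)
    expect_equal(adjusted_rand_index(x, y), pair_count_ari(x, y),
                 tolerance = 1e-12)
    # symmetry and relabeling invariance
    expect_equal(adjusted_rand_index(x, y), adjusted_rand_index(y, x))
    relab <- c(3, 1, 4, 2)[x]
    expect_equal(adjusted_rand_index(relab, y), adjusted_rand_index(x, y))
    if (requireNamespace("mclust", quietly = TRUE))
      expect_equal(adjusted_rand_index(x, y),
                   mclust::adjustedRandIndex(x, y), tolerance = 1e-12)
  }
  expect_error(adjusted_rand_index(1, 1), "at least two")
  expect_error(adjusted_rand_index(1:3, 1:4), "same samples")
})

planted_features <- function(n_per = 20, n_feat = 30, shift = 4, sd = 1,
                             seed = 1) {
  set.seed(seed)
  n <- 3 * n_per
  lab <- rep(1:3, each = n_per)
  f <- matrix(rnorm(n_feat * n, sd = sd), n_feat)
  for (k in 1:3) f[((k - 1) * 10 + 1):(k * 10), lab == k] <-
    f[((k - 1) * 10 + 1):(k * 10), lab == k] + shift
  dimnames(f) <- list(paste0("g", 1:n_feat), paste0("s", 1:n))
  list(f = f, lab = setNames(lab, colnames(f)))
}

test_that("consensus clustering is deterministic and well-formed", {
  pf <- planted_features()
  cc1 <- consensus_cluster(pf$f, k_range = 2:4, iters = 50, seed = 5)
  cc2 <- consensus_cluster(pf$f, k_range = 2:4, iters = 50, seed = 5)
  expect_identical(cc1$results[["3"]]$consensus, cc2$results[["3"]]$consensus)
  for (k in 2:4) {
    cons <- cc1$results[[as.character(k)]]$consensus
    expect_true(isSymmetric(cons))
    expect_true(all(cons >= 0 & cons <= 1))
    expect_true(all(diag(cons) == 1))
    expect_length(cc1$results[[as.character(k)]]$labels, ncol(pf$f))
  }
  expect_error(consensus_cluster(pf$f[1, , drop = FALSE], 2:3, 10, seed = 1),
               "2 features")
  expect_error(consensus_cluster(pf$f[, 1:8], k_range = 2:6, iters = 10,
                                 seed = 1), "samples")
})

test_that("planted partitions are recovered and k is chosen by delta area", {
  pf <- planted_features()
  cc <- consensus_cluster(pf$f, k_range = 2:5, iters = 200, seed = 5)
  expect_equal(choose_k(cc)$k, 3)
  lab <- cc$results[["3"]]$labels
  expect_gte(adjusted_rand_index(lab, pf$lab[names(lab)]), 0.9)
  cons <- cc$results[["3"]]$consensus
  ut <- cons[upper.tri(cons)]
  expect_gte(mean(ut < 0.1 | ut > 0.9), 0.9)     # near-binary consensus
})

test_that("choose_k falls back to the smallest k without structure", {
  fake <- structure(list(
    results = list(), delta_area = data.frame(k = 2:5, area = c(1, 2, 4, 8),
                                              delta = c(1, 1, 1, 1))),
    class = "consensus_result_set")
  out <- choose_k(fake)
  expect_equal(out$k, 2)
  expect_match(out$rationale, "no structure")
  # and picks the elbow when one exists
  fake$delta_area$delta <- c(0.9, 0.5, 0.05, 0.02)
  expect_equal(choose_k(fake)$k, 3)
})

test_that("Monte-Carlo CV scores planted structure high and noise at chance", {
  pf <- planted_features()
  cc <- consensus_cluster(pf$f, k_range = 3, iters = 100, seed = 5)
  ref <- cc$results[["3"]]$labels
  cv <- monte_carlo_cv(pf$f, 3, ref, iterations = 25, seed = 7, cc_iters = 50)
  expect_gte(cv$ari_mean, 0.9)
  expect_lte(cv$ci95[1], cv$ari_mean)
  expect_equal(length(cv$ari_per_iter), 25)

  # chance level needs a reasonably sized cohort: with very few samples the
  # train and full-data clusterings share sample-specific noise
  set.seed(8)
  noise <- matrix(rnorm(45 * 120), 45,
                  dimnames = list(paste0("g", 1:45), paste0("s", 1:120)))
  ccn <- consensus_cluster(noise, k_range = 3, iters = 100, seed = 5)
  cvn <- monte_carlo_cv(noise, 3, ccn$results[["3"]]$labels, iterations = 25,
                        seed = 7, cc_iters = 50)
  expect_lt(abs(cvn$ari_mean), 0.15)
  expect_lt(cvn$ari_mean, cv$ari_mean)
})

test_that("a single CV iteration collapses the confidence interval", {
  pf <- planted_features()
  cc <- consensus_cluster(pf$f, k_range = 3, iters = 50, seed = 5)
  expect_message(cv <- monte_carlo_cv(pf$f, 3, cc$results[["3"]]$labels,
                                      iterations = 1, seed = 2,
                                      cc_iters = 30), "single CV iteration")
  expect_equal(cv$ci95, rep(cv$ari_mean, 2))
})

test_that("subtype recovery degrades as the planted effect shrinks", {
  mean_ari <- sapply(c(4, 1, 0), function(shift) {
    mean(sapply(1:4, function(s) {
      pf <- planted_features(shift = shift, seed = 100 + s)
      cc <- consensus_cluster(pf$f, k_range = 3, iters = 60, seed = s)
      adjusted_rand_index(cc$results[["3"]]$labels, pf$lab)
    }))
  })
  expect_true(mean_ari[1] > mean_ari[2])
  expect_true(mean_ari[2] > mean_ari[3] - 0.05)
  expect_lt(mean_ari[3], 0.2)
})
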