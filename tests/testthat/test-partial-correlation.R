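test_that("partial correlation reduces to Pearson r when z is orthogonal", {
  set.seed(1)
  x <- rnorm(20); y <- rnorm(20)
  z <- rnorm(20)
  z <- stats::residuals(stats::lm(z ~ x + y))   # sample-orthogonal to both
  res <- partial_correlation(x, y, z)
  expect_equal(res$r_partial, stats::cor(x, y), tolerance = 1e-12)
})

test_that("partial correlation matches the residual-regression oracle", {
  set.seed(2)
  for (i in 1:100) {
    z <- rnorm(50)
    x <- 0.5 * z + rnorm(50)
    y <- -0.8 * z + rnorm(50)
    res <- partial_correlation(x, y, z)
    expect_equal(res$r_partial, residual_oracle(x, y, z), tolerance = 1e-10)
  }
})

test_that("identical vectors have partial correlation one", {
  set.seed(3)
  x <- rnorm(30); z <- rnorm(30)
  expect_equal(partial_correlation(x, x, z)$r_partial, 1)
})

test_that("degenerate inputs raise targeted errors", {
  set.seed(4)
  x <- rnorm(20); y <- rnorm(20)
  expect_error(partial_correlation(x, y, x), "collinear")
  expect_error(partial_correlation(rep(1, 20), y, rnorm(20)), "constant")
  expect_error(partial_correlation(x[1:4], y[1:4], rnorm(4)), "at least 5")
})

test_that("nominal p follows the t transform of r", {
  set.seed(5)
  z <- rnorm(40); x <- z + rnorm(40); y <- z + rnorm(40)
  res <- partial_correlation(x, y, z)
  tstat <- res$r_partial * sqrt((40 - 3) / (1 - res$r_partial^2))
  expect_equal(res$p_nominal, 2 * pt(-abs(tstat), 37), tolerance = 1e-12)
})

test_that("an observed |r| beyond every null draw gives p = 1/(B+1)", {
  set.seed(6)
  z <- rnorm(50)
  x <- rnorm(50)
  y <- x + 0.05 * rnorm(50)              # near-perfect association
  res <- permutation_empirical_p(x, y, z, B = 1000, seed = 9)
  expect_true(all(abs(res$null_stats) < abs(partial_correlation(x, y, z)$r_partial)))
  expect_equal(res$p_empirical, 1 / 1001)
})

test_that("empirical p is bounded, reproducible, and monotone in |r|", {
  set.seed(7)
  z <- rnorm(40); x <- 0.3 * z + rnorm(40); y <- 0.3 * z + rnorm(40)
  r1 <- permutation_empirical_p(x, y, z, B = 99, seed = 4)
  r2 <- permutation_empirical_p(x, y, z, B = 99, seed = 4)
  expect_identical(r1, r2)
  expect_gte(r1$p_empirical, 1 / 100)
  expect_lte(r1$p_empirical, 1)
  # recomputing p against the same null draws for increasing |r| is monotone
  ps <- vapply(c(0.05, 0.2, 0.5, 0.9), function(r)
    (sum(abs(r1$null_stats) >= r) + 1) / 100, 0)
  expect_true(all(diff(ps) <= 0))
})

test_that("B = 1 forces p into {0.5, 1}", {
  set.seed(8)
  z <- rnorm(30); x <- rnorm(30); y <- rnorm(30)
  ps <- vapply(1:20, function(i)
    permutation_empirical_p(x, y, z, B = 1, seed = i)$p_empirical, 0)
  expect_true(all(ps %in% c(0.5, 1)))
})

test_that("the shrinkage null mode stays close to the plain estimator", {
  set.seed(9)
  z <- rnorm(60); x <- 0.5 * z + rnorm(60); y <- 0.5 * z + rnorm(60)
  a <- permutation_empirical_p(x, y, z, B = 50, seed = 2)
  b <- permutation_empirical_p(x, y, z, B = 50, seed = 2,
                               estimator = "shrinkage")
  expect_lt(abs(a$p_empirical - b$p_empirical), 0.2)
  expect_lt(max(abs(sort(a$null_stats) - sort(b$null_stats))), 0.1)
})

test_that("BH adjustment matches the hand-worked examples", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.5), 0.5)
  expect_identical(bh_fdr(numeric(0)), numeric(0))
  expect_error(bh_fdr(c(0.5, 0)), "0, 1")
  # order-preserving on a shuffled input
  p <- c(0.03, 0.01, 0.04, 0.02)
  expect_equal(bh_fdr(p), rep(0.04, 4))
  q <- bh_fdr(c(0.001, 0.5, 0.04))
  expect_true(all(q <= 1) && all(diff(q[order(c(0.001, 0.5, 0.04))]) >= 0))
})

test_that("the vectorized scan equals the scalar operation pair by pair", {
  co <- small_cohort()
  tum <- names(co$purity)[co$expr$sample_group == "tumor"]
  mn <- log_quantile_normalize(subset_samples(co$expr, tum))
  pur <- co$purity[tum]
  genes <- unique(unlist(co$sets$sets))[1:5]
  pairs <- partial_correlation_scan(mn, pur, genes)
  set.seed(10)
  for (i in sample(nrow(pairs), 20)) {
    ref <- partial_correlation(mn$values[pairs$sno[i], ],
                               mn$values[pairs$gene[i], ], pur)
    expect_equal(pairs$r_partial[i], ref$r_partial, tolerance = 1e-10)
    expect_equal(pairs$p_nominal[i], ref$p_nominal, tolerance = 1e-10)
  }
})

test_that("empirical FDR is attached to screened candidates only", {
  co <- small_cohort()
  tum <- names(co$purity)[co$expr$sample_group == "tumor"]
  mn <- log_quantile_normalize(subset_samples(co$expr, tum))
  pur <- co$purity[tum]
  genes <- unique(unlist(co$sets$sets))[1:10]
  pairs <- partial_correlation_scan(mn, pur, genes)
  out <- add_empirical_fdr(pairs, mn, pur, B = 50, seed = 3)
  cand <- out$p_nominal < 0.05
  expect_true(all(is.na(out$p_empirical[!cand])))
  expect_true(all(!is.na(out$p_empirical[cand])))
  expect_true(all(out$p_empirical[cand] >= 1 / 51))
  expect_equal(out$fdr_empirical[cand], bh_fdr(out$p_empirical[cand]))
  # pair-level seeding: same run seed reproduces bitwise
  out2 <- add_empirical_fdr(pairs, mn, pur, B = 50, seed = 3)
  expect_identical(out, out2)
})
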