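mk_frac <- function(mat) structure(list(fractions = mat),
                                   class = "CellFractionMatrix")

test_that("Spearman calls are rank-invariant and match cor.test", {
  set.seed(1)
  n <- 40
  x <- rnorm(n)
  vals <- rbind(sno1 = exp(x) * 50, sno2 = rexp(n))
  colnames(vals) <- sprintf("s%02d", 1:n)
  m <- expression_matrix(vals, c(sno1 = "snoRNA", sno2 = "snoRNA"))
  ct1 <- plogis(x) / 4; ct2 <- runif(n) / 4
  fr <- rbind(tumor = 1 - ct1 - ct2, ct1 = ct1, ct2 = ct2)
  colnames(fr) <- colnames(vals)
  out <- spearman_infiltration(m, mk_frac(fr))
  # abundance is a monotone transform of sno1 expression -> rho = 1
  expect_equal(out$rho[out$sno == "sno1" & out$celltype == "ct1"], 1)
  # p matches the t approximation used by cor.test(exact = FALSE)
  ref <- suppressWarnings(cor.test(vals["sno2", ], fr["ct2", ],
                                   method = "spearman", exact = FALSE))
  row <- out[out$sno == "sno2" & out$celltype == "ct2", ]
  expect_equal(row$rho, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(row$p, ref$p.value, tolerance = 1e-10)
  # reversing the sample order of both matrices leaves rho unchanged
  rev_ids <- rev(colnames(vals))
  out_rev <- spearman_infiltration(subset_samples(m, rev_ids),
                                   mk_frac(fr[, rev_ids]))
  expect_equal(out_rev$rho, out$rho)
})

test_that("Spearman rho equals Pearson correlation of mid-ranks under ties", {
  set.seed(2)
  n <- 30
  vals <- matrix(sample(1:8, 2 * n, TRUE), 2,
                 dimnames = list(c("a", "b"), sprintf("s%02d", 1:n)))
  m <- expression_matrix(vals, c(a = "snoRNA", b = "snoRNA"))
  fr <- rbind(tumor = rep(0.5, n), ct = sample(1:5, n, TRUE) / 10)
  fr <- sweep(fr, 2, colSums(fr), "/"); colnames(fr) <- colnames(vals)
  out <- spearman_infiltration(m, mk_frac(fr))
  for (g in c("a", "b"))
    expect_equal(out$rho[out$sno == g],
                 cor(rank(vals[g, ]), rank(fr["ct", ])), tolerance = 1e-12)
})

test_that("null call rate matches the analytic tail beyond rho = 0.3", {
  set.seed(3)
  n <- 100; n_sno <- 500
  vals <- matrix(rexp(n_sno * n), n_sno,
                 dimnames = list(sprintf("g%03d", 1:n_sno),
                                 sprintf("s%03d", 1:n)))
  m <- expression_matrix(vals, setNames(rep("snoRNA", n_sno), rownames(vals)))
  fr <- rbind(tumor = rep(0.5, n),
              ct1 = runif(n), ct2 = runif(n), ct3 = runif(n), ct4 = runif(n))
  fr <- sweep(fr, 2, colSums(fr), "/"); colnames(fr) <- colnames(vals)
  out <- spearman_infiltration(m, mk_frac(fr))          # 2000 null pairs
  # analytic tail mass of the null rho distribution beyond 0.3 (t transform);
  # p < 0.05 is implied at |rho| >= 0.3 for n = 100
  analytic <- 2 * pt(-0.3 * sqrt((n - 2) / (1 - 0.09)), n - 2)
  rate <- mean(out$related)
  expect_lt(abs(rate - analytic), 3 * sqrt(analytic / nrow(out)) + 0.002)
})

test_that("absolute-mode calls contain signed-mode calls; constants flagged", {
  set.seed(4)
  n <- 30
  vals <- matrix(rexp(5 * n), 5, dimnames = list(paste0("g", 1:5),
                                                 sprintf("s%02d", 1:n)))
  m <- expression_matrix(vals, setNames(rep("snoRNA", 5), rownames(vals)))
  fr <- rbind(tumor = rep(0.5, n), up = runif(n), down = runif(n),
              flat = rep(0.1, n))
  fr <- sweep(fr, 2, colSums(fr), "/")
  # keep 'flat' exactly constant after normalization
  fr["flat", ] <- 0.1; fr["tumor", ] <- fr["tumor", ] - (colSums(fr) - 1)
  colnames(fr) <- colnames(vals)
  ab <- spearman_infiltration(m, mk_frac(fr), mode = "absolute")
  sg <- spearman_infiltration(m, mk_frac(fr), mode = "signed")
  called_ab <- paste(ab$sno, ab$celltype)[ab$related]
  called_sg <- paste(sg$sno, sg$celltype)[sg$related]
  expect_true(all(called_sg %in% called_ab))
  expect_true(all(ab$flagged[ab$celltype == "flat"]))
  expect_true(all(!ab$related[ab$celltype == "flat"]))
})

test_that("hypergeometric overlap matches combinatorial brute force", {
  uni <- paste0("g", 1:20)
  a <- uni[1:5]
  b <- c(uni[1:3], uni[10:11])          # overlap 3
  obs <- estimator_overlap_test(a, b, uni)
  expect_equal(obs$overlap, 3)
  # enumerate all 5-subsets of the universe as candidate b sets
  combos <- utils::combn(20, 5)
  ov <- colSums(matrix(combos %in% 1:5, nrow = 5))
  expect_equal(obs$p, mean(ov >= 3), tolerance = 1e-12)

  # maximal overlap is the minimal attainable p for these sizes
  eq <- estimator_overlap_test(a, a, uni)
  expect_equal(eq$p, mean(colSums(matrix(combos %in% 1:5, nrow = 5)) >= 5),
               tolerance = 1e-12)
  expect_true(eq$p <= obs$p)
  # disjoint sets sit near p = 1
  dis <- estimator_overlap_test(uni[1:5], uni[6:10], uni)
  expect_gt(dis$p, 0.95)
  expect_error(estimator_overlap_test(a, b, character(0)), "empty")
})

test_that("infiltration enrichment recovers the planted association", {
  co <- default_cohort()
  tn <- default_tumor_norm()
  tum <- colnames(tn$m$values)
  out <- spearman_infiltration(tn$m,
                               mk_frac(co$fractions$fractions[, tum]))
  related <- unique(out$sno[out$related])
  uni <- names(co$expr$gene_class)[co$expr$gene_class == "snoRNA"]
  r <- infiltration_enrichment(co$truth$immune_sno, related, uni)
  expect_gt(r$odds_ratio, 1)
  expect_lt(r$p, 0.05)
})
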