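# Independent oracles used to validate the analytical implementations.

# Correlation of least-squares residuals of x ~ z and y ~ z: the defining
# construction of the first-order partial correlation.
residual_oracle <- function(x, y, z) {
  rx <- stats::residuals(stats::lm(x ~ z))
  ry <- stats::residuals(stats::lm(y ~ z))
  stats::cor(rx, ry)
}

# Exhaustive prefix evaluation of the weighted KS running sum.
brute_force_es <- function(ranked, gene_set) {
  hit <- names(ranked) %in% gene_set
  w <- abs(unname(ranked))
  N <- length(ranked); n_hit <- sum(hit)
  wsum <- sum(w[hit])
  best <- 0
  run <- 0
  for (i in seq_len(N)) {
    run <- run + if (hit[i]) {
      if (wsum > 0) w[i] / wsum else 1 / n_hit
    } else -1 / (N - n_hit)
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# Exhaustive two-sided Fisher p: enumerate every 2x2 table with the observed
# margins via binomial coefficients and sum the probabilities not exceeding
# the observed table's.
enumerate_fisher_p <- function(a, b, c, d) {
  n1 <- a + b; n2 <- c + d; k <- a + c
  as <- max(0, k - n2):min(k, n1)
  probs <- choose(n1, as) * choose(n2, k - as) / choose(n1 + n2, k)
  obs <- probs[as == a]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Pair-counting ARI: classify every sample pair as co-clustered or not in
# each labeling and chance-correct the agreement directly.
pair_count_ari <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  n11 <- sum(same_a & same_b)
  n10 <- sum(same_a & !same_b); n01 <- sum(!same_a & same_b)
  tot <- length(same_a)
  expected <- (n11 + n10) * (n11 + n01) / tot
  denom <- (n11 + n10 + n11 + n01) / 2 - expected
  if (denom == 0) return(if (n11 == expected) 1 else 0)
  (n11 - expected) / denom
}
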