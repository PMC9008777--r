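# Independent brute-force oracles, deliberately written as plain loops so
# they share no code path with the package implementations.

# Mean over partners of the pairwise-difference SD (first-pass stability).
oracle_pairwise_stability <- function(m) {
  k <- nrow(m)
  out <- numeric(k)
  for (j in seq_len(k)) {
    acc <- 0
    for (l in seq_len(k)) {
      if (l == j) next
      acc <- acc + sd(m[j, ] - m[l, ])
    }
    out[j] <- acc / (k - 1)
  }
  names(out) <- rownames(m)
  out
}

# Full iterative-exclusion geNorm recomputation (M at exclusion; final pair
# keep their M from the last 3-candidate round).
oracle_genorm <- function(m) {
  alive <- rownames(m)
  M_out <- numeric(0)
  last <- NULL
  while (length(alive) > 2) {
    M <- oracle_pairwise_stability(m[alive, , drop = FALSE])
    last <- M
    worst <- names(M)[M == max(M)]
    worst <- sort(worst)[length(worst)]
    M_out[worst] <- M[[worst]]
    alive <- setdiff(alive, worst)
  }
  M_out[alive] <- last[alive]
  M_out[rownames(m)]
}

# Two-pass per-row sample variance.
oracle_row_sd <- function(m) {
  out <- numeric(nrow(m))
  for (j in seq_len(nrow(m))) {
    mu <- sum(m[j, ]) / ncol(m)
    out[j] <- sqrt(sum((m[j, ] - mu)^2) / (ncol(m) - 1))
  }
  names(out) <- rownames(m)
  out
}

# Quantile normalization: mean order statistic as reference, ties within a
# sample taking the mean of the reference values their ranks span.
oracle_quantile <- function(m) {
  ref <- rowMeans(apply(m, 2, sort))
  out <- m
  for (i in seq_len(ncol(m))) {
    v <- m[, i]
    o <- order(v)
    pos <- 1
    while (pos <= length(v)) {
      span <- which(v[o] == v[o[pos]])
      out[o[span], i] <- mean(ref[span])
      pos <- max(span) + 1
    }
  }
  out
}

# Random fully detected Ct matrix (candidates x samples) with offsets.
random_ct_matrix <- function(k, n, tau = 1, sigma = NULL) {
  if (is.null(sigma)) sigma <- runif(k, 0.2, 1.5)
  m <- matrix(rnorm(k * n, 0, sigma), k, n) +
    matrix(rnorm(n, 0, tau), k, n, byrow = TRUE) +
    runif(k, 20, 30)
  dimnames(m) <- list(sprintf("g%02d", seq_len(k)),
                      sprintf("s%02d", seq_len(n)))
  m
}

ct_experiment_from <- function(m, sampleData = NULL) {
  CtExperiment(m, sampleData = sampleData)
}
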