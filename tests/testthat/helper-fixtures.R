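# Small in-code fixtures shared across test files.

# A tiny fully observed table: 3 features, 2 samples x 2 replicates.
tiny_table <- function() {
  feature_table(
    intensities = matrix(c(100, 110, 200, 190,
                           50, 55, 60, 58,
                           1000, 1000, 1000, 1000),
                         nrow = 3, byrow = TRUE),
    mz = c(100.1, 200.2, 300.3),
    rt = c(10, 20, 30),
    sample_id = c("A", "A", "B", "B"),
    replicate = c(1, 2, 1, 2),
    feature_id = c("f1", "f2", "f3"))
}

# Quick null cohort (no planted structure) for calibration checks.
null_cohort <- function(n_features = 100, n = 20, seed = 1,
                        n_replicates = 1) {
  simulate_cohort(synth_config(
    n_features = n_features,
    n_per_group = c(control = 0, slow = n, rapid = n),
    n_replicates = n_replicates, n_effect_features = 0, n_modules = 0,
    missing_rate = 0, seed = seed))
}

# Brute-force BH step-up: enumerate all cutoffs.
bh_oracle <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  i_max <- 0
  for (i in seq_len(m)) if (ps[i] <= i * q / m) i_max <- i
  sig <- logical(m)
  if (i_max > 0) sig[ord[seq_len(i_max)]] <- TRUE
  sig
}

# Brute-force TOM via explicit triple loop.
tom_oracle <- function(A) {
  n <- nrow(A)
  k <- colSums(A)
  out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    num <- A[i, j]
    for (u in seq_len(n)) num <- num + A[i, u] * A[u, j]
    out[i, j] <- num / (min(k[i], k[j]) + 1 - A[i, j])
  }
  out
}

# Adjusted Rand index (independent of the clustering code under test).
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
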