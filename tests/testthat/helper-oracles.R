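# Independent brute-force quadratic-weighted-kappa oracle: explicit loops,
# no shared code with the package implementation.
qwk_oracle <- function(truth, pred, K = 4) {
  n <- length(truth)
  O <- matrix(0, K, K)
  for (i in seq_len(n)) O[truth[i], pred[i]] <- O[truth[i], pred[i]] + 1
  W <- matrix(0, K, K)
  for (i in 1:K) for (j in 1:K) W[i, j] <- (i - j)^2 / (K - 1)^2
  E <- matrix(0, K, K)
  for (i in 1:K) for (j in 1:K) E[i, j] <- sum(O[i, ]) * sum(O[, j]) / n
  num <- 0
  den <- 0
  for (i in 1:K) for (j in 1:K) {
    num <- num + W[i, j] * O[i, j]
    den <- den + W[i, j] * E[i, j]
  }
  1 - num / den
}

# Weighted observed disagreement (the severity penalty QWK normalizes).
qwk_penalty <- function(truth, pred, K = 4) {
  sum((truth - pred)^2) / (K - 1)^2
}

# A tiny three-row cohort CSV with one missing FEV1 cell.
write_tiny_csv <- function(path, labels = c(1, 3, 2)) {
  writeLines(c(
    "age,sex,FEV1,GOLD",
    paste0("52,1,2.1,", labels[1]),
    paste0("63,0,,", labels[2]),
    paste0("71,1,0.9,", labels[3])
  ), path)
}

tiny_specs <- function() {
  feature_spec(
    name = c("age", "sex", "FEV1"),
    role = "shared",
    lo = c(40, 0, 0.4), hi = c(100, 1, 4.0),
    normalize = TRUE
  )
}

# Small, fast synthetic pair for pipeline tests.
small_pair <- function(seed = 5, ...) {
  generate_pair(sim_spec(n_source = 60, n_target = 50, seed = seed, ...))
}

fast_control <- function(seed = 1, epochs = 120) {
  train_control(max_epochs = epochs, seed = seed)
}
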