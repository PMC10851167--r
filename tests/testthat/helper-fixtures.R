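# Shared fixtures, all generated in code.

small_cohort <- function(seed = 11L, n = 120L, p = 60L, ...) {
  m <- max(2L, min(12L, p %/% 5L))
  generate_feature_cohort(synthetic_config(
    n_patients = n, n_features_per_phase = p, n_latent = m,
    n_informative = min(6L, m), seed = seed, ...))
}

# literal double-loop biased/unbiased MMD^2 oracle (independent of the
# vectorized implementation path)
mmd2_oracle <- function(X, Y, sigmas, estimator = "biased") {
  k <- function(a, b, s) exp(-sum((a - b)^2) / (2 * s^2))
  n <- nrow(X); m <- nrow(Y)
  total <- 0
  for (s in sigmas) {
    kxx <- kyy <- kxy <- 0
    for (i in seq_len(n)) for (j in seq_len(n))
      kxx <- kxx + k(X[i, ], X[j, ], s)
    for (i in seq_len(m)) for (j in seq_len(m))
      kyy <- kyy + k(Y[i, ], Y[j, ], s)
    for (i in seq_len(n)) for (j in seq_len(m))
      kxy <- kxy + k(X[i, ], Y[j, ], s)
    if (estimator == "biased") {
      total <- total + kxx / n^2 + kyy / m^2 - 2 * kxy / (n * m)
    } else {
      total <- total + (kxx - n) / (n * (n - 1)) +
        (kyy - m) / (m * (m - 1)) - 2 * kxy / (n * m)
    }
  }
  total
}

# brute-force pair-counting AUC oracle
auc_oracle <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# trapezoidal area under the empirical ROC curve
auc_trapezoid <- function(scores, y) {
  rc <- roc_curve(scores, y)
  sum(diff(rc$fpr) * (head(rc$tpr, -1) + tail(rc$tpr, -1)) / 2)
}

# brute-force Mann-Whitney U with tie halving
u_oracle <- function(x0, x1) {
  tot <- 0
  for (a in x1) for (b in x0) tot <- tot + (a > b) + 0.5 * (a == b)
  tot
}
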