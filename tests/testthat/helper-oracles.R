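# Independent brute-force oracles used across test files. These deliberately
# avoid the package's code paths: plain double loops and textbook formulas.

# Pearson r from the raw definition (no stats::cor).
pearson_brute <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Correlation-distance RDM by double loop.
rdm_brute <- function(acts) {
  n <- nrow(acts)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) d[i, j] <- 1 - pearson_brute(acts[i, ], acts[j, ])
    }
  }
  d
}

# Spearman rho as rank-then-Pearson with average ranks for ties.
spearman_brute <- function(x, y) {
  pearson_brute(rank(x, ties.method = "average"),
                rank(y, ties.method = "average"))
}

# Canonical unordered-pair keys for comparing duplicate reports to planted
# ground truth.
pair_keys <- function(a, b) paste(pmin(a, b), pmax(a, b))

# Toy subject RDM stack with named stimuli, built directly from activations.
make_subjects <- function(n_subjects, n_stimuli, noise_sd = 0.5,
                          n_features = 12, seed = 1) {
  gen_subject_rdms(n_subjects, n_stimuli, n_features = n_features,
                   noise_sd = noise_sd, seed = seed)
}
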