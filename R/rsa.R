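#' Spearman similarity between two RDMs
#'
#' Spearman's rank correlation (average ranks for ties) between the upper
#' triangles of a model RDM and a reference (subject) RDM. No model fitting
#' or reweighting is applied: the model is scored on its raw representational
#' geometry.
#'
#' @param model,subject `rdm` objects over the same stimuli.
#' @return Spearman rho (scalar).
#' @export
rdm_similarity <- function(model, subject) {
  if (!identical(stimulus_ids(model), stimulus_ids(subject))) {
    abort("Model and subject RDMs must share stimulus ids and order.")
  }
  a <- upper_triangle(model)
  b <- upper_triangle(subject)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    abort("Spearman correlation undefined: constant upper triangle.")
  }
  stats::cor(a, b, method = "spearman")
}

#' Average model-to-subject RDM similarity
#'
#' The summary statistic for one network instance and layer: the mean over
#' subjects of the Spearman similarity between the model RDM and each
#' subject's RDM.
#'
#' @param model An `rdm`.
#' @param subjects List of subject `rdm`s.
#' @return Scalar mean Spearman rho.
#' @export
model_score <- function(model, subjects) {
  if (length(subjects) < 1) abort("Need at least one subject RDM.")
  mean(vapply(subjects, function(s) rdm_similarity(model, s), numeric(1)))
}

#' Lower bound of the noise ceiling
#'
#' Each subject's RDM is compared (Spearman) to the average RDM of the
#' remaining subjects; the mean of these leave-one-out correlations is the
#' lower bound of the noise ceiling — the agreement a true model of the
#' group-average representation could be expected to reach given
#' between-subject variability.
#'
#' @param subjects List of at least two subject `rdm`s (same stimuli).
#' @return Scalar lower-bound estimate.
#' @export
noise_ceiling_lower <- function(subjects) {
  n <- length(subjects)
  if (n < 2) abort("Noise ceiling needs at least 2 subjects.")
  mean(vapply(seq_len(n), function(i) {
    rdm_similarity(subjects[[i]], average_rdm(subjects[-i]))
  }, numeric(1)))
}

#' Permutation test comparing scores of two groups of network instances
#'
#' Tests whether network instances trained on dataset A score differently
#' from instances trained on dataset B. The statistic is `mean(a) - mean(b)`;
#' the null distribution re-splits the pooled scores into groups of the
#' original sizes (training-set labels are exchangeable under the null).
#' When the number of distinct splits `choose(na + nb, na)` does not exceed
#' `exhaustive_limit` every split is enumerated and the two-sided p-value is
#' the exact proportion of splits at least as extreme as the observation;
#' otherwise `n_perm` Monte-Carlo splits are drawn and the p-value carries
#' the add-one correction `(1 + k) / (n_perm + 1)` so it can never be zero.
#'
#' @param scores_a,scores_b Numeric vectors of per-instance scores (each
#'   typically a [model_score()] over subjects), at least 2 per group.
#' @param n_perm Monte-Carlo iterations (default 10000).
#' @param seed Optional integer seed for the Monte-Carlo branch.
#' @param exhaustive_limit Enumerate exhaustively when the number of distinct
#'   splits is at most this (default 10000; two groups of five give 252
#'   splits and are always enumerated).
#' @param alternative `"two.sided"` (default) or `"greater"`
#'   (mean(a) > mean(b)).
#' @return Object of class `perm_test` with elements `statistic`, `p_value`,
#'   `method` ("exhaustive" or "monte_carlo"), `n_splits`, `n_a`, `n_b`,
#'   `alternative`. Has [generics::tidy()] and [generics::glance()] methods.
#' @export
permutation_test <- function(scores_a, scores_b, n_perm = 10000L,
                             seed = NULL, exhaustive_limit = 10000L,
                             alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  scores_a <- as.numeric(scores_a)
  scores_b <- as.numeric(scores_b)
  na <- length(scores_a)
  nb <- length(scores_b)
  if (na < 2 || nb < 2) abort("Need at least 2 instances per group.")
  pool <- c(scores_a, scores_b)
  observed <- mean(scores_a) - mean(scores_b)

  if (max(pool) == min(pool)) {
    return(new_perm_test(0, 1, "degenerate", 0L, na, nb, alternative))
  }

  n_splits <- choose(na + nb, na)
  eps <- 1e-12
  extreme <- function(stat_perm) {
    if (alternative == "two.sided") {
      abs(stat_perm) >= abs(observed) - eps
    } else {
      stat_perm >= observed - eps
    }
  }

  if (n_splits <= exhaustive_limit) {
    idx <- utils::combn(na + nb, na)
    stats_perm <- apply(idx, 2, function(i) mean(pool[i]) - mean(pool[-i]))
    p <- mean(extreme(stats_perm))
    method <- "exhaustive"
    n_used <- ncol(idx)
  } else {
    stats_perm <- with_seed_(seed, {
      vapply(seq_len(n_perm), function(k) {
        i <- sample.int(na + nb, na)
        mean(pool[i]) - mean(pool[-i])
      }, numeric(1))
    })
    p <- (1 + sum(extreme(stats_perm))) / (n_perm + 1)
    method <- "monte_carlo"
    n_used <- n_perm
  }
  new_perm_test(observed, p, method, n_used, na, nb, alternative)
}

new_perm_test <- function(statistic, p_value, method, n_splits, n_a, n_b,
                          alternative) {
  structure(
    list(statistic = statistic, p_value = p_value, method = method,
         n_splits = n_splits, n_a = n_a, n_b = n_b,
         alternative = alternative),
    class = "perm_test"
  )
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf(
    "Permutation test (%s, %s): statistic = %.4g, p = %.4g [%d splits]\n",
    x$method, x$alternative, x$statistic, x$p_value, x$n_splits))
  invisible(x)
}

#' Bonferroni adjustment over a family of tests
#'
#' `min(1, p * m)` element-wise, with `m` the family size (e.g. the number
#' of network layers tested).
#'
#' @param p_values Numeric vector of raw p-values.
#' @param m Family size; must be at least `length(p_values)`.
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  stopifnot_scalar_number(m, "m", lower = 1)
  if (m < length(p_values)) {
    abort("`m` must be at least the number of tests.")
  }
  pmin(1, p_values * m)
}

#' Percentile bootstrap confidence interval for a mean score
#'
#' Resamples network instances with replacement and reports the percentile
#' interval of the resampled means.
#'
#' @param scores Numeric vector of per-instance scores (length >= 2).
#' @param n_boot Bootstrap samples (default 1000).
#' @param level Coverage level (default 0.95).
#' @param seed Optional integer seed.
#' @return Tibble with columns `mean`, `lower`, `upper`, `level`, `n_boot`.
#' @export
bootstrap_ci <- function(scores, n_boot = 1000L, level = 0.95, seed = NULL) {
  scores <- as.numeric(scores)
  n <- length(scores)
  if (n < 2) abort("Need at least 2 instances to bootstrap.")
  stopifnot_scalar_number(level, "level", lower = 0, upper = 1)
  means <- with_seed_(seed, {
    rowMeans(matrix(sample(scores, n * n_boot, replace = TRUE),
                    nrow = n_boot))
  })
  qs <- stats::quantile(means, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  tibble(mean = mean(scores), lower = qs[1], upper = qs[2],
         level = level, n_boot = as.integer(n_boot))
}

#' Stimulus-wise model-to-subject similarity
#'
#' Decomposes the whole-RDM comparison into one score per stimulus: for
#' stimulus i, the Spearman correlation between the model's and each
#' subject's i-th RDM column with the diagonal entry removed, averaged over
#' subjects. A constant column has no defined rank correlation; its score is
#' recorded as `NA` with a warning.
#'
#' @inheritParams model_score
#' @return Tibble with columns `stimulus` and `score`.
#' @export
stimuluswise_scores <- function(model, subjects) {
  if (length(subjects) < 1) abort("Need at least one subject RDM.")
  ids <- stimulus_ids(model)
  for (s in subjects) {
    if (!identical(stimulus_ids(s), ids)) {
      abort("Model and subject RDMs must share stimulus ids and order.")
    }
  }
  n <- length(ids)
  scores <- vapply(seq_len(n), function(i) {
    m_col <- as.matrix(model)[-i, i]
    per_subject <- vapply(subjects, function(s) {
      s_col <- as.matrix(s)[-i, i]
      if (stats::sd(m_col) == 0 || stats::sd(s_col) == 0) {
        return(NA_real_)
      }
      stats::cor(m_col, s_col, method = "spearman")
    }, numeric(1))
    mean(per_subject)
  }, numeric(1))
  if (anyNA(scores)) {
    warn(sprintf("Constant RDM column for %d stimulus(es); score set to NA.",
                 sum(is.na(scores))))
  }
  tibble(stimulus = ids, score = scores)
}

#' Animate-vs-inanimate interaction permutation test
#'
#' Tests whether the benefit of one training set over another (per-stimulus
#' score difference) is larger for animate than for inanimate stimuli. The
#' statistic is `mean(benefit | animate) - mean(benefit | inanimate)`; the
#' null permutes the animacy labels across stimuli. The hypothesis is
#' directional (animate > inanimate), so the p-value is one-sided, with the
#' add-one Monte-Carlo correction.
#'
#' @param scores_a,scores_b Stimulus-wise score tables as returned by
#'   [stimuluswise_scores()] for the two models being contrasted (benefit =
#'   `scores_a$score - scores_b$score`), aligned on `stimulus`.
#' @param animate Logical vector: `TRUE` for animate stimuli, in the order
#'   of `scores_a$stimulus`.
#' @param n_perm Number of label permutations (default 10000).
#' @param seed Optional integer seed.
#' @return A `perm_test` object (one-sided).
#' @export
animacy_interaction_test <- function(scores_a, scores_b, animate,
                                     n_perm = 10000L, seed = NULL) {
  if (!identical(scores_a$stimulus, scores_b$stimulus)) {
    abort("`scores_a` and `scores_b` must cover the same stimuli in order.")
  }
  animate <- as.logical(animate)
  benefit <- scores_a$score - scores_b$score
  if (length(animate) != length(benefit) || anyNA(animate)) {
    abort("`animate` must be a complete logical label per stimulus.")
  }
  keep <- !is.na(benefit)
  benefit <- benefit[keep]
  animate <- animate[keep]
  n_anim <- sum(animate)
  n_inan <- sum(!animate)
  if (n_anim == 0 || n_inan == 0) {
    abort("Both animate and inanimate groups must be non-empty.")
  }
  n <- length(benefit)
  total <- sum(benefit)
  stat_from_animsum <- function(s) s / n_anim - (total - s) / n_inan
  observed <- stat_from_animsum(sum(benefit[animate]))
  eps <- 1e-12
  perm_stats <- with_seed_(seed, {
    vapply(seq_len(n_perm), function(k) {
      stat_from_animsum(sum(benefit[sample.int(n, n_anim)]))
    }, numeric(1))
  })
  p <- (1 + sum(perm_stats >= observed - eps)) / (n_perm + 1)
  new_perm_test(observed, p, "monte_carlo", as.integer(n_perm),
                n_anim, n_inan, "greater")
}

#' Percentage-bend robust correlation
#'
#' A robust alternative to Pearson's r that down-weights the most extreme
#' `bend` fraction of observations in each margin before correlating, with a
#' Student-t approximation for the p-value (df = n - 2). With no outliers it
#' closely tracks Pearson's r; gross outliers cannot dominate it.
#'
#' @param x,y Numeric vectors of equal length >= 4.
#' @param bend Bend constant: fraction of observations allowed to be bent
#'   (default 0.2).
#' @return Tibble with columns `rho`, `p_value`, `n`, `bend`.
#' @export
robust_correlation <- function(x, y, bend = 0.2) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n || n < 4) {
    abort("`x` and `y` must have equal length >= 4.")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("Robust correlation undefined for constant input.")
  }
  omega <- function(v) {
    w <- sort(abs(v - stats::median(v)))
    om <- w[floor((1 - bend) * n)]
    if (om <= 0) abort("Too many tied values for the chosen bend constant.")
    om
  }
  pb_location <- function(v, om) {
    psi <- (v - stats::median(v)) / om
    lo <- sum(psi < -1)
    hi <- sum(psi > 1)
    sv <- ifelse(abs(psi) > 1, 0, v)
    (sum(sv) + (hi - lo) * om) / (n - lo - hi)
  }
  om_x <- omega(x)
  om_y <- omega(y)
  a <- pmax(-1, pmin(1, (x - pb_location(x, om_x)) / om_x))
  b <- pmax(-1, pmin(1, (y - pb_location(y, om_y)) / om_y))
  rho <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  tibble(rho = rho, p_value = p, n = n, bend = bend)
}
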