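test_that("RDM similarity is Spearman on upper triangles", {
  g <- make_subjects(2, 5, seed = 1)
  a <- g$subjects[[1]]
  b <- g$subjects[[2]]
  expect_equal(rdm_similarity(a, a), 1)
  expect_equal(rdm_similarity(a, b),
               spearman_brute(upper_triangle(a), upper_triangle(b)),
               tolerance = 1e-12)

  # exactly reversed rank order -> -1
  n <- 5
  v <- seq(0.1, 1, length.out = n * (n - 1) / 2)
  fill <- function(vec) {
    m <- matrix(0, n, n)
    k <- 1
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      m[i, j] <- vec[k]; k <- k + 1
    }
    as_rdm(m + t(m))
  }
  r1 <- fill(v)
  r2 <- fill(rev(v))
  expect_equal(rdm_similarity(r1, r2), -1)

  flat <- fill(rep(0.5, length(v)))
  expect_error(rdm_similarity(flat, r1), "constant")
})

test_that("model score averages per-subject similarities", {
  g <- make_subjects(3, 8, seed = 2)
  m <- g$truth
  subj <- g$subjects
  expect_equal(model_score(m, subj[1]), rdm_similarity(m, subj[[1]]))
  expect_equal(model_score(m, list(m, m)), 1)
  expect_equal(model_score(m, subj),
               (rdm_similarity(m, subj[[1]]) + rdm_similarity(m, subj[[2]]) +
                  rdm_similarity(m, subj[[3]])) / 3,
               tolerance = 1e-12)
})

test_that("noise ceiling lower bound behaves at its degenerate points", {
  g <- make_subjects(4, 10, noise_sd = 0, seed = 3)
  expect_equal(noise_ceiling_lower(g$subjects), 1)

  # exactly 2 subjects: leave-one-out average is the other subject
  g2 <- make_subjects(2, 10, noise_sd = 0.8, seed = 4)
  expect_equal(noise_ceiling_lower(g2$subjects),
               rdm_similarity(g2$subjects[[1]], g2$subjects[[2]]),
               tolerance = 1e-12)
  expect_error(noise_ceiling_lower(g2$subjects[1]), "at least 2")
})

test_that("noise ceiling is scale-invariant and internally consistent", {
  g <- make_subjects(5, 12, noise_sd = 0.6, seed = 5)
  nc <- noise_ceiling_lower(g$subjects)
  # Spearman comparisons are rank-invariant, so a common positive scaling
  # of all dissimilarities (which commutes with the leave-one-out average)
  # leaves the ceiling unchanged; nonlinear monotone maps need not, since
  # averaging happens in dissimilarity space
  scaled <- lapply(g$subjects, function(r) {
    as_rdm(0.8 * unclass(r), stimulus_ids(r))
  })
  expect_equal(noise_ceiling_lower(scaled), nc, tolerance = 1e-12)
  # the pairwise similarity itself is invariant under a common nonlinear
  # monotone transform of both RDMs (true Spearman invariance)
  mono <- function(r) as_rdm(2 * (unclass(r) / 2)^1.7, stimulus_ids(r))
  expect_equal(rdm_similarity(mono(g$subjects[[1]]), mono(g$subjects[[2]])),
               rdm_similarity(g$subjects[[1]], g$subjects[[2]]),
               tolerance = 1e-12)

  # scoring each subject's leave-one-out average reproduces the ceiling
  loo <- vapply(seq_along(g$subjects), function(i) {
    model_score(g$subjects[[i]], list(average_rdm(g$subjects[-i])))
  }, numeric(1))
  expect_equal(mean(loo), nc, tolerance = 1e-12)
})

test_that("permutation test: exhaustive branch matches hand enumeration", {
  # identical multisets -> statistic 0, p = 1
  pt0 <- permutation_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(pt0$statistic, 0)
  expect_equal(pt0$p_value, 1)

  # complete separation, 5 vs 5 -> two-sided p = 2 / 252
  pt <- permutation_test(6:10, 1:5)
  expect_identical(pt$method, "exhaustive")
  expect_identical(pt$n_splits, 252L)
  expect_equal(pt$p_value, 2 / 252, tolerance = 1e-12)

  # all scores identical -> degenerate p = 1
  expect_equal(permutation_test(rep(1, 3), rep(1, 4))$p_value, 1)
})

test_that("permutation test is symmetric and branch-consistent", {
  s <- gen_instance_scores(5, 0.3, 0.1, 0.2, seed = 6)
  ex <- permutation_test(s$a, s$b)
  sw <- permutation_test(s$b, s$a)
  expect_equal(sw$statistic, -ex$statistic)
  expect_equal(sw$p_value, ex$p_value)

  mc <- permutation_test(s$a, s$b, n_perm = 4000, seed = 11,
                         exhaustive_limit = 1)
  expect_identical(mc$method, "monte_carlo")
  se <- sqrt(ex$p_value * (1 - ex$p_value) / 4000)
  expect_lt(abs(mc$p_value - ex$p_value), 3 * se + 1 / 4001)
  # Monte-Carlo branch is reproducible under seed
  mc2 <- permutation_test(s$a, s$b, n_perm = 4000, seed = 11,
                          exhaustive_limit = 1)
  expect_identical(mc2$p_value, mc$p_value)
})

test_that("Bonferroni adjustment multiplies and clamps", {
  expect_equal(bonferroni(0.01, m = 10), 0.1)
  expect_equal(bonferroni(0.5, m = 10), 1)
  p <- c(0.001, 0.02, 0.4)
  expect_equal(bonferroni(p, m = 10), pmin(1, p * 10))
  expect_error(bonferroni(p, m = 2), "at least the number")
})

test_that("bootstrap CI is a seeded percentile interval", {
  expect_equal(unlist(bootstrap_ci(rep(0.7, 5), seed = 1)[c("lower", "upper")]),
               c(lower = 0.7, upper = 0.7))
  x <- rnorm(10)
  c1 <- bootstrap_ci(x, seed = 5)
  c2 <- bootstrap_ci(x, seed = 5)
  expect_identical(c1, c2)
  expect_lte(c1$lower, mean(x))
  expect_gte(c1$upper, mean(x))
  # wider noise -> wider interval (sanity of the resampling)
  cw <- bootstrap_ci(x * 10, seed = 5)
  expect_gt(cw$upper - cw$lower, c1$upper - c1$lower)
})

test_that("stimulus-wise scores decompose the RDM column by column", {
  g <- make_subjects(2, 9, noise_sd = 0.5, seed = 7)
  m <- g$truth
  # model identical to the single subject -> every stimulus scores 1
  self <- stimuluswise_scores(m, list(m))
  expect_true(all(self$score == 1))

  sw <- stimuluswise_scores(m, g$subjects)
  # brute force per column, excluding the diagonal, averaged over subjects
  for (i in c(1, 4, 9)) {
    per_subj <- vapply(g$subjects, function(s) {
      spearman_brute(as.matrix(m)[-i, i], as.matrix(s)[-i, i])
    }, numeric(1))
    expect_equal(sw$score[i], mean(per_subj), tolerance = 1e-10)
  }

  # permuting stimulus order permutes the scores identically
  perm <- sample(9)
  mp <- as_rdm(as.matrix(m)[perm, perm])
  subp <- lapply(g$subjects, function(s) as_rdm(as.matrix(s)[perm, perm]))
  swp <- stimuluswise_scores(mp, subp)
  expect_equal(swp$score, sw$score[perm], tolerance = 1e-12)
})

test_that("animacy interaction test detects planted effects directionally", {
  ids <- sprintf("s%03d", 1:60)
  anim <- rep(c(TRUE, FALSE), each = 30)

  # constant benefits -> statistic 0, p ~ 1
  sa <- tibble::tibble(stimulus = ids, score = 0.3)
  sb <- tibble::tibble(stimulus = ids, score = 0.1)
  t0 <- animacy_interaction_test(sa, sb, anim, n_perm = 500, seed = 1)
  expect_equal(t0$statistic, 0)
  expect_gt(t0$p_value, 0.99)

  # planted animate advantage is detected
  set.seed(8)
  sa2 <- tibble::tibble(stimulus = ids,
                        score = rnorm(60, sd = 0.05) + anim * 0.3)
  t1 <- animacy_interaction_test(sa2, sb, anim, n_perm = 999, seed = 2)
  expect_lt(t1$p_value, 0.01)
  expect_equal(t1$statistic, mean(sa2$score[anim] - 0.1) -
                 mean(sa2$score[!anim] - 0.1), tolerance = 1e-12)

  expect_error(
    animacy_interaction_test(sa, sb, rep(TRUE, 60), n_perm = 10),
    "non-empty")
})

test_that("percentage-bend correlation is robust to a gross outlier", {
  x <- 1:10
  expect_equal(robust_correlation(x, x)$rho, 1)
  expect_equal(robust_correlation(x, -x)$rho, -1)
  expect_error(robust_correlation(x, rep(1, 10)), "constant")

  wins <- 0L
  for (s in 1:200) {
    set.seed(s)
    xs <- rnorm(20)
    ys <- 0.9 * xs + sqrt(1 - 0.81) * rnorm(20)
    xs <- c(xs, 8)
    ys <- c(ys, -8)
    rob <- robust_correlation(xs, ys)$rho
    plain <- cor(xs, ys)
    wins <- wins + (abs(rob - 0.9) < abs(plain - 0.9))
  }
  expect_gte(wins / 200, 0.9)
})

test_that("permutation results tidy and glance into one-row tables", {
  pt <- permutation_test(6:10, 1:5)
  td <- tidy(pt)
  expect_identical(nrow(td), 1L)
  expect_identical(td$method, "exhaustive")
  expect_identical(glance(pt), td)
})
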