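test_that("held-out stability follows (n+1)/(m+K) with its anchors", {
  # a held-out set containing only the explanandum: 1/(1+K) for any K
  expect_equal(heldout_stability(0, 1, K = 2), 1 / 3)
  expect_equal(heldout_stability(0, 1, K = 4), 1 / 5)
  expect_equal(heldout_stability(99, 100, K = 2), 100 / 102)
  # approaches precision as the held-out set grows
  p <- 0.8
  m <- 1e5
  expect_equal(heldout_stability(round(p * (m - 1)), m, K = 3), p,
               tolerance = 1e-3)
  expect_lt(heldout_stability(round(p * (m - 1)), m, K = 3), 1)
  expect_error(heldout_stability(0, 0, K = 2), "m must be")
  expect_error(heldout_stability(5, 5, K = 2), "n <= m - 1")
})

test_that("leave-one-out evaluation scores rules without leaking the explanandum", {
  fx <- fix_planted_small()
  d_test <- planted_rule_dataset(default_planted_spec(n_rows = 200L),
                                 seed = 99)
  rec <- loo_evaluate(fx$model, fx$data$X, fx$data$y, d_test$X,
                      max_units = 12L)
  expect_equal(nrow(rec), 12L)
  expect_true(all(rec$precision >= 0 & rec$precision <= 1))
  expect_true(all(rec$heldout_stability >= 1 / 3 & rec$heldout_stability < 1))
  K <- 2L
  expect_equal(rec$heldout_stability,
               (rec$n_correct_covered + 1) / (rec$m_covered + K))

  # recount record 1 by hand from a fresh explanation
  test_pred <- predict(fx$model, d_test$X, type = "class")
  e1 <- whips_explain(fx$model, d_test$X[1, ], fx$data$X, fx$data$y)
  rest <- 2:nrow(d_test$X)
  cov <- covers(e1$rule$terms, d_test$X)
  m_excl <- sum(cov[rest])
  n_excl <- sum(cov[rest] & test_pred[rest] == e1$decision)
  expect_equal(rec$coverage[1L], m_excl / length(rest))
  expect_equal(rec$precision[1L], if (m_excl == 0) 0 else n_excl / m_excl)
  expect_equal(rec$m_covered[1L], m_excl + 1L) # explanandum always covered

  s <- summarize_evaluation(rec)
  expect_equal(s$overfit_proportion, mean(rec$precision == 0))
  expect_equal(sum(s$rule_length_histogram), nrow(rec))
  expect_error(loo_evaluate(fx$model, fx$data$X, fx$data$y,
                            fx$data$X[0, , drop = FALSE]), "empty test set")
})

test_that("Cohen's kappa matches hand-worked confusion matrices", {
  expect_equal(cohens_kappa(matrix(c(40, 20, 10, 30), 2)), 0.4)
  expect_equal(cohens_kappa(diag(c(12, 7, 31))), 1)
  # predictions independent of truth: chance agreement, kappa 0
  indep <- outer(c(60, 40), c(0.6, 0.4))
  expect_equal(cohens_kappa(indep), 0)
  expect_error(cohens_kappa(matrix(c(10, 0, 0, 0), 2)), "undefined kappa")
  expect_error(cohens_kappa(matrix(1:6, 2)), "not square")
})

test_that("kappa is invariant under simultaneous class reordering", {
  set.seed(8)
  for (r in seq_len(20)) {
    K <- sample(2:4, 1L)
    cm <- matrix(rpois(K * K, 10) + 1, K)
    k0 <- cohens_kappa(cm)
    perm <- sample(K)
    expect_equal(cohens_kappa(cm[perm, perm]), k0, tolerance = 1e-12)
    expect_true(k0 >= -1 && k0 <= 1)
  }
})

test_that("modified Friedman F matches hand-worked and oracle values", {
  # all algorithms tied on every instance: no evidence of difference
  tied <- matrix(2, nrow = 5, ncol = 3)
  res <- friedman_modified_f(tied)
  expect_equal(res$chi2_F, 0)
  expect_equal(res$F_F, 0)
  expect_equal(res$df1, 2)
  expect_equal(res$df2, 8)

  # perfectly consistent ordering saturates chi2 and degenerates F
  strict <- matrix(rep(1:3, each = 4), nrow = 4)
  expect_error(friedman_modified_f(strict), "degenerate ranks")
  expect_error(friedman_modified_f(matrix(1, 1, 3)), "N >= 2")
})

test_that("Friedman statistic agrees with the rank-sum form on random data", {
  # independent oracle: chi2 = 12/(Nk(k+1)) * sum(Rsum^2) - 3N(k+1)
  set.seed(55)
  for (r in seq_len(200)) {
    N <- sample(3:12, 1L)
    k <- sample(2:5, 1L)
    ranks <- rank_scores(matrix(runif(N * k), N, k))
    Rsum <- colSums(ranks)
    chi2_oracle <- 12 / (N * k * (k + 1)) * sum(Rsum^2) - 3 * N * (k + 1)
    res <- tryCatch(friedman_modified_f(ranks), error = function(e) NULL)
    if (is.null(res)) next # degenerate-ranks branch
    expect_equal(res$chi2_F, chi2_oracle, tolerance = 1e-10)
    expect_equal(res$F_F,
                 (N - 1) * chi2_oracle / (N * (k - 1) - chi2_oracle),
                 tolerance = 1e-10)
  }
})

test_that("rank_scores assigns rank 1 to the best score with average ties", {
  r <- rank_scores(matrix(c(0.9, 0.1, 0.5, 0.5, 0.2, 0.8), 3, 2,
                          byrow = TRUE))
  expect_equal(r[1, ], c(1, 2))
  expect_equal(r[2, ], c(1.5, 1.5))
  expect_equal(r[3, ], c(2, 1))
})

test_that("post-hoc z follows its closed form and Bonferroni constant", {
  expect_equal(posthoc_z(2.1, 2.1, k = 3, N = 50)$z, 0)
  res <- posthoc_z(2.0, 1.5, k = 3, N = 100)
  expect_equal(res$z, 0.5 / sqrt(12 / 600), tolerance = 1e-10)
  expect_equal(res$z, 3.5355339, tolerance = 1e-6)
  expect_equal(res$bonferroni_critical, 0.025 / 3)
  expect_equal(res$bonferroni_critical, 0.00833, tolerance = 1e-3)
})

test_that("Wilcoxon signed-rank matches exact enumeration on a fixed sample", {
  a <- c(12.10, 14.20, 10.95, 17.30, 9.85, 15.50, 13.00, 11.65)
  b <- c(11.00, 15.00, 9.10, 15.20, 10.40, 12.90, 12.25, 11.00)
  d <- a - b # distinct magnitudes, no zeros
  stopifnot(!anyDuplicated(abs(d)), all(d != 0))
  rk <- rank(abs(d))
  V <- sum(rk[d > 0])
  # enumerate all 2^8 sign assignments for the exact two-sided p
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Vs <- signs %*% rk
  p_exact <- min(1, 2 * min(mean(Vs <= V), mean(Vs >= V)))
  res <- wilcoxon_signed_rank(a, b)
  expect_equal(res$statistic, V)
  expect_equal(res$p_value, p_exact, tolerance = 1e-12)
})

test_that("Wilcoxon conventions: identical samples and symmetry", {
  a <- c(1, 2, 3, 4)
  expect_equal(wilcoxon_signed_rank(a, a)$p_value, 1)
  x <- c(3.2, 1.1, 4.8, 2.2, 5.5, 0.4)
  y <- c(2.1, 1.9, 4.1, 3.3, 4.9, 1.2)
  expect_equal(wilcoxon_signed_rank(x, y)$p_value,
               wilcoxon_signed_rank(y, x)$p_value)
  expect_error(wilcoxon_signed_rank(1:3, 1:4), "length")
})
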