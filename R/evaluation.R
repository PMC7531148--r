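# ---------------------------------------------------------------------------
# Evaluation protocol: leave-one-out per-instance scoring of explanations on
# held-out data, plus the significance-testing battery (Cohen's kappa,
# modified Friedman F with Bonferroni post-hoc z, Wilcoxon signed rank).
# ---------------------------------------------------------------------------

#' Held-out stability of an explanation
#'
#' Stability measured on a held-out set that includes the explanandum
#' itself: `(n + 1) / (m + K)`, where `m` counts covered held-out instances
#' including the explanandum, `n` counts covered-and-correct instances
#' excluding it, and `K` is the number of classes. For a held-out set
#' containing only the explanandum this gives `1 / (1 + K)` — both the
#' minimum and the maximum — removing the 0/1 precision discontinuity that
#' rewards over-fitting rules; as the held-out set grows the value
#' approaches held-out precision.
#'
#' @param n covered-and-correct count, explanandum excluded (`0 <= n <=
#'   m - 1`).
#' @param m covered count, explanandum included (`m >= 1`).
#' @param K number of classes.
#' @return scalar in `[1/(1+K), 1)`.
#' @export
heldout_stability <- function(n, m, K) {
  if (m < 1) stop("m must be >= 1 (the explanandum is always covered)")
  if (n < 0 || n > m - 1) stop("need 0 <= n <= m - 1")
  (n + 1) / (m + K)
}

#' Leave-one-out evaluation of explanations on a held-out test set
#'
#' For each test instance (up to `max_units`), generates an explanation
#' from the training data, then scores its rule on the remaining test
#' instances: coverage and precision on the test set minus the explanandum
#' (so no information leaks from the explanation-generating instance into
#' its own scores) and held-out stability on the test set with the
#' explanandum included. An explanation whose rule covers nothing beyond
#' its own explanandum has held-out precision 0.0 and is flagged as
#' over-fitting.
#'
#' @param model a trained `whips_model`.
#' @param X_train,y_train the data the explainer conditions on.
#' @param X_test held-out feature matrix (disjoint from training rows).
#' @param max_units cap on the number of test units explained (default
#'   1000).
#' @param ... further arguments passed to [whips_explain()].
#' @return data.frame with one row per explained unit: `instance_id`,
#'   `coverage`, `precision`, `heldout_stability`, `n_correct_covered`,
#'   `m_covered`, `rule_length`, `overfit`, `elapsed_seconds`.
#' @export
loo_evaluate <- function(model, X_train, y_train, X_test,
                         max_units = 1000L, ...) {
  X_test <- as.matrix(X_test)
  if (nrow(X_test) == 0L) stop("empty test set")
  units <- seq_len(min(max_units, nrow(X_test)))
  K <- length(model$class_labels)
  train_pred <- predict(model, X_train, type = "class")
  test_pred <- predict(model, X_test, type = "class")

  records <- lapply(units, function(i) {
    t0 <- proc.time()[["elapsed"]]
    expl <- whips_explain(model, X_test[i, ], X_train, y_train,
                          train_pred = train_pred, ...)
    rest <- setdiff(seq_len(nrow(X_test)), i)
    covered <- covers(expl$rule$terms, X_test)
    m_excl <- sum(covered[rest])
    n_excl <- sum(covered[rest] & test_pred[rest] == expl$decision)
    prec <- if (m_excl == 0) 0 else n_excl / m_excl
    data.frame(
      instance_id = i,
      coverage = m_excl / length(rest),
      precision = prec,
      heldout_stability = heldout_stability(n_excl, m_excl + 1L, K),
      n_correct_covered = n_excl,
      m_covered = m_excl + 1L,
      rule_length = nrow(expl$rule$terms),
      overfit = prec == 0,
      elapsed_seconds = proc.time()[["elapsed"]] - t0
    )
  })
  do.call(rbind, records)
}

#' Summarise a leave-one-out evaluation
#'
#' @param records output of [loo_evaluate()].
#' @return list with `mean_coverage`, `mean_precision`, `mean_stability`,
#'   `overfit_proportion` and `rule_length_histogram`.
#' @export
summarize_evaluation <- function(records) {
  h <- table(records$rule_length)
  list(
    mean_coverage = mean(records$coverage),
    mean_precision = mean(records$precision),
    mean_stability = mean(records$heldout_stability),
    overfit_proportion = mean(records$overfit),
    rule_length_histogram = stats::setNames(as.integer(h), names(h))
  )
}

#' Cohen's kappa from a confusion matrix
#'
#' Chance-corrected agreement between true and predicted classes:
#' `kappa = (N * sum_i N_ii - sum_i N_i+ N_+i) / (N^2 - sum_i N_i+ N_+i)`.
#'
#' @param confusion K x K matrix of counts, rows = true class, columns =
#'   predicted class.
#' @return scalar in `[-1, 1]`.
#' @export
cohens_kappa <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion)) stop("confusion matrix not square")
  N <- sum(confusion)
  if (N <= 0) stop("empty confusion matrix")
  chance <- sum(rowSums(confusion) * colSums(confusion))
  denom <- N^2 - chance
  if (denom == 0) stop("undefined kappa: all mass in one row and column")
  (N * sum(diag(confusion)) - chance) / denom
}

#' Modified Friedman test on a rank matrix
#'
#' The conservative chi-squared Friedman statistic and its F-distributed
#' modification for large N:
#' `chi2_F = 12N / (k(k+1)) * (sum_j R_j^2 - k(k+1)^2 / 4)` and
#' `F_F = (N-1) chi2_F / (N(k-1) - chi2_F)`, with `df1 = k - 1` and
#' `df2 = (k-1)(N-1)`.
#'
#' @param rank_matrix N x k matrix: per-instance ranks of k algorithms
#'   (ties as average ranks); see [rank_scores()].
#' @return list with `chi2_F`, `F_F`, `df1`, `df2`, `mean_ranks`,
#'   `p_value` (upper tail of the F reference distribution).
#' @export
friedman_modified_f <- function(rank_matrix) {
  rank_matrix <- as.matrix(rank_matrix)
  N <- nrow(rank_matrix)
  k <- ncol(rank_matrix)
  if (N < 2 || k < 2) stop("need N >= 2 instances and k >= 2 algorithms")
  R <- colMeans(rank_matrix)
  chi2 <- (12 * N / (k * (k + 1))) * (sum(R^2) - k * (k + 1)^2 / 4)
  denom <- N * (k - 1) - chi2
  if (denom <= 0) stop("degenerate ranks: modified F undefined")
  FF <- (N - 1) * chi2 / denom
  df1 <- k - 1
  df2 <- (k - 1) * (N - 1)
  list(chi2_F = chi2, F_F = FF, df1 = df1, df2 = df2, mean_ranks = R,
       p_value = stats::pf(FF, df1, df2, lower.tail = FALSE))
}

#' Rank algorithm scores per instance
#'
#' @param scores N x k matrix of raw quality scores.
#' @param higher_is_better rank 1 goes to the best score (default TRUE).
#' @return N x k matrix of within-row ranks, ties as average ranks.
#' @export
rank_scores <- function(scores, higher_is_better = TRUE) {
  scores <- as.matrix(scores)
  t(apply(scores, 1L, function(r) {
    rank(if (higher_is_better) -r else r, ties.method = "average")
  }))
}

#' Post-hoc pairwise z statistic for mean ranks
#'
#' `z = (R_i - R_j) / sqrt(k(k+1) / (6N))`. With the Bonferroni correction
#' for three pairwise comparisons, the two-tailed critical p-value is
#' `0.025 / 3 = 0.00833`.
#'
#' @param R_i,R_j mean ranks of the two algorithms.
#' @param k number of algorithms.
#' @param N number of instances.
#' @return list with `z`, `p_value` (two-tailed normal) and
#'   `bonferroni_critical` (for three comparisons).
#' @export
posthoc_z <- function(R_i, R_j, k, N) {
  if (N < 1 || k < 2) stop("need N >= 1 and k >= 2")
  z <- (R_i - R_j) / sqrt(k * (k + 1) / (6 * N))
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)),
       bonferroni_critical = 0.025 / 3)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided paired-samples signed-rank test, delegated to
#' [stats::wilcox.test()], with the convention that identical samples (all
#' pairwise differences zero) give `p = 1` rather than an error.
#'
#' @param a,b paired numeric samples of equal length.
#' @return list with `statistic` (V, the sum of positive signed ranks) and
#'   `p_value`.
#' @export
wilcoxon_signed_rank <- function(a, b) {
  if (length(a) != length(b)) stop("paired samples differ in length")
  if (length(a) == 0L) stop("empty samples")
  d <- a - b
  if (all(d == 0)) return(list(statistic = 0, p_value = 1))
  res <- suppressWarnings(
    stats::wilcox.test(a, b, paired = TRUE, alternative = "two.sided")
  )
  list(statistic = unname(res$statistic), p_value = res$p.value)
}
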