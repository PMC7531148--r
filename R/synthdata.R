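# ---------------------------------------------------------------------------
# Synthetic tabular data with known structure: Gaussian mixtures (two
# overlapping clouds, the classic illustration of a complex boosted
# decision boundary), planted-conjunctive-rule data with label-flip noise
# (for parameter-recovery testing), and mixed numeric/ordinal tables
# emulating clinical questionnaire data.
# ---------------------------------------------------------------------------

# one draw from N(mu, Sigma) per row, via the Cholesky factor
rmvnorm_chol <- function(n, mu, sigma) {
  d <- length(mu)
  sigma <- as.matrix(sigma)
  if (!isSymmetric(sigma, tol = 1e-8)) stop("covariance must be symmetric")
  ch <- tryCatch(chol(sigma),
                 error = function(e) stop("covariance not positive definite"))
  z <- matrix(stats::rnorm(n * d), n, d)
  sweep(z %*% ch, 2L, mu, `+`)
}

#' Gaussian-mixture classification data
#'
#' Each class is one multivariate normal component; labels are drawn
#' i.i.d. from `class_proportions`. Reproducible under a fixed seed.
#'
#' @param n number of rows.
#' @param means list (or K x d matrix) of component means.
#' @param covariances list of d x d symmetric positive-definite matrices
#'   (a single matrix is recycled; default identity).
#' @param class_proportions mixing proportions summing to 1 (default
#'   uniform).
#' @param seed integer seed.
#' @param class_labels labels for the components (default `c1, c2, ...`).
#' @return list with `X` (n x d matrix), `y` (character labels) and
#'   `feature_names`.
#' @export
gaussian_mixture <- function(n, means = list(c(0, 0), c(2, 2)),
                             covariances = NULL, class_proportions = NULL,
                             seed = 1L, class_labels = NULL) {
  if (is.matrix(means)) means <- asplit(means, 1L)
  Kc <- length(means)
  d <- length(means[[1L]])
  if (is.null(covariances)) covariances <- list(diag(d))
  if (is.matrix(covariances)) covariances <- list(covariances)
  if (length(covariances) == 1L) covariances <- rep(covariances, Kc)
  if (is.null(class_proportions)) class_proportions <- rep(1 / Kc, Kc)
  if (abs(sum(class_proportions) - 1) > 1e-9) {
    stop("class proportions must sum to 1")
  }
  if (is.null(class_labels)) class_labels <- paste0("c", seq_len(Kc))

  set.seed(as.integer(seed))
  comp <- sample.int(Kc, n, replace = TRUE, prob = class_proportions)
  X <- matrix(0, n, d)
  for (k in seq_len(Kc)) {
    idx <- which(comp == k)
    if (length(idx) > 0L) {
      X[idx, ] <- rmvnorm_chol(length(idx), means[[k]], covariances[[k]])
    }
  }
  fn <- paste0("x", seq_len(d))
  colnames(X) <- fn
  list(X = X, y = class_labels[comp], feature_names = fn)
}

#' Specification of a planted conjunctive rule
#'
#' @param terms data.frame with columns `feature`, `op` (`"<="` or `">"`),
#'   `threshold` — the planted conjunction.
#' @param positive_class,negative_class labels assigned inside/outside the
#'   planted region (before noise).
#' @param noise_rate independent label-flip probability, in `[0, 0.5)`.
#' @param n_rows,n_features table dimensions.
#' @param ranges 2 x n_features matrix of uniform feature ranges (default
#'   all `[0, 1]`).
#' @return list of class `planted_rule_spec`.
#' @export
planted_rule_spec <- function(terms, positive_class = "pos",
                              negative_class = "neg", noise_rate = 0.05,
                              n_rows = 2000L, n_features = 5L,
                              ranges = NULL) {
  if (nrow(terms) == 0L) stop("planted rule needs at least one term")
  if (any(terms$feature < 1L | terms$feature > n_features)) {
    stop("planted terms reference invalid features")
  }
  if (noise_rate < 0 || noise_rate >= 0.5) stop("noise_rate must be in [0, 0.5)")
  if (is.null(ranges)) ranges <- rbind(rep(0, n_features), rep(1, n_features))
  structure(
    list(terms = terms, positive_class = positive_class,
         negative_class = negative_class, noise_rate = noise_rate,
         n_rows = as.integer(n_rows), n_features = as.integer(n_features),
         ranges = ranges),
    class = "planted_rule_spec"
  )
}

#' Tabular data with a planted conjunctive rule
#'
#' Features are uniform over the spec's ranges; the label is the positive
#' class iff all planted terms hold, then flipped independently with
#' probability `noise_rate`.
#'
#' @param spec a [planted_rule_spec()].
#' @param seed integer seed.
#' @return list with `X`, `y`, `y_clean` (pre-noise labels) and
#'   `feature_names`.
#' @export
planted_rule_dataset <- function(spec, seed = 1L) {
  set.seed(as.integer(seed))
  n <- spec$n_rows
  d <- spec$n_features
  X <- vapply(seq_len(d), function(j) {
    stats::runif(n, spec$ranges[1L, j], spec$ranges[2L, j])
  }, numeric(n))
  fn <- paste0("x", seq_len(d))
  colnames(X) <- fn
  inside <- covers(spec$terms, X)
  y_clean <- ifelse(inside, spec$positive_class, spec$negative_class)
  flip <- stats::runif(n) < spec$noise_rate
  other <- ifelse(y_clean == spec$positive_class,
                  spec$negative_class, spec$positive_class)
  y <- ifelse(flip, other, y_clean)
  list(X = X, y = y, y_clean = y_clean, feature_names = fn)
}

#' Mixed numeric/ordinal classification table
#'
#' Emulates clinical questionnaire data: continuous measurements plus
#' small-integer answer codes (0-4), two or more classes with mild
#' imbalance, and a class-dependent mean shift on every column so the
#' classes are learnable.
#'
#' @param n number of rows.
#' @param n_numeric,n_ordinal numbers of continuous and ordinal columns.
#' @param n_classes number of classes (>= 2).
#' @param imbalance class proportions (default mildly imbalanced,
#'   proportional to `n_classes:1`).
#' @param seed integer seed.
#' @return list with `X`, `y`, `feature_names` and `ordinal_columns`.
#' @export
mixed_tabular_fixture <- function(n, n_numeric = 3L, n_ordinal = 3L,
                                  n_classes = 2L, imbalance = NULL,
                                  seed = 1L) {
  if (n_classes < 2L) stop("need at least 2 classes")
  if (is.null(imbalance)) {
    imbalance <- rev(seq_len(n_classes))
    imbalance <- imbalance / sum(imbalance)
  }
  if (abs(sum(imbalance) - 1) > 1e-9) stop("imbalance must sum to 1")
  set.seed(as.integer(seed))
  labels <- paste0("class", seq_len(n_classes))
  yk <- sample.int(n_classes, n, replace = TRUE, prob = imbalance)

  num <- matrix(stats::rnorm(n * n_numeric), n, n_numeric)
  num <- num + matrix(0.8 * yk, n, n_numeric) # class-dependent shift
  ord <- matrix(0L, n, n_ordinal)
  for (j in seq_len(n_ordinal)) {
    # answer codes 0-4, distribution shifted by class
    p <- outer(yk, 0:4, function(k, a) stats::dpois(a, lambda = 0.8 + 0.6 * k))
    p <- p / rowSums(p)
    ord[, j] <- vapply(seq_len(n), function(i) {
      sample(0:4, 1L, prob = p[i, ])
    }, integer(1L))
  }
  X <- cbind(num, ord)
  fn <- c(paste0("num", seq_len(n_numeric)), paste0("ord", seq_len(n_ordinal)))
  colnames(X) <- fn
  list(X = X, y = labels[yk], feature_names = fn,
       ordinal_columns = n_numeric + seq_len(n_ordinal))
}
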