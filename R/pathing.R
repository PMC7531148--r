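# ---------------------------------------------------------------------------
# Decision-path extraction, majority tree set T+ with margin decomposition,
# and the relative-entropy machinery that substitutes for classifier weights
# under SAMME.R.
# ---------------------------------------------------------------------------

#' Kullback-Leibler divergence between two class distributions
#'
#' Relative entropy `sum_k P_k log(P_k / P'_k)`. Both vectors are floored at
#' `floor` and renormalised first, so distributions with exact zeros give a
#' finite value. Always nonnegative; zero iff the floored distributions are
#' equal.
#'
#' @param p,p_prime probability vectors of equal length, each summing to 1
#'   (within 1e-9).
#' @param floor small positive flooring constant (default 1e-12).
#' @return nonnegative scalar.
#' @export
kl_divergence <- function(p, p_prime, floor = 1e-12) {
  if (length(p) != length(p_prime)) {
    stop("distribution length mismatch: ", length(p), " vs ", length(p_prime))
  }
  if (floor <= 0) stop("floor must be > 0")
  if (abs(sum(p) - 1) > 1e-9 || abs(sum(p_prime) - 1) > 1e-9) {
    stop("inputs must be probability vectors summing to 1")
  }
  pf <- pmax(p, floor); pf <- pf / sum(pf)
  qf <- pmax(p_prime, floor); qf <- qf / sum(qf)
  sum(pf * log(pf / qf))
}

#' Extract the decision path of one instance through one tree
#'
#' Walks from the root to the reached leaf, recording one node detail triple
#' `(feature, threshold, truth)` per internal node visited, where `truth` is
#' whether the instance satisfies `x[feature] <= threshold`. Branches the
#' instance does not take never appear, so the path alone reproduces the
#' tree's output for this instance.
#'
#' @param tree a `whips_tree`.
#' @param x a single instance.
#' @param tree_index index of the tree within its ensemble (bookkeeping).
#' @return a list of class `whips_path` with `triples` (data.frame with
#'   columns `feature`, `threshold`, `truth`), `tree_index`,
#'   `terminal_posterior` and `path_weight` (`NA` until assigned by
#'   [majority_trees()]).
#' @export
extract_path <- function(tree, x, tree_index = tree$iteration) {
  feature <- integer(0); threshold <- double(0); truth <- logical(0)
  id <- 1L
  while (!is.na(tree$feature[id])) {
    j <- tree$feature[id]
    v <- tree$threshold[id]
    tau <- x[j] <= v
    feature <- c(feature, j)
    threshold <- c(threshold, v)
    truth <- c(truth, tau)
    id <- if (tau) tree$left[id] else tree$right[id]
  }
  structure(
    list(
      triples = data.frame(feature = feature, threshold = threshold,
                           truth = truth),
      tree_index = tree_index,
      terminal_posterior = as.numeric(tree$posterior[id, ]),
      path_weight = NA_real_
    ),
    class = "whips_path"
  )
}

#' SAMME.R path weight: relative entropy of leaf posterior vs the prior
#'
#' The weight substituted for the (absent) SAMME.R classifier weight: the KL
#' divergence between the posterior class distribution at the leaf reached
#' by `x` and the training prior. Larger for trees whose leaf separates the
#' classes more sharply than the prior does.
#'
#' @param tree a `whips_tree`.
#' @param x a single instance.
#' @param prior training-label class distribution.
#' @param floor flooring constant passed to [kl_divergence()].
#' @return nonnegative scalar.
#' @export
samme_r_tree_weight <- function(tree, x, prior, floor = 1e-12) {
  leaf <- tree_leaf_ids(tree, matrix(x, nrow = 1L))
  kl_divergence(as.numeric(tree$posterior[leaf, ]), prior, floor = floor)
}

#' Majority-agreeing trees and margin decomposition for one instance
#'
#' Identifies the set T+ of base trees whose individual classification of
#' `x` agrees with the full ensemble's prediction (for SAMME, the tree's
#' one-hot vote; for SAMME.R, the argmax of the tree's run-time confidence
#' vector). T+ alone determines the ensemble output: adding back any subset
#' of the disagreeing trees T- cannot change the prediction.
#'
#' For SAMME, `a_plus` is the summed weight of T+, `a_minus` the weight of
#' T- averaged over the K-1 non-majority classes, and
#' `margin = (a_plus - a_minus) / sum(alpha)`, in (0, 1]. For SAMME.R the
#' same decomposition is computed from the KL-divergence path weights and
#' `margin` is reported as `NA` (no established margin formalisation).
#'
#' @param model a `whips_model`.
#' @param x a single instance.
#' @return list of class `whips_margin`: `predicted_class`,
#'   `majority_paths` (list of `whips_path` with `path_weight` filled in),
#'   `minority_tree_indices`, `a_plus`, `a_minus`, `margin`.
#' @export
majority_trees <- function(model, x) {
  x <- as.numeric(x)
  K <- length(model$class_labels)
  pred <- predict(model, x, type = "class")
  pred_k <- match(pred, model$class_labels)

  M <- length(model$trees)
  agree <- logical(M)
  weight <- numeric(M)
  for (m in seq_len(M)) {
    tree <- model$trees[[m]]
    if (model$algorithm == "SAMME") {
      vote <- which.max(tree_output(tree, x, "SAMME"))
      agree[m] <- vote == pred_k
      weight[m] <- tree$alpha
    } else {
      conf <- as.numeric(samme_r_conf_matrix(tree, matrix(x, nrow = 1L)))
      agree[m] <- which.max(conf) == pred_k
      weight[m] <- samme_r_tree_weight(tree, x, model$prior)
    }
  }

  a_plus <- sum(weight[agree])
  a_minus <- sum(weight[!agree]) / (K - 1)
  margin <- if (model$algorithm == "SAMME") {
    (a_plus - a_minus) / sum(weight)
  } else {
    NA_real_
  }

  paths <- lapply(which(agree), function(m) {
    p <- extract_path(model$trees[[m]], x, tree_index = m)
    p$path_weight <- weight[m]
    p
  })

  structure(
    list(
      predicted_class = pred, majority_paths = paths,
      minority_tree_indices = which(!agree),
      a_plus = a_plus, a_minus = a_minus, margin = margin
    ),
    class = "whips_margin"
  )
}
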