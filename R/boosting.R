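# ---------------------------------------------------------------------------
# Shallow weighted-entropy decision trees and multi-class AdaBoost (SAMME /
# SAMME.R). Trees are stored in a flat, vectorised layout (one slot per node,
# children referenced by integer id) so that path extraction, batch
# prediction and JSON serialisation stay cheap.
# ---------------------------------------------------------------------------

#' Fit a weighted entropy-split decision tree
#'
#' Grows a binary CART-style tree by exhaustive search for the split that
#' minimises the weighted entropy of the two children. Split thresholds are
#' midpoints between consecutive distinct sorted feature values; an instance
#' with `x[j] <= threshold` goes left. Every leaf stores the weighted class
#' distribution (posterior) of the training instances that reach it.
#'
#' @param X numeric feature matrix (rows = instances).
#' @param y class labels: integer codes `1..n_classes` or a factor.
#' @param w nonnegative instance weights, one per row; defaults to uniform.
#' @param maxdepth maximum depth (root is depth 0); must be >= 1.
#' @param n_classes number of classes K. Defaults to the number of observed
#'   levels of `y`; set explicitly when a subset of the data may be missing
#'   some class.
#' @return an object of class `whips_tree`: a flat node table with fields
#'   `feature`, `threshold`, `left`, `right`, `depth` (all `NA` for leaves
#'   except `depth`), a `posterior` matrix (nodes x K) and `weight_mass`
#'   (sum of instance weights reaching the node). `alpha` and `iteration`
#'   are filled in by the boosting loop.
#' @export
fit_tree <- function(X, y, w = NULL, maxdepth = 4L, n_classes = NULL) {
  X <- as.matrix(X)
  if (is.factor(y)) y <- as.integer(y)
  y <- as.integer(y)
  n <- nrow(X)
  if (n == 0L || length(y) == 0L) stop("no training data")
  if (length(y) != n) stop("X rows and y length differ")
  if (is.null(w)) w <- rep(1 / n, n)
  if (length(w) != n) stop("weight vector length differs from X rows")
  if (any(w < 0)) stop("negative instance weights")
  if (sum(w) <= 0) stop("instance weights sum to zero")
  if (maxdepth < 1L) stop("maxdepth must be >= 1")
  K <- if (is.null(n_classes)) max(y) else as.integer(n_classes)

  # growing accumulators; <=2^(maxdepth+1)-1 nodes, appended in preorder
  acc <- new.env(parent = emptyenv())
  acc$feature <- integer(0)
  acc$threshold <- double(0)
  acc$left <- integer(0)
  acc$right <- integer(0)
  acc$depth <- integer(0)
  acc$posterior <- NULL
  acc$weight_mass <- double(0)

  grow(acc, X, y, w, seq_len(n), depth = 0L, maxdepth = maxdepth, K = K)

  structure(
    list(
      feature = acc$feature, threshold = acc$threshold,
      left = acc$left, right = acc$right, depth = acc$depth,
      posterior = acc$posterior, weight_mass = acc$weight_mass,
      alpha = NA_real_, iteration = NA_integer_, n_classes = K
    ),
    class = "whips_tree"
  )
}

# recursive growth; returns the id of the node it created
grow <- function(acc, X, y, w, idx, depth, maxdepth, K) {
  wsub <- w[idx]
  ysub <- y[idx]
  cls_w <- vapply(seq_len(K), function(k) sum(wsub[ysub == k]), 0)
  mass <- sum(cls_w)
  post <- if (mass > 0) cls_w / mass else rep(1 / K, K)

  id <- length(acc$feature) + 1L
  acc$feature[id] <- NA_integer_
  acc$threshold[id] <- NA_real_
  acc$left[id] <- NA_integer_
  acc$right[id] <- NA_integer_
  acc$depth[id] <- depth
  acc$weight_mass[id] <- mass
  acc$posterior <- rbind(acc$posterior, post)

  pure <- sum(cls_w > 0) <= 1L
  if (depth >= maxdepth || pure || length(idx) < 2L) return(id)

  sp <- best_split(X, y, w, idx, K)
  if (is.null(sp)) return(id)

  go_left <- X[idx, sp$feature] <= sp$threshold
  acc$feature[id] <- sp$feature
  acc$threshold[id] <- sp$threshold
  acc$left[id] <- grow(acc, X, y, w, idx[go_left], depth + 1L, maxdepth, K)
  acc$right[id] <- grow(acc, X, y, w, idx[!go_left], depth + 1L, maxdepth, K)
  id
}

# v*log(v) with the 0*log(0) = 0 convention
xlogx <- function(v) {
  out <- numeric(length(v))
  pos <- v > 0
  out[pos] <- v[pos] * log(v[pos])
  out
}

# Exhaustive best weighted-entropy split over all features; NULL only when
# no candidate cut exists (all rows identical on every feature). Zero-gain
# splits are allowed on impure nodes (pure nodes never reach here), so
# XOR-style patterns that need two levels to show any gain remain
# learnable. Uses per-class cumulative weight sums over the per-feature
# sort order, so each feature is O(s log s).
best_split <- function(X, y, w, idx, K) {
  s <- length(idx)
  wsub <- w[idx]
  ysub <- y[idx]
  tot_k <- vapply(seq_len(K), function(k) sum(wsub[ysub == k]), 0)
  W <- sum(tot_k)
  parent <- xlogx(W) - sum(xlogx(tot_k)) # W * H(parent)

  best <- NULL
  best_gain <- -Inf
  for (j in seq_len(ncol(X))) {
    xv <- X[idx, j]
    ord <- order(xv, method = "radix")
    xs <- xv[ord]
    cut_ok <- xs[-s] != xs[-1L] # candidate cuts between distinct values
    if (!any(cut_ok)) next
    ws <- wsub[ord]
    ys <- ysub[ord]
    # cumulative class-weight matrix, rows = prefix lengths 1..s-1
    cw <- matrix(0, s, K)
    cw[cbind(seq_len(s), ys)] <- ws
    cw <- apply(cw, 2L, cumsum)
    wl <- cw[-s, , drop = FALSE]
    wr <- rep(tot_k, each = s - 1L) - wl
    WL <- rowSums(wl)
    WR <- W - WL
    child <- xlogx(WL) - rowSums(matrix(xlogx(wl), ncol = K)) +
      xlogx(WR) - rowSums(matrix(xlogx(wr), ncol = K))
    gain <- parent - child
    gain[!cut_ok] <- -Inf
    i <- which.max(gain)
    if (gain[i] > best_gain) {
      best_gain <- gain[i]
      best <- list(feature = j, threshold = (xs[i] + xs[i + 1L]) / 2)
    }
  }
  best
}

# leaf id reached by every row of X (vectorised frontier propagation)
tree_leaf_ids <- function(tree, X) {
  n <- nrow(X)
  node <- rep(1L, n)
  repeat {
    f <- tree$feature[node]
    open <- !is.na(f)
    if (!any(open)) return(node)
    i <- which(open)
    thr <- tree$threshold[node[i]]
    goes_left <- X[cbind(i, f[i])] <= thr
    node[i] <- ifelse(goes_left, tree$left[node[i]], tree$right[node[i]])
  }
}

#' Output of a single base tree for one instance
#'
#' Under SAMME the tree casts a one-hot vote for the majority class of the
#' reached leaf; under SAMME.R it returns the leaf's full posterior class
#' distribution (the weighted class distribution of training instances in
#' that leaf). Either way the returned vector sums to 1.
#'
#' @param tree a `whips_tree`.
#' @param x a single instance (numeric vector).
#' @param algorithm `"SAMME"` or `"SAMME.R"`.
#' @return numeric vector of length K summing to 1.
#' @export
tree_output <- function(tree, x, algorithm = c("SAMME", "SAMME.R")) {
  algorithm <- match.arg(algorithm)
  leaf <- tree_leaf_ids(tree, matrix(x, nrow = 1L))
  post <- tree$posterior[leaf, ]
  if (algorithm == "SAMME") {
    out <- numeric(length(post))
    out[which.max(post)] <- 1
    out
  } else {
    post
  }
}

# SAMME classifier weight (error must already satisfy 0 < err <= 1 - 1/K)
samme_alpha <- function(err, K) log((1 - err) / err) + log(K - 1)

# run-time SAMME.R confidence weights from a leaf posterior (floored so the
# logs are finite); the vector is centred and therefore sums to zero
samme_r_confidence <- function(posterior, floor = 1e-12) {
  lp <- log(pmax(posterior, floor))
  K <- length(posterior)
  (K - 1) * (lp - mean(lp))
}

#' Train a multi-class AdaBoost ensemble
#'
#' Boosts shallow weighted-entropy decision trees. `"SAMME"` uses discrete
#' one-hot votes weighted by `alpha = log((1 - err)/err) + log(K - 1)`;
#' boosting halts early when a round is perfect (error clipped at 1e-10)
#' or no better than chance (`err > 1 - 1/K`, round discarded). `"SAMME.R"`
#' carries no per-tree weight: confidence weights are computed at
#' prediction time from the floored leaf posteriors.
#'
#' @param X numeric feature matrix.
#' @param y class labels (factor, character or integer); at least two
#'   distinct values.
#' @param algorithm `"SAMME"` (default) or `"SAMME.R"`.
#' @param ntrees maximum number of boosting rounds.
#' @param maxdepth maximum tree depth (default 4).
#' @param seed optional integer seed (training is deterministic; the seed is
#'   recorded in the model for provenance).
#' @param feature_names column names for rendering rule terms; defaults to
#'   `colnames(X)` or `x1..xd`.
#' @return an object of class `whips_model` with elements `algorithm`,
#'   `trees` (list of `whips_tree`), `class_labels`, `prior` (training class
#'   frequencies), and `feature_names`.
#' @export
ada_boost <- function(X, y, algorithm = c("SAMME", "SAMME.R"), ntrees = 200L,
                      maxdepth = 4L, seed = NULL,
                      feature_names = NULL) {
  algorithm <- match.arg(algorithm)
  X <- as.matrix(X)
  if (nrow(X) == 0L) stop("no training data")
  if (ntrees < 1L) stop("ntrees must be >= 1")
  if (!is.null(seed)) set.seed(as.integer(seed))

  labels <- sort(unique(as.character(y)))
  if (length(labels) < 2L) stop("degenerate labels: need at least 2 classes")
  yi <- match(as.character(y), labels)
  K <- length(labels)
  n <- nrow(X)
  prior <- as.numeric(tabulate(yi, K)) / n
  if (is.null(feature_names)) {
    feature_names <- colnames(X)
    if (is.null(feature_names)) feature_names <- paste0("x", seq_len(ncol(X)))
  }

  w <- rep(1 / n, n)
  trees <- vector("list", ntrees)
  m_used <- 0L
  for (m in seq_len(ntrees)) {
    tree <- fit_tree(X, yi, w, maxdepth = maxdepth, n_classes = K)
    leaf <- tree_leaf_ids(tree, X)
    pred <- max.col(tree$posterior[leaf, , drop = FALSE], ties.method = "first")
    miss <- pred != yi
    err <- sum(w[miss])

    if (algorithm == "SAMME") {
      if (err > 1 - 1 / K) break # worse than chance: discard round, stop
      stop_now <- err <= 0
      err_c <- max(err, 1e-10)
      tree$alpha <- samme_alpha(err_c, K)
      tree$iteration <- m
      m_used <- m
      trees[[m]] <- tree
      if (stop_now) break
      w <- w * exp(tree$alpha * miss)
      w <- w / sum(w)
    } else {
      tree$alpha <- NA_real_ # SAMME.R: weights evaluated at run time
      tree$iteration <- m
      m_used <- m
      trees[[m]] <- tree
      if (err <= 0) break
      # w_i <- w_i * exp(-((K-1)/K) * y_i . log p(x_i)), y in +-1/(K-1) coding
      lp <- log(pmax(tree$posterior[leaf, , drop = FALSE], 1e-12))
      ydot <- lp[cbind(seq_len(n), yi)] - (1 / (K - 1)) *
        (rowSums(lp) - lp[cbind(seq_len(n), yi)])
      w <- w * exp(-((K - 1) / K) * ydot)
      w <- w / sum(w)
    }
  }
  trees <- trees[seq_len(m_used)]
  if (length(trees) == 0L) stop("boosting produced no usable tree")

  structure(
    list(
      algorithm = algorithm, trees = trees, class_labels = labels,
      prior = prior, feature_names = feature_names,
      maxdepth = as.integer(maxdepth), seed = seed
    ),
    class = "whips_model"
  )
}

# per-tree SAMME.R confidence matrix for a batch (rows x K), one tree
samme_r_conf_matrix <- function(tree, X, floor = 1e-12) {
  leaf <- tree_leaf_ids(tree, X)
  lp <- log(pmax(tree$posterior[leaf, , drop = FALSE], floor))
  K <- ncol(lp)
  (K - 1) * (lp - rowMeans(lp))
}

# ensemble score matrix (rows x K): Eq-1 weighted vote tallies for SAMME,
# summed run-time confidence weights for SAMME.R
ensemble_scores <- function(model, X) {
  X <- as.matrix(X)
  K <- length(model$class_labels)
  scores <- matrix(0, nrow(X), K)
  for (tree in model$trees) {
    if (model$algorithm == "SAMME") {
      leaf <- tree_leaf_ids(tree, X)
      vote <- max.col(tree$posterior[leaf, , drop = FALSE],
                      ties.method = "first")
      scores[cbind(seq_len(nrow(X)), vote)] <-
        scores[cbind(seq_len(nrow(X)), vote)] + tree$alpha
    } else {
      scores <- scores + samme_r_conf_matrix(tree, X)
    }
  }
  colnames(scores) <- model$class_labels
  scores
}

#' Predict with a boosted ensemble
#'
#' @param object a `whips_model`.
#' @param newdata feature matrix (or single instance vector).
#' @param type `"class"` for predicted labels, `"scores"` for the per-class
#'   vote/confidence tallies, `"full"` for both plus (SAMME.R) the per-tree
#'   confidence vectors of a single instance.
#' @param ... unused.
#' @return labels, a score matrix, or a list, per `type`. Ties are broken
#'   deterministically towards the lowest class index.
#' @export
predict.whips_model <- function(object, newdata,
                                type = c("class", "scores", "full"), ...) {
  type <- match.arg(type)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) > 0 && length(object$feature_names) != ncol(newdata)) {
    stop("dimensionality mismatch: model expects ",
         length(object$feature_names), " features, got ", ncol(newdata))
  }
  scores <- ensemble_scores(object, newdata)
  cls <- object$class_labels[max.col(scores, ties.method = "first")]
  switch(type,
    class = cls,
    scores = scores,
    full = {
      per_tree <- NULL
      if (object$algorithm == "SAMME.R" && nrow(newdata) == 1L) {
        per_tree <- lapply(object$trees, function(tr) {
          as.numeric(samme_r_conf_matrix(tr, newdata))
        })
      }
      list(predicted_class = cls, class_scores = scores,
           per_tree_confidences = per_tree)
    }
  )
}

#' @export
print.whips_model <- function(x, ...) {
  cat(sprintf(
    "Boosted ensemble (%s): %d trees, maxdepth %d, %d classes [%s]\n",
    x$algorithm, length(x$trees), x$maxdepth,
    length(x$class_labels), paste(x$class_labels, collapse = ", ")
  ))
  invisible(x)
}
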