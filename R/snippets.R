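# ---------------------------------------------------------------------------
# Weight redistribution: disaggregate the retained decision paths into
# individual decision nodes ("path snippets"), score each node by the
# sequential relative entropy it contributes, renormalise each path's
# scores to its classifier weight, pool duplicates, filter and sort.
# ---------------------------------------------------------------------------

# class distribution of y over a logical mask, in K slots
class_distribution <- function(y, mask, K) {
  cnt <- tabulate(y[mask], K)
  s <- sum(cnt)
  if (s == 0L) return(NULL)
  cnt / s
}

#' Sequential relative-entropy scores along one decision path
#'
#' Scores the i-th node of a path by the KL divergence between the training
#' class distribution after applying the first `i` decisions (P) and the
#' distribution after the first `i - 1` (P'), with the prior playing P' at
#' the root. Distributions are computed from the (ground-truth) training
#' labels over the subset of training rows satisfying the conjunction of
#' triples; once the surviving subset is empty, that node and all deeper
#' ones score 0.
#'
#' @param path a `whips_path`.
#' @param X_train training feature matrix.
#' @param y_train training labels as integer codes `1..K` (or a vector of
#'   model predictions when scoring against the model instead of ground
#'   truth).
#' @param prior training class distribution (P' for the root node).
#' @return numeric vector, one nonnegative score per triple (empty for a
#'   root-leaf path).
#' @export
path_node_scores <- function(path, X_train, y_train, prior) {
  triples <- path$triples
  n_nodes <- nrow(triples)
  if (is.null(n_nodes) || n_nodes == 0L) return(numeric(0))
  X_train <- as.matrix(X_train)
  if (is.factor(y_train)) y_train <- as.integer(y_train)
  K <- length(prior)

  scores <- numeric(n_nodes)
  mask <- rep(TRUE, nrow(X_train))
  prev <- prior
  for (i in seq_len(n_nodes)) {
    j <- triples$feature[i]
    v <- triples$threshold[i]
    mask <- mask & if (triples$truth[i]) X_train[, j] <= v else X_train[, j] > v
    cur <- class_distribution(y_train, mask, K)
    if (is.null(cur)) break # empty subset: this and deeper nodes score 0
    scores[i] <- kl_divergence(cur, prev)
    prev <- cur
  }
  scores
}

#' Rescale node scores so they sum to the path's classifier weight
#'
#' Preserves proportions. An all-zero score vector (possible when the
#' surviving subsets are empty or the distributions never move) distributes
#' the weight uniformly over the path's nodes.
#'
#' @param scores nonnegative node scores.
#' @param path_weight nonnegative path weight (`alpha` for SAMME, the KL
#'   substitute for SAMME.R).
#' @return vector of the same length summing to `path_weight`.
#' @export
normalize_to_weight <- function(scores, path_weight) {
  if (any(scores < 0)) stop("negative node score")
  if (path_weight < 0) stop("negative path weight")
  if (length(scores) == 0L) return(numeric(0))
  total <- sum(scores)
  if (total == 0) return(rep(path_weight / length(scores), length(scores)))
  scores * (path_weight / total)
}

#' Pool identical decision nodes across paths
#'
#' Groups normalised node scores by exact `(feature, threshold, truth)`
#' identity and sums within groups, so total weight is conserved: the sum of
#' all snippet weights equals the sum of all path weights.
#'
#' @param paths list of `whips_path` objects.
#' @param score_list list of normalised score vectors, parallel to `paths`.
#' @return data.frame of class `whips_snippets` with columns `feature`,
#'   `threshold`, `truth`, `weight`, `support` (number of contributing
#'   paths).
#' @export
aggregate_snippets <- function(paths, score_list) {
  stopifnot(length(paths) == length(score_list))
  keep <- vapply(paths, function(p) nrow(p$triples) > 0L, TRUE)
  paths <- paths[keep]
  score_list <- score_list[keep]
  if (length(paths) == 0L) {
    return(structure(
      data.frame(feature = integer(0), threshold = double(0),
                 truth = logical(0), weight = double(0), support = integer(0)),
      class = c("whips_snippets", "data.frame")
    ))
  }
  all_triples <- do.call(rbind, lapply(paths, `[[`, "triples"))
  all_scores <- unlist(score_list, use.names = FALSE)
  if (length(all_scores) != nrow(all_triples)) {
    stop("score vectors do not match path lengths")
  }
  key <- paste(all_triples$feature,
               format(all_triples$threshold, digits = 17),
               all_triples$truth)
  first <- !duplicated(key)
  out <- all_triples[first, , drop = FALSE]
  grp <- match(key, key[first]) # group ids in first-occurrence order
  w <- rowsum(all_scores, grp)
  cnt <- rowsum(rep(1L, length(grp)), grp)
  out$weight <- as.numeric(w[as.character(seq_len(sum(first))), 1L])
  out$support <- as.integer(cnt[as.character(seq_len(sum(first))), 1L])
  rownames(out) <- NULL
  structure(out, class = c("whips_snippets", "data.frame"))
}

#' Keep the heaviest snippets, sorted
#'
#' Retains the top `ceiling(top_fraction * n)` snippets by weight and
#' returns them sorted by weight descending, with deterministic tie-breaks
#' (feature, then threshold ascending, then truth).
#'
#' @param snippets a `whips_snippets` data.frame.
#' @param top_fraction fraction in (0, 1]; default 0.2.
#' @return the filtered, sorted `whips_snippets`.
#' @export
filter_and_sort <- function(snippets, top_fraction = 0.2) {
  if (nrow(snippets) == 0L) stop("no snippets")
  if (top_fraction <= 0 || top_fraction > 1) {
    stop("top_fraction must be in (0, 1]")
  }
  ord <- order(-snippets$weight, snippets$feature, snippets$threshold,
               snippets$truth)
  keep <- ceiling(top_fraction * nrow(snippets))
  out <- snippets[ord[seq_len(keep)], , drop = FALSE]
  rownames(out) <- NULL
  out
}
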