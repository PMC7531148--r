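# ---------------------------------------------------------------------------
# Greedy assembly of a single conjunctive classification rule from the
# sorted snippets, optimising the stability objective (a regularised
# precision that penalises tiny coverage).
# ---------------------------------------------------------------------------

# rule terms live in a data.frame: feature (int), op ("<=" or ">"),
# threshold (double), feature_name (chr)
empty_terms <- function() {
  data.frame(feature = integer(0), op = character(0), threshold = double(0),
             feature_name = character(0), stringsAsFactors = FALSE)
}

#' Which instances satisfy a conjunction of rule terms?
#'
#' @param terms rule terms (data.frame with `feature`, `op`, `threshold`).
#'   An empty term list covers everything.
#' @param X feature matrix (or a single instance vector).
#' @return logical vector, one element per row of `X`.
#' @export
covers <- function(terms, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  X <- as.matrix(X)
  mask <- rep(TRUE, nrow(X))
  for (i in seq_len(nrow(terms))) {
    v <- X[, terms$feature[i]]
    mask <- mask & if (terms$op[i] == "<=") v <= terms$threshold[i]
                   else v > terms$threshold[i]
  }
  mask
}

#' Precision of a rule against model predictions
#'
#' The fraction of instances covered by the antecedent whose model
#' prediction equals the consequent class; 0 by convention when the rule
#' covers nothing.
#'
#' @param terms rule terms.
#' @param consequent class label asserted by the rule.
#' @param X evaluation feature matrix.
#' @param model a `whips_model`, or a precomputed character vector of
#'   predictions for the rows of `X`.
#' @return scalar in \[0, 1\].
#' @export
rule_precision <- function(terms, consequent, X, model) {
  pred <- if (is.character(model)) model else predict(model, X, type = "class")
  m <- covers(terms, X)
  if (!any(m)) return(0)
  sum(pred[m] == consequent) / sum(m)
}

#' Coverage of a rule over a data set
#'
#' @param terms rule terms.
#' @param X evaluation feature matrix with at least one row.
#' @return fraction of rows satisfying the antecedent.
#' @export
rule_coverage <- function(terms, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (nrow(X) == 0L) stop("empty evaluation set")
  mean(covers(terms, X))
}

#' Stability of a rule: precision regularised against tiny coverage
#'
#' `zeta = |{z in Z : g(z) = consequent}| / (|Z| + K)` where Z is the
#' covered set and K the number of classes. Equals
#' `precision * |Z| / (|Z| + K)`, so it approaches precision as coverage
#' grows but a rule covering a single matching instance scores only
#' `1 / (1 + K)` — a brake on tautological, over-fitting rules.
#'
#' @inheritParams rule_precision
#' @param K number of classes (>= 2).
#' @return scalar in \[0, 1).
#' @export
stability <- function(terms, consequent, X, model, K) {
  if (K < 2) stop("K must be >= 2")
  pred <- if (is.character(model)) model else predict(model, X, type = "class")
  m <- covers(terms, X)
  sum(pred[m] == consequent) / (sum(m) + K)
}

# insert a term, intersecting with an existing bound on the same feature
# (<=: keep the smaller threshold; >: keep the larger)
add_term <- function(terms, feature, op, threshold, feature_name) {
  hit <- which(terms$feature == feature & terms$op == op)
  if (length(hit) == 1L) {
    tighter <- if (op == "<=") threshold < terms$threshold[hit]
               else threshold > terms$threshold[hit]
    if (tighter) terms$threshold[hit] <- threshold
    return(terms)
  }
  rbind(terms, data.frame(feature = feature, op = op, threshold = threshold,
                          feature_name = feature_name,
                          stringsAsFactors = FALSE))
}

#' Greedily merge sorted snippets into one classification rule
#'
#' Walks the weight-sorted snippet list. The first snippet's term is always
#' added; each later term is kept only if it strictly increases stability
#' on the evaluation data, with terms on the same feature intersected into
#' at most a lower and an upper bound. The walk stops once stability
#' reaches `stability_threshold` or the list is exhausted. The consequent
#' is fixed to the model's prediction of the explanandum, so the rule has
#' perfect fidelity by construction.
#'
#' @param snippets sorted `whips_snippets` (from [filter_and_sort()]).
#' @param x the explanandum instance.
#' @param consequent the model's predicted class for `x`.
#' @param X evaluation feature matrix (normally the training data).
#' @param model a `whips_model` or precomputed prediction vector for `X`.
#' @param K number of classes.
#' @param stability_threshold stop once stability reaches this (default
#'   0.95).
#' @param feature_names display names for rule terms.
#' @return list of class `whips_rule`: `terms`, `consequent`, `stats`
#'   (coverage, precision, stability, prior placeholder) and
#'   `stability_trace` (stability after each accepted term).
#' @export
greedy_merge <- function(snippets, x, consequent, X, model, K,
                         stability_threshold = 0.95,
                         feature_names = NULL) {
  if (nrow(snippets) == 0L) stop("no snippets to merge")
  X <- as.matrix(X)
  pred <- if (is.character(model)) model else predict(model, X, type = "class")
  if (is.null(feature_names)) feature_names <- paste0("x", seq_len(ncol(X)))

  snip_op <- ifelse(snippets$truth, "<=", ">")
  terms <- empty_terms()
  trace <- numeric(0)
  zeta <- -Inf

  for (i in seq_len(nrow(snippets))) {
    cand <- add_term(terms, snippets$feature[i], snip_op[i],
                     snippets$threshold[i],
                     feature_names[snippets$feature[i]])
    cand_zeta <- stability(cand, consequent, X, pred, K)
    accept <- if (i == 1L) TRUE else cand_zeta > zeta
    if (accept) {
      terms <- cand
      zeta <- cand_zeta
      trace <- c(trace, zeta)
    }
    if (zeta >= stability_threshold) break
  }

  structure(
    list(
      terms = terms, consequent = consequent,
      stats = list(
        coverage = rule_coverage(terms, X),
        precision = rule_precision(terms, consequent, X, pred),
        stability = zeta, prior = NA_real_
      ),
      stability_trace = trace
    ),
    class = "whips_rule"
  )
}

# human-readable rendering, e.g. "DP <= 0.0013 & FHR > 133.5 => Pathological"
format_rule <- function(rule, digits = 4) {
  if (nrow(rule$terms) == 0L) {
    return(paste("TRUE =>", rule$consequent))
  }
  lhs <- paste(
    sprintf("%s %s %s", rule$terms$feature_name, rule$terms$op,
            signif(rule$terms$threshold, digits)),
    collapse = " & "
  )
  paste(lhs, "=>", rule$consequent)
}

#' @export
print.whips_rule <- function(x, ...) {
  cat(format_rule(x), "\n")
  cat(sprintf("coverage %.3f | precision %.3f | stability %.3f\n",
              x$stats$coverage, x$stats$precision, x$stats$stability))
  invisible(x)
}
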