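# ---------------------------------------------------------------------------
# Counterfactual contrast sets: reverse one rule inequality at a time,
# measure the precision drop, and prune terms whose reversal barely moves
# precision (non-counterfactual, hence redundant, conditions).
# ---------------------------------------------------------------------------

#' Reverse a single rule inequality
#'
#' Flips `<=` to `>` (and vice versa) at the identical threshold, so the
#' reversed term's region is disjoint from the original in that dimension.
#'
#' @param term a one-row rule-term data.frame.
#' @return the reversed one-row term.
#' @export
reverse_inequality <- function(term) {
  term$op <- ifelse(term$op == "<=", ">", "<=")
  term
}

#' Counterfactual contrast set of a rule
#'
#' For each inequality in the rule, computes the precision of the rule with
#' that single inequality reversed (all other terms and the consequent
#' unchanged) and the resulting change in precision — typically a drop.
#' A two-sided interval on one feature contributes two items, one per
#' boundary.
#'
#' @param rule a `whips_rule` with at least one term.
#' @param X evaluation feature matrix.
#' @param model a `whips_model` or precomputed prediction vector for `X`.
#' @return data.frame with one row per inequality: `feature`,
#'   `feature_name`, `op`, `threshold`, `reversed_op`,
#'   `counterfactual_precision` and `delta` (counterfactual minus original
#'   precision).
#' @export
contrast_set <- function(rule, X, model) {
  if (nrow(rule$terms) == 0L) stop("rule has no terms to reverse")
  X <- as.matrix(X)
  pred <- if (is.character(model)) model else predict(model, X, type = "class")
  base_prec <- rule_precision(rule$terms, rule$consequent, X, pred)

  items <- lapply(seq_len(nrow(rule$terms)), function(i) {
    terms_cf <- rule$terms
    terms_cf[i, ] <- reverse_inequality(terms_cf[i, ])
    cf_prec <- rule_precision(terms_cf, rule$consequent, X, pred)
    data.frame(
      feature = rule$terms$feature[i],
      feature_name = rule$terms$feature_name[i],
      op = rule$terms$op[i],
      threshold = rule$terms$threshold[i],
      reversed_op = terms_cf$op[i],
      counterfactual_precision = cf_prec,
      delta = cf_prec - base_prec,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, items)
}

#' Prune redundant (non-counterfactual) rule terms
#'
#' A term whose reversal decreases precision by no more than `tolerance` is
#' not doing counterfactual work and is removed. Candidates are removed one
#' at a time, weakest precision drop first, re-evaluating the contrasts
#' after each removal until a fixpoint (with `fixpoint = FALSE`, at most
#' one removal is made). The rule is never emptied: the last remaining term is
#' always retained. Removing conjuncts can only grow coverage, and the
#' explanandum still satisfies the pruned rule.
#'
#' @param rule a `whips_rule`.
#' @param X evaluation feature matrix.
#' @param model a `whips_model` or precomputed prediction vector for `X`.
#' @param tolerance maximum tolerated precision drop (default 0.05).
#' @param K number of classes (to refresh the stability stat).
#' @param fixpoint re-iterate until no further term is removable (default).
#' @return the pruned `whips_rule` with refreshed `stats`.
#' @export
prune_redundant <- function(rule, X, model, tolerance = 0.05, K = 2L,
                            fixpoint = TRUE) {
  if (tolerance < 0) stop("tolerance must be >= 0")
  X <- as.matrix(X)
  pred <- if (is.character(model)) model else predict(model, X, type = "class")

  passes <- 0L
  repeat {
    if (nrow(rule$terms) <= 1L) break
    cs <- contrast_set(rule, X, pred)
    drop <- -cs$delta # precision decrease caused by each reversal
    removable <- which(drop <= tolerance)
    if (length(removable) == 0L) break
    victim <- removable[which.min(drop[removable])]
    rule$terms <- rule$terms[-victim, , drop = FALSE]
    rownames(rule$terms) <- NULL
    passes <- passes + 1L
    if (!fixpoint && passes >= 1L) break # single removal pass
  }

  rule$stats$coverage <- rule_coverage(rule$terms, X)
  rule$stats$precision <- rule_precision(rule$terms, rule$consequent, X, pred)
  rule$stats$stability <- stability(rule$terms, rule$consequent, X, pred, K)
  rule
}

#' Explain one classification of a boosted ensemble
#'
#' The full pipeline: identify the majority-agreeing trees T+ and their
#' decision paths for the explanandum, redistribute the classifier weights
#' onto individual decision nodes by sequential relative entropy, keep the
#' heaviest nodes, greedily merge them into a single conjunctive rule
#' maximising stability, optionally prune non-counterfactual terms, and
#' attach the counterfactual contrast set. The rule's consequent is the
#' model's own prediction, so fidelity is perfect by construction.
#'
#' @param model a trained `whips_model`.
#' @param x the explanandum instance (numeric vector).
#' @param X_train training feature matrix (evaluation data for the
#'   objective).
#' @param y_train training labels (ground truth), used for the
#'   relative-entropy node scores.
#' @param top_fraction fraction of snippets kept before merging (default
#'   0.2).
#' @param stability_threshold greedy-merge stopping threshold (default
#'   0.95).
#' @param prune prune non-counterfactual terms? (default TRUE).
#' @param tolerance pruning tolerance on the precision drop (default 0.05).
#' @param use_model_labels score node entropies against model predictions
#'   instead of ground-truth labels (default FALSE).
#' @param train_pred optional precomputed `predict(model, X_train)`; pass
#'   it when explaining many instances to avoid rescoring the ensemble.
#' @return object of class `whips_explanation`: `decision`, `rule`,
#'   `contrast`, `confidence` (coverage / precision / prior of the
#'   predicted class), `margin` and `provenance`.
#' @export
whips_explain <- function(model, x, X_train, y_train,
                          top_fraction = 0.2, stability_threshold = 0.95,
                          prune = TRUE, tolerance = 0.05,
                          use_model_labels = FALSE, train_pred = NULL) {
  x <- as.numeric(x)
  X_train <- as.matrix(X_train)
  K <- length(model$class_labels)
  if (is.null(train_pred)) {
    train_pred <- predict(model, X_train, type = "class")
  }

  md <- majority_trees(model, x)
  consequent <- md$predicted_class

  score_y <- if (use_model_labels) {
    match(train_pred, model$class_labels)
  } else {
    match(as.character(y_train), model$class_labels)
  }
  score_list <- lapply(md$majority_paths, function(p) {
    normalize_to_weight(
      path_node_scores(p, X_train, score_y, model$prior),
      p$path_weight
    )
  })
  snippets <- aggregate_snippets(md$majority_paths, score_list)
  snippets <- filter_and_sort(snippets, top_fraction)

  rule <- greedy_merge(snippets, x, consequent, X_train, train_pred, K,
                       stability_threshold = stability_threshold,
                       feature_names = model$feature_names)
  if (prune) {
    rule <- prune_redundant(rule, X_train, train_pred,
                            tolerance = tolerance, K = K)
  }
  rule$stats$prior <- model$prior[match(consequent, model$class_labels)]
  contrast <- contrast_set(rule, X_train, train_pred)

  structure(
    list(
      decision = consequent,
      rule = rule,
      contrast = contrast,
      confidence = list(
        coverage = rule$stats$coverage,
        precision = rule$stats$precision,
        prior = rule$stats$prior
      ),
      margin = md$margin,
      snippets = snippets,
      provenance = list(
        algorithm = model$algorithm, ntrees = length(model$trees),
        seed = model$seed, timestamp = format(Sys.time(), tz = "UTC")
      )
    ),
    class = "whips_explanation"
  )
}

#' @export
print.whips_explanation <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' @export
format.whips_explanation <- function(x, ...) {
  pct <- function(v) sprintf("%.1f%%", 100 * v)
  lines <- c(
    sprintf("Decision: %s", x$decision),
    "Explanation:",
    paste0("  ", format_rule(x$rule)),
    "Contrast:"
  )
  for (i in seq_len(nrow(x$contrast))) {
    lines <- c(lines, sprintf(
      "  %s %s %s  →  %+.1f%%",
      x$contrast$feature_name[i], x$contrast$reversed_op[i],
      signif(x$contrast$threshold[i], 4), 100 * x$contrast$delta[i]
    ))
  }
  c(lines,
    "Confidence:",
    sprintf("  Coverage: %s  Precision: %s  Prior: %s",
            pct(x$confidence$coverage), pct(x$confidence$precision),
            pct(x$confidence$prior)))
}
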