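# ---------------------------------------------------------------------------
# Dataset ingestion (CSV with integer-encoding of nominal columns), model
# serialisation to JSON, and explanation output in JSON and plain text.
# ---------------------------------------------------------------------------

#' Read a CSV dataset, encoding nominal columns
#'
#' Reads a headed CSV, splits off the label column, rejects missing values
#' (naming the offending rows) and integer-encodes any non-numeric feature
#' column with stable sorted-category codes (0, 1, 2, ... in lexicographic
#' category order). The code book is retained so rule terms can be rendered
#' in the original category language.
#'
#' @param path CSV file path (header row, comma separator, UTF-8).
#' @param label_column name of the label column.
#' @return list of class `whips_dataset`: `X` (numeric matrix), `y`
#'   (character labels), `feature_names`, `class_names`, `encoding` (named
#'   list of category vectors for encoded columns).
#' @export
read_dataset <- function(path, label_column) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!label_column %in% names(df)) {
    stop("label column '", label_column, "' not found in ", path)
  }
  bad <- which(rowSums(is.na(df) | df == "") > 0)
  if (length(bad) > 0) {
    stop("missing values in row(s): ",
         paste(utils::head(bad, 10L), collapse = ", "))
  }
  y <- as.character(df[[label_column]])
  feats <- df[setdiff(names(df), label_column)]
  encoding <- list()
  for (nm in names(feats)) {
    col <- feats[[nm]]
    if (!is.numeric(col)) {
      cats <- sort(unique(as.character(col)))
      encoding[[nm]] <- cats
      feats[[nm]] <- match(as.character(col), cats) - 1L
    }
  }
  X <- as.matrix(feats)
  if (!is.numeric(X)) stop("unparseable cells remain after encoding")
  structure(
    list(X = X, y = y, feature_names = colnames(X),
         class_names = sort(unique(y)), encoding = encoding),
    class = "whips_dataset"
  )
}

#' Write a dataset back to CSV
#'
#' @param data a `whips_dataset` or a list with `X` and `y`.
#' @param path output path.
#' @param label_column name for the label column (default `"label"`).
#' @export
write_dataset <- function(data, path, label_column = "label") {
  df <- as.data.frame(data$X)
  df[[label_column]] <- data$y
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# flatten one tree to the JSON node-table shape
tree_to_json_list <- function(tree) {
  ids <- seq_along(tree$feature)
  list(
    alpha = tree$alpha,
    iteration = tree$iteration,
    nodes = lapply(ids, function(i) {
      list(
        id = i,
        feature = if (is.na(tree$feature[i])) NULL else tree$feature[i],
        threshold = if (is.na(tree$threshold[i])) NULL else tree$threshold[i],
        left = if (is.na(tree$left[i])) NULL else tree$left[i],
        right = if (is.na(tree$right[i])) NULL else tree$right[i],
        depth = tree$depth[i],
        posterior = as.numeric(tree$posterior[i, ]),
        weight_mass = tree$weight_mass[i]
      )
    })
  )
}

json_list_to_tree <- function(lst, K) {
  nodes <- lst$nodes
  n <- length(nodes)
  get <- function(field, cast, na) {
    vapply(nodes, function(nd) {
      if (is.null(nd[[field]])) na else cast(nd[[field]])
    }, na)
  }
  structure(
    list(
      feature = get("feature", as.integer, NA_integer_),
      threshold = get("threshold", as.numeric, NA_real_),
      left = get("left", as.integer, NA_integer_),
      right = get("right", as.integer, NA_integer_),
      depth = get("depth", as.integer, NA_integer_),
      posterior = do.call(rbind, lapply(nodes, function(nd) {
        as.numeric(nd$posterior)
      })),
      weight_mass = get("weight_mass", as.numeric, NA_real_),
      alpha = if (is.null(lst$alpha)) NA_real_ else as.numeric(lst$alpha),
      iteration = if (is.null(lst$iteration)) NA_integer_
                  else as.integer(lst$iteration),
      n_classes = K
    ),
    class = "whips_tree"
  )
}

#' Save a boosted model as JSON
#'
#' Probabilities and thresholds are serialised at full double precision, so
#' a round-tripped model predicts identically.
#'
#' @param model a `whips_model`.
#' @param path output path.
#' @export
save_model <- function(model, path) {
  doc <- list(
    algorithm = model$algorithm,
    class_labels = model$class_labels,
    prior = model$prior,
    feature_names = model$feature_names,
    maxdepth = model$maxdepth,
    seed = model$seed,
    trees = lapply(model$trees, tree_to_json_list)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load a boosted model from JSON
#'
#' @param path path written by [save_model()].
#' @return a `whips_model`.
#' @export
load_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  K <- length(doc$class_labels)
  structure(
    list(
      algorithm = doc$algorithm,
      trees = lapply(doc$trees, json_list_to_tree, K = K),
      class_labels = vapply(doc$class_labels, as.character, ""),
      prior = vapply(doc$prior, as.numeric, 0),
      feature_names = vapply(doc$feature_names, as.character, ""),
      maxdepth = as.integer(doc$maxdepth),
      seed = if (is.null(doc$seed)) NULL else as.integer(doc$seed)
    ),
    class = "whips_model"
  )
}

# explanation as a plain list ready for JSON
explanation_to_list <- function(expl) {
  list(
    decision = expl$decision,
    rule = lapply(seq_len(nrow(expl$rule$terms)), function(i) {
      list(feature = expl$rule$terms$feature[i],
           feature_name = expl$rule$terms$feature_name[i],
           op = expl$rule$terms$op[i],
           threshold = expl$rule$terms$threshold[i])
    }),
    contrast = lapply(seq_len(nrow(expl$contrast)), function(i) {
      list(feature_name = expl$contrast$feature_name[i],
           reversed_op = expl$contrast$reversed_op[i],
           threshold = expl$contrast$threshold[i],
           delta_pct = 100 * expl$contrast$delta[i])
    }),
    confidence = list(
      coverage_pct = 100 * expl$confidence$coverage,
      precision_pct = 100 * expl$confidence$precision,
      prior_pct = 100 * expl$confidence$prior
    ),
    provenance = expl$provenance
  )
}

#' Write an explanation to disk
#'
#' `format = "json"` writes the structured document (rule terms, contrast
#' deltas in signed percentage points, confidence block, provenance);
#' `format = "text"` writes the human-readable report: Decision /
#' Explanation / Contrast / Confidence.
#'
#' @param explanation a `whips_explanation`.
#' @param path output path.
#' @param format `"json"` or `"text"`.
#' @export
write_explanation <- function(explanation, path, format = c("json", "text")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(explanation_to_list(explanation), path,
                         auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    writeLines(format(explanation), path)
  }
  invisible(path)
}

#' Structural validation of an explanation JSON document
#'
#' Checks a written explanation against the field schema shipped in
#' `inst/extdata/explanation-schema.json`: required top-level fields,
#' rule-term fields, contrast fields and the confidence block.
#'
#' @param path an explanation JSON file.
#' @return TRUE invisibly; stops with a message on the first violation.
#' @export
validate_explanation <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  schema <- jsonlite::read_json(
    system.file("extdata", "explanation-schema.json", package = "adawhips"),
    simplifyVector = FALSE
  )
  for (f in names(schema$required)) {
    if (is.null(doc[[f]])) stop("missing required field: ", f)
  }
  for (term in doc$rule) {
    for (f in schema$rule_term_fields) {
      if (is.null(term[[f]])) stop("rule term missing field: ", f)
    }
    if (!term$op %in% c("<=", ">")) stop("invalid operator: ", term$op)
  }
  for (item in doc$contrast) {
    for (f in schema$contrast_fields) {
      if (is.null(item[[f]])) stop("contrast item missing field: ", f)
    }
  }
  for (f in schema$confidence_fields) {
    if (is.null(doc$confidence[[f]])) stop("confidence missing field: ", f)
  }
  invisible(TRUE)
}
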