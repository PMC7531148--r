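# Shared fixtures, built in code and memoised for the duration of a test run.

.fixture_cache <- new.env(parent = emptyenv())

with_cache <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# hand-built tree: parallel node vectors, NA marks leaf fields
make_tree <- function(feature, threshold, left, right, posterior,
                      alpha = 1, iteration = 1L, weight_mass = NULL) {
  n <- length(feature)
  if (is.null(weight_mass)) weight_mass <- rep(1, n)
  depth <- integer(n)
  for (i in seq_len(n)) {
    if (!is.na(left[i])) {
      depth[left[i]] <- depth[i] + 1L
      depth[right[i]] <- depth[i] + 1L
    }
  }
  structure(
    list(feature = as.integer(feature), threshold = as.numeric(threshold),
         left = as.integer(left), right = as.integer(right), depth = depth,
         posterior = posterior, weight_mass = weight_mass,
         alpha = alpha, iteration = as.integer(iteration),
         n_classes = ncol(posterior)),
    class = "whips_tree"
  )
}

# single-leaf tree voting for (SAMME) / returning (SAMME.R) `posterior`
make_leaf_tree <- function(posterior, alpha = 1, iteration = 1L) {
  make_tree(NA, NA, NA, NA, matrix(posterior, nrow = 1L),
            alpha = alpha, iteration = iteration)
}

make_model <- function(trees, class_labels = c("A", "B"),
                       prior = NULL, n_features = 2L,
                       algorithm = "SAMME") {
  K <- length(class_labels)
  if (is.null(prior)) prior <- rep(1 / K, K)
  trees <- lapply(seq_along(trees), function(m) {
    tr <- trees[[m]]
    tr$iteration <- m
    tr
  })
  structure(
    list(algorithm = algorithm, trees = trees, class_labels = class_labels,
         prior = prior, feature_names = paste0("x", seq_len(n_features)),
         maxdepth = 4L, seed = NULL),
    class = "whips_model"
  )
}

# small separable Gaussian mixture + SAMME model, for fast pipeline tests
fix_gaussian <- function() {
  with_cache("gaussian", {
    gm <- gaussian_mixture(500, seed = 42)
    model <- ada_boost(gm$X, gm$y, "SAMME", ntrees = 25, maxdepth = 3,
                       seed = 7)
    list(data = gm, model = model,
         train_pred = predict(model, gm$X, type = "class"))
  })
}

fix_gaussian_samme_r <- function() {
  with_cache("gaussian_samme_r", {
    gm <- fix_gaussian()$data
    model <- ada_boost(gm$X, gm$y, "SAMME.R", ntrees = 25, maxdepth = 3,
                       seed = 7)
    list(data = gm, model = model,
         train_pred = predict(model, gm$X, type = "class"))
  })
}

default_planted_spec <- function(noise_rate = 0.05, n_rows = 600L) {
  planted_rule_spec(
    terms = data.frame(feature = c(1L, 2L), op = c("<=", ">"),
                       threshold = c(0.6, 0.4)),
    noise_rate = noise_rate, n_rows = n_rows, n_features = 5L
  )
}

# small planted-rule dataset + model, for rule-recovery tests
fix_planted_small <- function() {
  with_cache("planted_small", {
    d <- planted_rule_dataset(default_planted_spec(), seed = 5)
    model <- ada_boost(d$X, d$y, "SAMME", ntrees = 60, maxdepth = 4,
                       seed = 5)
    list(data = d, model = model,
         train_pred = predict(model, d$X, type = "class"))
  })
}

# independent elementwise KL oracle: floor, renormalise, loop over entries
kl_oracle <- function(p, q, floor = 1e-12) {
  p <- pmax(p, floor); p <- p / sum(p)
  q <- pmax(q, floor); q <- q / sum(q)
  acc <- 0
  for (i in seq_along(p)) acc <- acc + p[i] * log(p[i] / q[i])
  acc
}

random_distribution <- function(K) {
  v <- stats::runif(K)
  v / sum(v)
}
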