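test_that("fit_tree finds the exact midpoint split on separable 1-D data", {
  X <- matrix(c(1, 2, 3, 4), ncol = 1)
  y <- c(1L, 1L, 2L, 2L)
  tree <- fit_tree(X, y, maxdepth = 1L, n_classes = 2L)
  expect_equal(tree$feature[1L], 1L)
  expect_equal(tree$threshold[1L], 2.5)
  left <- tree$left[1L]; right <- tree$right[1L]
  expect_equal(as.numeric(tree$posterior[left, ]), c(1, 0))
  expect_equal(as.numeric(tree$posterior[right, ]), c(0, 1))
})

test_that("fit_tree on one-class data yields a single one-hot leaf", {
  X <- matrix(rnorm(20), ncol = 2)
  tree <- fit_tree(X, rep(2L, 10), maxdepth = 3L, n_classes = 3L)
  expect_equal(length(tree$feature), 1L)
  expect_equal(as.numeric(tree$posterior[1L, ]), c(0, 1, 0))
})

test_that("fit_tree handles degenerate inputs per contract", {
  expect_error(fit_tree(matrix(0, 0, 2), integer(0)), "no training data")
  # all-identical rows: degenerate single leaf, not an error
  X <- matrix(1, 6, 2)
  tree <- fit_tree(X, rep(c(1L, 2L), 3), maxdepth = 2L, n_classes = 2L)
  expect_equal(length(tree$feature), 1L)
  expect_true(is.na(tree$feature[1L]))
})

test_that("XOR needs two levels: depth 2 is exact, depth 1 is chance", {
  X <- matrix(c(0, 0, 1, 1, 0, 1, 0, 1), ncol = 2)
  y <- c(1L, 2L, 2L, 1L)
  err <- function(maxdepth) {
    tree <- fit_tree(X, y, maxdepth = maxdepth, n_classes = 2L)
    pred <- apply(X, 1L, function(r) which.max(tree_output(tree, r, "SAMME")))
    mean(pred != y)
  }
  expect_equal(err(2L), 0)
  expect_equal(err(1L), 0.5)
})

test_that("SAMME classifier weight matches its closed form", {
  expect_equal(adawhips:::samme_alpha(0.5, 2), 0)
  expect_equal(adawhips:::samme_alpha(0.25, 2), log(3))
  expect_equal(adawhips:::samme_alpha(0.6, 3), log(4 / 3))
})

test_that("SAMME.R confidence weights are the centred scaled log-posteriors", {
  expect_equal(adawhips:::samme_r_confidence(c(0.5, 0.5)), c(0, 0))
  a <- adawhips:::samme_r_confidence(c(0.75, 0.25))
  expect_equal(a, c(0.5 * log(3), -0.5 * log(3)))
  # always centred: sums to zero, including at floored posteriors
  for (post in list(c(0.9, 0.1), c(1, 0), c(0.2, 0.3, 0.5))) {
    expect_equal(sum(adawhips:::samme_r_confidence(post)), 0, tolerance = 1e-9)
  }
})

test_that("tree_output is a one-hot vote under SAMME, posterior under SAMME.R", {
  tree <- make_leaf_tree(c(0.9, 0.1))
  expect_equal(tree_output(tree, c(0, 0), "SAMME"), c(1, 0))
  expect_equal(tree_output(tree, c(0, 0), "SAMME.R"), c(0.9, 0.1))
})

test_that("tree_output follows the split conditions down to a single leaf", {
  # two-level tree: root on feature 1 (<= 1.0), left child on feature 2
  tree <- make_tree(
    feature = c(1L, 2L, NA, NA, NA),
    threshold = c(1.0, 5.0, NA, NA, NA),
    left = c(2L, 4L, NA, NA, NA),
    right = c(3L, 5L, NA, NA, NA),
    posterior = rbind(c(.5, .5), c(.5, .5), c(0, 1), c(1, 0), c(.2, .8))
  )
  # x = (0.1, 10): root true -> node 2; 10 > 5 -> node 5; the unreachable
  # right branch of the root never influences the output
  expect_equal(tree_output(tree, c(0.1, 10), "SAMME.R"), c(0.2, 0.8))
  expect_equal(tree_output(tree, c(0.1, 10), "SAMME"), c(0, 1))
})

test_that("predict sums weighted votes and breaks ties to the lowest class", {
  m <- make_model(list(
    make_leaf_tree(c(1, 0), alpha = 2),
    make_leaf_tree(c(0, 1), alpha = 1)
  ))
  expect_equal(predict(m, c(0, 0)), "A")
  m3 <- make_model(list(
    make_leaf_tree(c(1, 0), alpha = 1),
    make_leaf_tree(c(1, 0), alpha = 1),
    make_leaf_tree(c(0, 1), alpha = 1)
  ))
  out <- predict(m3, c(0, 0), type = "full")
  expect_equal(out$predicted_class, "A")
  expect_equal(as.numeric(out$class_scores), c(2, 1))
  # exact tie: lowest class index wins
  tie <- make_model(list(
    make_leaf_tree(c(0, 1), alpha = 1),
    make_leaf_tree(c(1, 0), alpha = 1)
  ))
  expect_equal(predict(tie, c(0, 0)), "A")
  expect_error(predict(m, matrix(0, 1, 5)), "dimensionality mismatch")
})

test_that("single-tree ensemble predicts that tree's class", {
  m <- make_model(list(make_leaf_tree(c(0.2, 0.8), alpha = 0.7)))
  expect_equal(predict(m, c(1, 1)), "B")
})

test_that("training rejects degenerate labels and empty data", {
  X <- matrix(rnorm(10), ncol = 1)
  expect_error(ada_boost(X, rep("A", 10)), "degenerate labels")
  expect_error(ada_boost(matrix(0, 0, 2), character(0)), "no training data")
})

test_that("tree outputs are normalised and SAMME alphas positive on real fits", {
  fx <- fix_gaussian()
  m <- fx$model
  set.seed(31)
  Xr <- matrix(rnorm(40), ncol = 2)
  for (tree in m$trees[seq_len(5)]) {
    expect_gt(tree$alpha, 0) # err < 1 - 1/K on learnable data
    for (i in seq_len(nrow(Xr))) {
      expect_equal(sum(tree_output(tree, Xr[i, ], "SAMME")), 1)
      expect_equal(sum(tree_output(tree, Xr[i, ], "SAMME.R")), 1,
                   tolerance = 1e-9)
    }
  }
})

test_that("SAMME.R per-tree confidence vectors sum to zero over classes", {
  fx <- fix_gaussian_samme_r()
  out <- predict(fx$model, fx$data$X[1, ], type = "full")
  expect_true(length(out$per_tree_confidences) >= 1L)
  for (conf in out$per_tree_confidences) {
    expect_equal(sum(conf), 0, tolerance = 1e-9)
  }
})

test_that("boosting beats a single depth-limited tree on separable data", {
  gm <- gaussian_mixture(400, means = list(c(0, 0), c(3, 3)), seed = 9)
  single <- fit_tree(gm$X, match(gm$y, sort(unique(gm$y))), maxdepth = 1L,
                     n_classes = 2L)
  pred1 <- apply(gm$X, 1L, function(r) {
    sort(unique(gm$y))[which.max(tree_output(single, r, "SAMME"))]
  })
  model <- ada_boost(gm$X, gm$y, "SAMME", ntrees = 20, maxdepth = 1, seed = 2)
  acc_boost <- mean(predict(model, gm$X) == gm$y)
  expect_gte(acc_boost, mean(pred1 == gm$y))
})

test_that("training is deterministic: identical inputs, identical serialisation", {
  gm <- gaussian_mixture(200, seed = 8)
  m1 <- ada_boost(gm$X, gm$y, "SAMME", ntrees = 10, maxdepth = 3, seed = 3)
  m2 <- ada_boost(gm$X, gm$y, "SAMME", ntrees = 10, maxdepth = 3, seed = 3)
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  save_model(m1, f1); save_model(m2, f2)
  expect_identical(readLines(f1), readLines(f2))
})
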