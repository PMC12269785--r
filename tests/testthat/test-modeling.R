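test_that("a constant response yields constant predictions with zero-width PIs", {
  m <- tiny_matrix(120, seed = 1)
  m$response <- 2
  m$socd <- expm1(2)
  fit <- fit_joint_forest(m, list(n_trees = 20), seed = 1)
  pp <- predict_point(fit, m[1:10, ])
  expect_true(all(abs(pp$mean - expm1(2)) < 1e-12))
  expect_true(all(pp$piw == 0))
})

test_that("fitting and prediction are deterministic under seed", {
  m <- tiny_matrix(200, seed = 4)
  f1 <- fit_joint_forest(m, list(n_trees = 30), seed = 5)
  f2 <- fit_joint_forest(m, list(n_trees = 30), seed = 5)
  q <- m[1:20, ]
  expect_identical(predict_point(f1, q), predict_point(f2, q))
})

test_that("non-finite responses and short matrices are rejected", {
  m <- tiny_matrix(60, seed = 1)
  m$response[1] <- NA
  expect_error(fit_joint_forest(m), "non-finite")
  expect_error(fit_joint_forest(tiny_matrix(30)), "50")
})

test_that("the well-specified scenario is predicted with skill", {
  fx <- coverage_fit()
  pp <- predict_point(fx$fit, fx$test)
  pm <- point_metrics(fx$test$socd, pp$mean)
  expect_gt(pm$r2, 0.45)
  expect_gt(pm$ccc, 0.55)
})

test_that("pooled quantiles equal a brute-force sort of the leaf multisets", {
  tf <- tiny_fit()
  probs <- c(0.025, 0.25, 0.5, 0.975)
  pp <- predict_point(tf$fit, tf$matrix[1:15, ], probs = probs)
  for (i in 1:15) {
    pooled <- pooled_leaf_values(tf$fit, tf$matrix[i, , drop = FALSE])
    expect_equal(as.numeric(pp[i, c("p025", "p25", "p5", "p975")]),
                 expm1(quantile_bruteforce(pooled, probs)))
  }
  # mean equals the average over trees of leaf means
  pos <- socforest:::query_leaves(tf$fit, tf$matrix[1:15, ])
  M <- socforest:::leaf_mean_matrix(tf$fit, pos)
  expect_equal(pp$mean, expm1(rowMeans(M)))
})

test_that("interval bounds are ordered and probs validated", {
  tf <- tiny_fit()
  for (mode in c("leaf_pooled", "tree_ensemble")) {
    pp <- predict_point(tf$fit, tf$matrix[1:30, ], mode = mode)
    expect_true(all(pp$p025 <= pp$p975))
    expect_true(all(pp$p025 >= -1))
  }
  expect_error(predict_point(tf$fit, tf$matrix[1, ], probs = c(0, 0.5)),
               "probs")
  expect_error(predict_point(tf$fit, tf$matrix[1, c("x1", "socd")]),
               "missing feature")
})

test_that("block prediction reduces to the tree-ensemble point prediction", {
  tf <- tiny_fit()
  x <- tf$matrix[3, , drop = FALSE]
  pt <- predict_point(tf$fit, x, mode = "tree_ensemble")
  b1 <- predict_block(tf$fit, x)                       # single node
  expect_equal(b1$mean, pt$mean)
  expect_equal(b1$p025, pt$p025)
  expect_equal(b1$p975, pt$p975)
  # N identical nodes: same ensemble, same prediction
  b4 <- predict_block(tf$fit, x[rep(1, 4), ],
                      block = block_spec(2000:2003, 10, expand = FALSE))
  expect_equal(b4$mean, pt$mean)
  expect_equal(b4$p975, pt$p975)
  # node count validation
  expect_error(predict_block(tf$fit, x[rep(1, 3), ],
                             block = block_spec(2000:2003, 10,
                                                expand = FALSE)),
               "one row per block node")
})

test_that("batched block prediction equals per-block calls", {
  tf <- tiny_fit()
  X <- tf$matrix[1:12, ]
  batch <- predict_block_batch(tf$fit, X, n_nodes = 4)
  for (b in 1:3) {
    single <- predict_block(tf$fit, X[(4 * b - 3):(4 * b), ])
    expect_equal(batch[b, ], single, ignore_attr = TRUE)
  }
  expect_error(predict_block_batch(tf$fit, X[1:10, ], n_nodes = 4),
               "multiple")
})

test_that("ensemble spread of block means shrinks like 1/sqrt(N)", {
  sc <- make_benchmark_scenarios("blocks", seed = 7)
  st <- make_feature_fields(sc)
  tr <- make_truth(st, sc)
  pts <- sample_points(st, tr, 2000, sc)
  m <- spacetime_overlay(pts, st)
  fit <- fit_joint_forest(m, seed = 1)
  set.seed(99)
  g <- st$grid
  qx <- runif(60, g$xmin, g$xmax)
  qy <- runif(60, g$ymin, g$ymax)
  ratios <- vapply(seq_along(qx), function(i) {
    rows <- lapply(sc$years, function(y) {
      ix <- socforest:::cell_index(g, qx[i], qy[i])
      dl <- st$dynamic[[as.character(y)]]
      as.data.frame(c(list(depth = 10),
                      lapply(st$static, function(mm) mm[ix$row, ix$col]),
                      lapply(dl, function(mm) mm[ix$row, ix$col])))
    })
    X4 <- do.call(rbind, rows)
    M4 <- socforest:::leaf_mean_matrix(fit, socforest:::query_leaves(fit, X4))
    c(sd(colMeans(M4)), sd(M4[1, ]))
  }, numeric(2))
  ratio <- mean(ratios[1, ]) / mean(ratios[2, ])
  expect_gt(ratio, 0.4)
  expect_lt(ratio, 0.6)
})

test_that("cumulative importance sorts, normalizes and validates", {
  ci <- cumulative_importance(c(a = 0.5, b = 0.3, c = 0.2))
  expect_equal(ci$cfi, c(0.5, 0.8, 1.0))
  expect_equal(ci$feature, c("a", "b", "c"))
  eq <- cumulative_importance(c(w = 1, x = 1, y = 1, z = 1))
  expect_equal(eq$cfi, (1:4) / 4)
  # permutation invariance of the ordered output
  p1 <- cumulative_importance(c(b = 0.3, c = 0.2, a = 0.5))
  expect_equal(p1, ci)
  expect_error(cumulative_importance(c(a = -0.1, b = 1)), "negative")
  expect_error(cumulative_importance(c(a = 0, b = 0)), "zero")
})

test_that("successive-halving tuning returns a sound winner", {
  m <- tiny_matrix(250, seed = 6)
  one <- list(splitrule = "variance", max_depth = 10, mtry_frac = "0.5",
              min_node_size = 2)
  got <- tune_hyperparameters(m, lapply(one, function(v) v), folds = 3,
                              seed = 1)
  expect_equal(got$best$max_depth, 10)
  expect_equal(got$best$min_node_size, 2)
  expect_error(tune_hyperparameters(m, list()), "empty")
  # small search: winner's CV CCC is the max of the final candidates
  space <- list(splitrule = "variance", max_depth = c(10, 30),
                mtry_frac = c("0.5", "sqrt"), min_node_size = c(1, 4))
  res <- tune_hyperparameters(m, space, folds = 3, n_candidates = 6,
                              seed = 2)
  expect_gte(res$best_ccc, stats::median(res$results$cv_ccc))
  res2 <- tune_hyperparameters(m, space, folds = 3, n_candidates = 6,
                               seed = 2)
  expect_identical(res$best, res2$best)
})

test_that("RSCFI validates inputs and never grows the feature set", {
  m <- tiny_matrix(200, seed = 7)
  expect_error(rscfi_select(m, cfi_threshold = 1.5), "threshold")
  sel <- rscfi_select(m, cfi_threshold = 1, repeats = 2, folds = 3, seed = 1,
                      n_trees = 30)
  # threshold 1 drops nothing: a single iteration over the full set
  expect_equal(nrow(sel$trace), 1)
  expect_setequal(sel$selected, c("x1", "x2"))
  sel2 <- rscfi_select(m, cfi_threshold = 1, repeats = 2, folds = 3,
                       seed = 1, n_trees = 30)
  expect_identical(sel$trace, sel2$trace)
})

test_that("RSCFI recovers informative features on the selection scenario", {
  sc <- make_benchmark_scenarios("selection", seed = 1)
  st <- make_feature_fields(sc)
  tr <- make_truth(st, sc)
  pts <- sample_points(st, tr, 1200, sc)
  m <- spacetime_overlay(pts, st)
  sel <- rscfi_select(m, cfi_threshold = 0.90, seed = 1)
  expect_gte(sum(tr$informative %in% sel$selected), 4)
  noise <- setdiff(attr(m, "features"), c(tr$informative, "depth"))
  expect_lte(sum(sel$selected %in% noise), 4)
  # monotone shrinkage of the candidate set
  expect_true(all(diff(sel$trace$n_features) <= 0))
})
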