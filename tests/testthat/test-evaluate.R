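test_that("point metrics behave at identity, shift, and validate input", {
  obs <- c(5, 8, 13, 21, 34, 2, 7)
  id <- point_metrics(obs, obs)
  expect_equal(id$r2, 1)
  expect_equal(id$ccc, 1)
  expect_equal(id$mae, 0)
  expect_equal(id$bias, 0)
  # constant shift: bias = c, CCC drops below 1 per Lin's closed form
  sh <- point_metrics(obs, obs + 3)
  expect_equal(sh$bias, 3)
  vx <- mean((obs - mean(obs))^2)
  expect_equal(sh$ccc, 2 * vx / (2 * vx + 9))
  expect_lt(sh$ccc, 1)
  # |CCC| <= |pearson r|
  set.seed(1)
  pred <- obs * 1.4 + rnorm(7)
  pm <- point_metrics(obs, pred)
  expect_lte(abs(pm$ccc), abs(cor(obs, pred)))
  expect_error(point_metrics(rep(1, 5), 1:5), "variance")
  expect_error(point_metrics(1:4, 1:3), "mismatch")
  # permutation invariance
  o <- c(3, 1, 4, 1, 5); p <- c(2, 7, 1, 8, 2)
  i <- c(4, 2, 5, 1, 3)
  expect_equal(point_metrics(o, p)$ccc, point_metrics(o[i], p[i])$ccc)
})

test_that("ISIW weights are inverse cell counts normalized to mean one", {
  # 10 points in one 25 km cell, 1 in another
  xy <- rbind(cbind(runif(10, 0, 1000), runif(10, 0, 1000)),
              c(50000, 50000))
  w <- isiw_weights(xy)
  expect_equal(mean(w), 1)
  expect_equal(w[11] / w[1], 10)
  # uniform points, one per cell: all weights 1
  u <- cbind(seq(0, 9) * 25000 + 10, 10)
  expect_equal(isiw_weights(u), rep(1, 10))
  expect_error(isiw_weights(u[1, , drop = FALSE]), "2 points")
})

test_that("cross-validation schemes partition correctly", {
  m <- tiny_matrix(240, seed = 9)
  cv <- cross_validate(m, "loyo", hyperparameters = list(n_trees = 30),
                       seed = 1)
  expect_equal(length(cv$per_fold), length(unique(m$year)))
  for (f in sort(unique(cv$fold))) {
    expect_equal(length(unique(m$year[cv$fold == f])), 1)
  }
  m1 <- m; m1$year <- 2000L
  expect_error(cross_validate(m1, "loyo"), "2 distinct years")
  cvk <- cross_validate(m, "isiw_kfold", k = 4,
                        hyperparameters = list(n_trees = 30), seed = 2)
  expect_equal(sort(unique(cvk$fold)), 1:4)
  expect_true(is.finite(cvk$overall$ccc))
  # deterministic under seed
  cvk2 <- cross_validate(m, "isiw_kfold", k = 4,
                         hyperparameters = list(n_trees = 30), seed = 2)
  expect_equal(cvk$overall, cvk2$overall)
})

test_that("interval metrics and QCP equal brute-force counting", {
  obs <- c(1, 2, 3, 4)
  im <- interval_metrics(obs, p025 = c(0.5, 1.5, 3.5, 4.5),
                         p975 = c(1.5, 2.5, 3.9, 4.9))
  expect_equal(im$picp, 0.5)   # obs 1 and 2 covered, 3 and 4 not
  expect_equal(im$piw, (1 + 1 + 0.4 + 0.4) / 4)
  expect_equal(interval_metrics(obs, obs, obs)$piw, 0)
  expect_equal(interval_metrics(obs, obs - 1, obs + 1)$picp, 1)
  expect_error(interval_metrics(obs, c(2, 2, 2, 2), c(1, 3, 3, 3)), "p025")
  expect_error(interval_metrics(obs, 1:3, 1:3), "mismatch")
  # randomized oracle equivalence
  set.seed(3)
  for (rep in 1:5) {
    o <- rnorm(50); lo <- o - runif(50); hi <- o + runif(50) - 0.3
    lo2 <- pmin(lo, hi); hi2 <- pmax(lo, hi)
    im <- interval_metrics(o, lo2, hi2)
    cover <- 0
    for (i in 1:50) if (o[i] >= lo2[i] && o[i] <= hi2[i]) cover <- cover + 1
    expect_equal(im$picp, cover / 50)
    expect_equal(qcp(o, hi2, 0.975), sum(o <= hi2) / 50)
  }
  expect_equal(qcp(obs, rep(Inf, 4), 0.5), 1)
  expect_equal(qcp(obs, rep(-Inf, 4), 0.5), 0)
  expect_error(qcp(obs, obs, 1.2), "p must")
})

test_that("accuracy curve is consistent, monotone and near-diagonal for an oracle", {
  set.seed(7)
  obs <- rnorm(4000)
  qf <- function(p) rep(qnorm(p), length(obs))  # perfect oracle quantiles
  ac <- accuracy_curve(obs, qf)
  expect_true(all(diff(ac$observed) >= 0))
  expect_lt(max(abs(ac$observed - ac$level)), 0.03)
  # level 0.95 reproduces interval_metrics picp for the same bounds
  im <- interval_metrics(obs, qf(0.025), qf(0.975))
  expect_equal(ac$observed[ac$level == 0.95], im$picp)
})

test_that("strata reporting suppresses tiny strata and conserves counts", {
  set.seed(5)
  n <- 60
  obs <- runif(n, 1, 50); pred <- obs + rnorm(n)
  lo <- pred - 5; hi <- pred + 5
  lc <- c(rep("cropland", 40), rep("woodland", 16), rep("shrubland", 4))
  di <- rep("0-20", n)
  rep_ <- strata_report(obs, pred, lo, hi, lc, di)
  expect_equal(sum(rep_$n), n)
  expect_true(is.na(rep_$r2[rep_$land_cover == "shrubland"]))  # n = 4 < 5
  expect_false(anyNA(rep_$ccc[rep_$land_cover == "cropland"]))
  # a single stratum reproduces the global metrics
  solo <- strata_report(obs, pred, lo, hi, rep("cropland", n), di)
  pm <- point_metrics(obs, pred)
  expect_equal(solo$ccc, pm$ccc)
  expect_equal(solo$picp, interval_metrics(obs, lo, hi)$picp)
})

test_that("Shapley contributions satisfy efficiency and match exact enumeration", {
  tf <- tiny_fit()
  x <- tf$matrix[5, , drop = FALSE]
  bg <- tf$matrix[21:40, ]
  ex <- shapley_contributions(tf$fit, x, bg, mode = "exact")
  expect_equal(sum(ex$contributions), ex$prediction - ex$baseline,
               tolerance = 1e-10)
  mc <- shapley_contributions(tf$fit, x, bg, n_perm = 2000, seed = 2)
  expect_equal(sum(mc$contributions), mc$prediction - mc$baseline,
               tolerance = 1e-8)
  expect_lt(max(abs(mc$contributions - ex$contributions)), 0.05)
})

test_that("exact Shapley is refused beyond 10 features", {
  fx <- coverage_fit()
  m11 <- fx$train[1:100, ]
  wide <- cbind(m11, matrix(rnorm(100 * 8), ncol = 8,
                            dimnames = list(NULL, paste0("pad", 1:8))))
  attr(wide, "features") <- c(attr(fx$train, "features"),
                              paste0("pad", 1:8))
  fit <- fit_joint_forest(wide, list(n_trees = 20), seed = 1)
  expect_error(shapley_contributions(fit, wide[1, ], wide[1:10, ],
                                     mode = "exact"), "10 features")
})

test_that("informative features dominate the global Shapley ranking", {
  fx <- coverage_fit()
  # all five features of the coverage scenario are informative; compare
  # against two appended pure-noise columns
  tr <- fx$train[1:400, ]
  set.seed(8)
  tr$noiseA <- rnorm(400)
  tr$noiseB <- rnorm(400)
  attr(tr, "features") <- c(attr(fx$train, "features"), "noiseA", "noiseB")
  fit <- fit_joint_forest(tr, list(n_trees = 60), seed = 2)
  gs <- shapley_global(fit, tr[1:12, ], tr[101:130, ], n_perm = 120,
                       seed = 3)
  inf <- fx$truth$informative
  expect_gt(min(gs[inf]), max(gs[c("noiseA", "noiseB")]))
})
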