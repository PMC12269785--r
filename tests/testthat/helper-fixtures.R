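# fixtures are generated in code and cached per test run

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# coverage scenario: stack, truth, points, regression matrix, trained forest
coverage_fit <- function() {
  fixture("coverage_fit", function() {
    sc <- make_benchmark_scenarios("coverage", seed = 7)
    st <- make_feature_fields(sc)
    tr <- make_truth(st, sc)
    pts <- sample_points(st, tr, 3000, sc)
    m <- spacetime_overlay(pts, st)
    train <- m[1:2000, ]
    attr(train, "features") <- attr(m, "features")
    fit <- fit_joint_forest(train, seed = 7)
    test <- m[2001:3000, ]
    attr(test, "features") <- attr(m, "features")
    list(scenario = sc, stack = st, truth = tr, points = pts,
         matrix = m, train = train, test = test, fit = fit)
  })
}

# a small forest on a trivial synthetic regression (fast unit fixture)
tiny_matrix <- function(n = 300, seed = 1, sd = 0.3) {
  set.seed(seed)
  x1 <- runif(n); x2 <- runif(n)
  response <- 1 + x1 + 0.5 * x2 + rnorm(n, 0, sd)
  m <- data.frame(response = response, socd = expm1(response),
                  x1 = x1, x2 = x2, is_pseudo_zero = FALSE,
                  x = runif(n, 0, 1e5), y = runif(n, 0, 1e5),
                  year = sample(2000:2003, n, replace = TRUE),
                  land_cover = sample(c("cropland", "grassland"), n, TRUE),
                  depth = runif(n, 0, 100))
  m$depth_interval <- as.character(assign_depth_interval(m$depth))
  m$stratum <- paste(m$land_cover, m$depth_interval, sep = ":")
  attr(m, "features") <- c("x1", "x2")
  m
}

tiny_fit <- function() {
  fixture("tiny_fit", function() {
    m <- tiny_matrix(300, seed = 2)
    list(matrix = m, fit = fit_joint_forest(m, list(n_trees = 40), seed = 3))
  })
}

# one cached end-to-end pipeline run shared across pipeline tests
pipeline_run <- function() {
  fixture("pipeline_run", function() {
    cfg <- pipeline_config(scenario = "coverage", n_points = 900,
                           select_features = FALSE, tune = FALSE,
                           cv_folds = 3, seed = 5,
                           out_dir = file.path(tempdir(), "socforest_pipe"))
    list(cfg = cfg, res = suppressMessages(run_pipeline(cfg)))
  })
}

# independent type-7 quantile: sorted-vector interpolation by hand
quantile_bruteforce <- function(v, p) {
  s <- sort(v)
  n <- length(s)
  vapply(p, function(pp) {
    h <- (n - 1) * pp + 1
    lo <- floor(h)
    hi <- ceiling(h)
    s[lo] + (h - lo) * (s[hi] - s[lo])
  }, numeric(1))
}

# gather the pooled leaf multiset for one query row directly from the
# stored per-tree structures (oracle path for pooled quantiles)
pooled_leaf_values <- function(fit, xrow) {
  tn <- predict(fit$rf, xrow[fit$features], type = "terminalNodes",
                num.threads = 1)$predictions
  unlist(lapply(seq_len(fit$n_trees), function(t) {
    j <- which(fit$leaf_ids[[t]] == tn[1, t])
    fit$leaf_values[[t]][[j]]
  }), use.names = FALSE)
}
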