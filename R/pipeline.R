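#' Pipeline configuration
#'
#' Declarative configuration for [run_pipeline()]: scenario, sample sizes,
#' split fractions, which optional stages to run, and the master seed (all
#' stage seeds derive from it).
#'
#' @param scenario a [synth_scenario()] or a [make_benchmark_scenarios()]
#'   name.
#' @param n_points total synthetic points.
#' @param calibration,test split fractions (see [stratified_split()]).
#' @param select_features run RSCFI feature selection on the calibration
#'   set.
#' @param tune run hyperparameter tuning on the calibration set.
#' @param cv_folds folds for the ISIW cross-validation.
#' @param probs prediction-interval probabilities.
#' @param risk fit the extrapolation-risk model and risk layer.
#' @param aggregate compute the variogram-based AOI aggregate.
#' @param map produce a small spacetime-block map product.
#' @param out_dir optional directory; when set, reports and tables are
#'   written there (JSON/CSV).
#' @param seed master integer seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(scenario = "coverage", n_points = 1500,
                            calibration = 0.11, test = 0.2,
                            select_features = TRUE, tune = FALSE,
                            cv_folds = 5, probs = c(0.025, 0.975),
                            risk = TRUE, aggregate = TRUE, map = TRUE,
                            out_dir = NULL, seed = 1) {
  if (is.character(scenario)) {
    scenario <- make_benchmark_scenarios(scenario, seed = seed)
  }
  stopifnot(inherits(scenario, "synth_scenario"))
  structure(list(scenario = scenario, n_points = n_points,
                 calibration = calibration, test = test,
                 select_features = select_features, tune = tune,
                 cv_folds = cv_folds, probs = probs, risk = risk,
                 aggregate = aggregate, map = map, out_dir = out_dir,
                 seed = seed),
            class = "pipeline_config")
}

#' Per-pixel spacetime-block map prediction
#'
#' Applies [predict_block_batch()] across a raster: for every grid cell,
#' the (year x depth) block nodes are assembled from the stack's layers
#' and the per-tree node predictions averaged into a block ensemble,
#' yielding co-registered mean, lower- and upper-bound layers. Pixels are
#' processed in row chunks so memory stays bounded; chunked and
#' whole-array prediction agree exactly.
#'
#' @param model a [fit_joint_forest()] model.
#' @param stack a `feature_stack` providing the model features.
#' @param block a [block_spec()] of (year, depth) nodes.
#' @param probs interval probabilities.
#' @param chunk_rows grid rows per processing chunk.
#' @param mask optional logical matrix; masked pixels are set to NA.
#' @return list of class `map_product`: matrices `mean`, `p025`, `p975`,
#'   `piw`, plus `grid`, `block`, and a `provenance` record (seed,
#'   hyperparameters, block nodes).
#' @export
predict_map <- function(model, stack, block, probs = c(0.025, 0.975),
                        chunk_rows = 16, mask = NULL) {
  g <- stack$grid
  N <- nrow(block)
  lab <- vapply(probs, prob_label, character(1))
  layers <- c("mean", lab, if (all(c("p025", "p975") %in% lab)) "piw")
  out <- stats::setNames(
    lapply(layers, function(l) matrix(NA_real_, g$nrows, g$ncols)), layers)

  node_layers <- lapply(seq_len(N), function(i) {
    dl <- stack$dynamic[[as.character(nearest_year(stack, block$year[i]))]]
    list(depth = block$depth[i], dyn = dl)
  })

  for (r0 in seq(1, g$nrows, by = chunk_rows)) {
    rows <- r0:min(r0 + chunk_rows - 1, g$nrows)
    npix <- length(rows) * g$ncols
    idx <- cbind(rep(rows, times = g$ncols),
                 rep(seq_len(g$ncols), each = length(rows)))
    # interleave the N node rows per pixel
    Xn <- lapply(node_layers, function(nl) {
      cols <- c(list(depth = rep(nl$depth, npix)),
                lapply(stack$static, function(m) m[idx]),
                lapply(nl$dyn, function(m) m[idx]))
      as.data.frame(cols)
    })
    Xall <- do.call(rbind, Xn)[rep(seq_len(npix), each = N) +
                                 npix * (seq_len(N) - 1), , drop = FALSE]
    pb <- predict_block_batch(model, Xall, N, probs)
    for (l in layers) out[[l]][idx] <- pb[[l]]
  }
  if (!is.null(mask)) for (l in layers) out[[l]][mask] <- NA_real_
  structure(c(out, list(grid = g, block = block,
                        provenance = list(seed = model$seed,
                                          hyperparameters = model$hyperparameters,
                                          nodes = as.data.frame(block)))),
            class = "map_product")
}

#' Run the end-to-end desk-scale pipeline
#'
#' Executes, in order: synthetic-data generation, spacetime overlay,
#' stratified splitting, optional RSCFI feature selection and
#' hyperparameter tuning on the calibration set, forest training,
#' evaluation (ISIW k-fold CV, LOYO CV where multiple years exist,
#' independent test with point/interval/stratified metrics),
#' extrapolation-risk scoring, spacetime-block map prediction, and
#' variogram-based aggregate uncertainty for a central AOI. Every stage is
#' seeded from the config; rerunning a config reproduces the metric report
#' exactly.
#'
#' @param config a [pipeline_config()].
#' @return list with `report` (nested metric list, also written as JSON
#'   when `out_dir` is set), `model`, `matrix`, `split`, `selected`,
#'   `map`, `risk`, `aggregate`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  sc <- config$scenario
  seed <- config$seed
  stage <- function(name, expr) {
    message("[socforest] stage: ", name)
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  stack <- stage("simulate", make_feature_fields(sc))
  truth <- make_truth(stack, sc)
  points <- sample_points(stack, truth, config$n_points, sc)
  mat <- stage("overlay", spacetime_overlay(points, stack))
  role <- stage("split", stratified_split(mat, config$calibration,
                                          config$test, seed = seed))
  feats0 <- rm_features(mat)
  subset_matrix <- function(m, rows, feats) {
    out <- m[rows, , drop = FALSE]
    attr(out, "features") <- feats
    out
  }
  cal <- subset_matrix(mat, role == "calibration", feats0)
  feats <- feats0
  sel <- NULL
  if (config$select_features && nrow(cal) >= 100) {
    sel <- stage("select", rscfi_select(cal, seed = seed))
    feats <- sel$selected
  }
  hp <- list()
  if (config$tune) {
    cal2 <- subset_matrix(mat, role == "calibration", feats)
    hp <- stage("tune", tune_hyperparameters(cal2, seed = seed))$best
  }
  train <- subset_matrix(mat, role != "test", feats)
  test <- subset_matrix(mat, role == "test", feats)
  model <- stage("train", fit_joint_forest(train, hp, seed = seed))

  cv_isiw <- stage("evaluate",
                   cross_validate(train, "isiw_kfold", k = config$cv_folds,
                                  hyperparameters = hp, seed = seed))
  cv_loyo <- if (length(unique(train$year)) >= 2) {
    cross_validate(train, "loyo", hyperparameters = hp, seed = seed)
  } else NULL

  pp <- predict_point(model, test, probs = config$probs)
  real <- !test$is_pseudo_zero
  pm <- point_metrics(test$socd[real], pp$mean[real])
  im <- interval_metrics(test$socd[real], pp$p025[real], pp$p975[real])
  qlo <- qcp(test$socd[real], pp$p025[real], 0.025)
  qhi <- qcp(test$socd[real], pp$p975[real], 0.975)
  strata <- strata_report(test$socd[real], pp$mean[real], pp$p025[real],
                          pp$p975[real], test$land_cover[real],
                          test$depth_interval[real])

  risk <- NULL
  if (config$risk) {
    risk <- stage("risk", {
      rmod <- fit_risk_model(train[feats], seed = seed)
      list(model = rmod,
           grid = risk_grid(rmod, stack, depth = 10,
                            year = stats::median(sc$years)))
    })
  }

  map <- NULL
  if (config$map) {
    blk <- block_spec(range(sc$years), c(0, 20))
    map <- stage("predict", predict_map(model, stack, blk,
                                        probs = config$probs))
  }

  aggregate <- NULL
  if (config$aggregate && !is.null(map)) {
    aggregate <- stage("aggregate", {
      g <- stack$grid
      # central AOI: middle third of the landscape
      aoi <- cbind(x = c(g$xmax / 3, 2 * g$xmax / 3, 2 * g$xmax / 3,
                         g$xmax / 3),
                   y = c(g$ymax / 3, g$ymax / 3, 2 * g$ymax / 3,
                         2 * g$ymax / 3))
      sr <- standardize_residuals(test$socd[real], pp$mean[real],
                                  pp$p025[real], pp$p975[real],
                                  test[real, c("x", "y")])
      sd_raster <- map$piw / 4 * sr$correction
      be <- block_mean_sd(map$mean, sd_raster, g, aoi, sr$variogram,
                          grid = max(500, g$cell), seed = seed)
      list(block = be, residuals = sr,
           design = design_based_estimate(
             test$socd[real][pracma::inpolygon(test$x[real], test$y[real],
                                               aoi[, 1], aoi[, 2])]))
    })
  }

  report <- list(
    n_points = nrow(mat),
    split = as.list(table(role)),
    features = list(initial = length(feats0), selected = length(feats)),
    cv = list(
      isiw = unclass(cv_isiw$overall),
      loyo = if (!is.null(cv_loyo)) unclass(cv_loyo$overall)),
    test = c(unclass(pm),
             list(picp = im$picp, piw = im$piw,
                  qcp_p025 = qlo, qcp_p975 = qhi)),
    aggregate = if (!is.null(aggregate)) list(
      mean = aggregate$block$mean, sd_mb = aggregate$block$sd_mb,
      n_points = aggregate$block$n_points,
      design_mean = aggregate$design$mean,
      design_sd = aggregate$design$sd_db),
    risk = if (!is.null(risk)) list(
      threshold = risk$model$threshold,
      extrapolated_fraction = mean(risk$grid$extrapolated)),
    seed = seed)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(strata, file.path(config$out_dir, "strata.csv"),
                     row.names = FALSE)
    utils::write.csv(mat, file.path(config$out_dir, "regression_matrix.csv"),
                     row.names = FALSE)
    if (!is.null(map)) {
      write_grid_csv(stack$grid, map$mean,
                     file.path(config$out_dir, "map_mean.csv"))
    }
  }

  list(report = report, strata = strata, model = model, matrix = mat,
       split = role, selected = sel, map = map, risk = risk,
       aggregate = aggregate, stack = stack, truth = truth)
}
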