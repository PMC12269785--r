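#' Point-prediction metrics
#'
#' R2 (coefficient of determination), Lin's concordance correlation
#' coefficient `ccc = 2*cov(x,y) / (var(x) + var(y) + (mean(x)-mean(y))^2)`
#' (population moments), mean and median absolute error, and bias
#' (mean of predicted minus observed, so underestimation is negative).
#' Metrics are computed on whatever scale `obs`/`pred` are passed in —
#' back-transformed kg/m3 throughout this package. Optional weights give
#' the inverse-sampling-intensity variants.
#'
#' @param obs,pred observed and predicted values, equal length >= 2.
#' @param weights optional nonnegative weights.
#' @return list of class `metric_report`: `r2`, `ccc`, `mae`, `medae`,
#'   `bias`, `n`.
#' @export
point_metrics <- function(obs, pred, weights = NULL) {
  n <- length(obs)
  if (length(pred) != n) stop("length mismatch", call. = FALSE)
  if (n < 2) stop("need at least 2 observations", call. = FALSE)
  w <- weights %||% rep(1, n)
  if (stats::var(obs) == 0) {
    stop("zero variance in observations: r2/ccc undefined", call. = FALSE)
  }
  sw <- sum(w)
  mx <- sum(w * obs) / sw
  my <- sum(w * pred) / sw
  vx <- sum(w * (obs - mx)^2) / sw
  vy <- sum(w * (pred - my)^2) / sw
  cxy <- sum(w * (obs - mx) * (pred - my)) / sw
  structure(list(
    r2 = 1 - sum(w * (obs - pred)^2) / sum(w * (obs - mx)^2),
    ccc = 2 * cxy / (vx + vy + (mx - my)^2),
    mae = sum(w * abs(pred - obs)) / sw,
    medae = weighted_median(abs(pred - obs), w),
    bias = sum(w * (pred - obs)) / sw,
    n = n), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("R2 %.3f | CCC %.3f | MAE %.2f | MedAE %.2f | bias %+.2f | n %d\n",
              x$r2, x$ccc, x$mae, x$medae, x$bias, x$n))
  invisible(x)
}

#' Inverse sampling-intensity weights
#'
#' Down-weights spatially clustered observations: local sampling intensity
#' is the count of points in the enclosing cell of a coarse grid (default
#' 25 km), and each point's weight is the reciprocal of its cell count,
#' normalized to mean 1.
#'
#' @param coords two-column matrix or data frame of planar coordinates (m).
#' @param cell aggregation cell size, m.
#' @return numeric weights with mean 1.
#' @export
isiw_weights <- function(coords, cell = 25000) {
  coords <- as.data.frame(coords)
  if (nrow(coords) < 2) stop("need at least 2 points", call. = FALSE)
  key <- paste(floor(coords[[1]] / cell), floor(coords[[2]] / cell))
  cnt <- table(key)
  w <- 1 / as.numeric(cnt[key])
  w / mean(w)
}

#' Cross-validate a forest specification
#'
#' Two schemes: `"isiw_kfold"` partitions rows into k random folds and
#' weights the pooled held-out metrics by inverse sampling intensity
#' ([isiw_weights()]); `"loyo"` (leave-one-year-out) holds out each
#' calendar year in turn, probing temporal transferability. Pseudo-zero
#' rows are used for training but excluded from all metrics.
#'
#' @param matrix regression matrix.
#' @param scheme `"isiw_kfold"` or `"loyo"`.
#' @param k folds for `"isiw_kfold"`.
#' @param hyperparameters forest settings, as in [fit_joint_forest()].
#' @param seed integer seed.
#' @param cell intensity-grid cell size for the ISIW weights, m.
#' @return list with `overall` ([point_metrics()] on pooled held-out
#'   predictions), `per_fold` (list of per-fold reports), `pred` (pooled
#'   held-out predictions, kg/m3) and `fold` assignments.
#' @export
cross_validate <- function(matrix, scheme = c("isiw_kfold", "loyo"), k = 5,
                           hyperparameters = list(), seed = 1, cell = 25000) {
  scheme <- match.arg(scheme)
  n <- nrow(matrix)
  feats <- rm_features(matrix)
  if (scheme == "loyo") {
    years <- sort(unique(matrix$year))
    if (length(years) < 2) {
      stop("leave-one-year-out needs at least 2 distinct years", call. = FALSE)
    }
    fold <- match(matrix$year, years)
  } else {
    set.seed(seed)
    fold <- sample(rep_len(seq_len(k), n))
  }
  pred <- rep(NA_real_, n)
  per_fold <- list()
  for (f in sort(unique(fold))) {
    tr <- matrix[fold != f, , drop = FALSE]
    attr(tr, "features") <- feats
    fit <- fit_joint_forest(tr, hyperparameters, seed = seed + f)
    pos <- query_leaves(fit, matrix[fold == f, , drop = FALSE])
    pred[fold == f] <- expm1(rowMeans(leaf_mean_matrix(fit, pos)))
    real_f <- fold == f & !matrix$is_pseudo_zero
    if (sum(real_f) >= 2 && stats::var(matrix$socd[real_f]) > 0) {
      per_fold[[as.character(f)]] <-
        point_metrics(matrix$socd[real_f], pred[real_f])
    }
  }
  real <- !matrix$is_pseudo_zero
  w <- if (scheme == "isiw_kfold") {
    isiw_weights(matrix[real, c("x", "y")], cell = cell)
  } else NULL
  list(overall = point_metrics(matrix$socd[real], pred[real], weights = w),
       per_fold = per_fold, pred = pred, fold = fold)
}

#' Prediction-interval coverage and width
#'
#' PICP is the fraction of observations falling inside their intervals
#' (closed bounds); PIW is the mean interval width.
#'
#' @param obs observations.
#' @param p025,p975 interval bounds, `p025 <= p975` elementwise.
#' @return list with `picp`, `piw`, `n`.
#' @export
interval_metrics <- function(obs, p025, p975) {
  n <- length(obs)
  if (length(p025) != n || length(p975) != n) {
    stop("length mismatch", call. = FALSE)
  }
  if (any(p025 > p975)) stop("p025 must not exceed p975", call. = FALSE)
  list(picp = mean(obs >= p025 & obs <= p975),
       piw = mean(p975 - p025), n = n)
}

#' Quantile coverage probability
#'
#' Fraction of observations at or below the predicted quantile; a
#' well-calibrated quantile at probability `p` yields QCP close to `p`.
#' Asymmetry between QCP at the two interval bounds reveals lopsided
#' intervals that PICP alone would hide.
#'
#' @param obs observations.
#' @param q_pred predicted quantile values.
#' @param p nominal probability in (0, 1).
#' @return observed fraction.
#' @export
qcp <- function(obs, q_pred, p) {
  if (p <= 0 || p >= 1) stop("p must lie in (0, 1)", call. = FALSE)
  mean(obs <= q_pred)
}

#' Accuracy curve of interval calibration
#'
#' For each nominal level `p`, builds the symmetric interval between the
#' `(1-p)/2` and `(1+p)/2` predicted quantiles and records the observed
#' coverage — the data behind an accuracy plot (observed vs nominal
#' fractions, ideally on the diagonal).
#'
#' @param obs observations.
#' @param quantile_fn function of one probability returning the predicted
#'   quantile for every observation.
#' @param levels nominal interval levels in (0, 1).
#' @return data frame with `level` and `observed`.
#' @export
accuracy_curve <- function(obs, quantile_fn,
                           levels = c(seq(0.05, 0.95, by = 0.05), 0.99)) {
  stopifnot(all(levels > 0 & levels < 1))
  observed <- vapply(levels, function(p) {
    lo <- quantile_fn((1 - p) / 2)
    hi <- quantile_fn((1 + p) / 2)
    mean(obs >= lo & obs <= hi)
  }, numeric(1))
  data.frame(level = levels, observed = observed)
}

#' Stratified metric report
#'
#' Point and interval metrics per (land cover x depth interval) stratum.
#' Strata with fewer than `min_n` real observations report counts only,
#' with metrics suppressed (NA).
#'
#' @param obs,pred observations and predictions, kg/m3.
#' @param p025,p975 interval bounds.
#' @param land_cover,depth_interval stratum labels per observation.
#' @param min_n minimum stratum size for metric reporting.
#' @return data frame with one row per stratum: `land_cover`,
#'   `depth_interval`, `n`, `r2`, `ccc`, `mae`, `medae`, `bias`, `picp`,
#'   `piw`.
#' @export
strata_report <- function(obs, pred, p025, p975, land_cover, depth_interval,
                          min_n = 5) {
  key <- paste(land_cover, depth_interval, sep = ":")
  out <- lapply(unique(key), function(s) {
    i <- key == s
    row <- data.frame(land_cover = land_cover[i][1],
                      depth_interval = depth_interval[i][1],
                      n = sum(i), r2 = NA_real_, ccc = NA_real_,
                      mae = NA_real_, medae = NA_real_, bias = NA_real_,
                      picp = NA_real_, piw = NA_real_,
                      stringsAsFactors = FALSE)
    if (sum(i) >= min_n && stats::var(obs[i]) > 0) {
      pm <- point_metrics(obs[i], pred[i])
      im <- interval_metrics(obs[i], p025[i], p975[i])
      row[c("r2", "ccc", "mae", "medae", "bias")] <-
        pm[c("r2", "ccc", "mae", "medae", "bias")]
      row[c("picp", "piw")] <- im[c("picp", "piw")]
    }
    row
  })
  do.call(rbind, out)
}

# transform-scale mean prediction used by the Shapley estimators
predict_transform_mean <- function(model, X) {
  pos <- query_leaves(model, X)
  rowMeans(leaf_mean_matrix(model, pos))
}

#' Shapley feature contributions for a single query
#'
#' Attributes the (log1p-scale) mean prediction at `x` to the model
#' features against a background sample, either by the permutation-
#' sampling estimator (`"monte_carlo"`) or by exact enumeration over all
#' feature subsets (`"exact"`, at most 10 features). Both satisfy the
#' efficiency property: contributions sum to `prediction - baseline`,
#' where the baseline is the mean prediction over the background rows
#' used.
#'
#' @param model a [fit_joint_forest()] model.
#' @param x single-row data frame with the feature columns.
#' @param background data frame of background (reference) rows.
#' @param n_perm permutations for the Monte-Carlo estimator.
#' @param seed integer seed.
#' @param mode `"monte_carlo"` or `"exact"`.
#' @return list of class `shapley_report`: `contributions` (named,
#'   log1p-scale), `baseline`, `prediction`, `mode`.
#' @export
shapley_contributions <- function(model, x, background, n_perm = 2000,
                                  seed = 1, mode = c("monte_carlo", "exact")) {
  mode <- match.arg(mode)
  feats <- model$features
  M <- length(feats)
  x <- as.data.frame(x)[feats]
  background <- as.data.frame(background)[feats]
  nb <- nrow(background)
  fx <- predict_transform_mean(model, x)

  bm <- as.matrix(background)
  xv <- as.numeric(x[1, ])

  if (mode == "exact") {
    if (M > 10) stop("exact mode supports at most 10 features", call. = FALSE)
    n_sub <- 2^M
    # value v(S): mean over background rows of the prediction with features
    # in S taken from x and the rest from the background row
    big <- bm[rep(seq_len(nb), n_sub), , drop = FALSE]
    for (s in seq_len(n_sub) - 1L) {
      rows <- (s * nb + 1):((s + 1) * nb)
      in_s <- bitwAnd(s, 2^(seq_len(M) - 1)) > 0
      for (j in which(in_s)) big[rows, j] <- xv[j]
    }
    pv <- predict_transform_mean(model, as.data.frame(big))
    v <- vapply(seq_len(n_sub) - 1L, function(s) {
      mean(pv[(s * nb + 1):((s + 1) * nb)])
    }, numeric(1))
    fact <- factorial(0:M)
    contrib <- stats::setNames(numeric(M), feats)
    for (j in seq_len(M)) {
      bit <- 2^(j - 1)
      for (s in seq_len(n_sub) - 1L) {
        if (bitwAnd(s, bit) > 0) next
        size <- sum(bitwAnd(s, 2^(seq_len(M) - 1)) > 0)
        w <- fact[size + 1] * fact[M - size] / fact[M + 1]
        contrib[j] <- contrib[j] + w * (v[s + bit + 1] - v[s + 1])
      }
    }
    baseline <- v[1]
  } else {
    set.seed(seed)
    border <- matrix(0L, n_perm, M)
    brow <- sample.int(nb, n_perm, replace = TRUE)
    for (p in seq_len(n_perm)) border[p, ] <- sample.int(M)
    # rows: for each permutation, the background row followed by M
    # cumulative replacements by x's values in permutation order
    big <- bm[rep(brow, each = M + 1), , drop = FALSE]
    for (p in seq_len(n_perm)) {
      base_row <- (p - 1) * (M + 1) + 1
      for (step in seq_len(M)) {
        j <- border[p, step]
        rows <- (base_row + step):(base_row + M)
        big[rows, j] <- xv[j]
      }
    }
    pv <- predict_transform_mean(model, as.data.frame(big))
    contrib <- stats::setNames(numeric(M), feats)
    for (p in seq_len(n_perm)) {
      base_row <- (p - 1) * (M + 1) + 1
      d <- diff(pv[base_row:(base_row + M)])
      contrib[border[p, ]] <- contrib[border[p, ]] + d
    }
    contrib <- contrib / n_perm
    baseline <- mean(pv[seq(1, by = M + 1, length.out = n_perm)])
  }
  structure(list(contributions = contrib, baseline = baseline,
                 prediction = fx, mode = mode),
            class = "shapley_report")
}

#' Global mean-absolute Shapley importance
#'
#' Averages the absolute per-feature Shapley contributions over a set of
#' query rows — the global feature-impact summary.
#'
#' @param model a [fit_joint_forest()] model.
#' @param X data frame of query rows.
#' @param background background rows.
#' @param n_perm permutations per query (Monte-Carlo estimator).
#' @param seed integer seed.
#' @return named vector of mean absolute contributions (log1p scale).
#' @export
shapley_global <- function(model, X, background, n_perm = 200, seed = 1) {
  X <- as.data.frame(X)
  acc <- stats::setNames(numeric(length(model$features)), model$features)
  for (i in seq_len(nrow(X))) {
    sr <- shapley_contributions(model, X[i, , drop = FALSE], background,
                                n_perm = n_perm, seed = seed + i)
    acc <- acc + abs(sr$contributions)
  }
  acc / nrow(X)
}
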