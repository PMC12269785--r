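# average path length of an unsuccessful BST search over n points; the
# normalizing constant of the isolation-forest anomaly score
c_factor <- function(n) {
  if (n <= 1) return(0)
  if (n == 2) return(1)
  2 * (log(n - 1) + 0.5772156649015329) - 2 * (n - 1) / n
}

# grow one isolation tree on rows `idx` of matrix X (nested-list nodes)
grow_itree <- function(X, idx, depth, hmax) {
  if (depth >= hmax || length(idx) <= 1) {
    return(list(leaf = TRUE, size = length(idx)))
  }
  sub <- X[idx, , drop = FALSE]
  rng <- apply(sub, 2, range)
  usable <- which(rng[2, ] > rng[1, ])
  if (length(usable) == 0) return(list(leaf = TRUE, size = length(idx)))
  f <- if (length(usable) == 1) usable else sample(usable, 1)
  sp <- stats::runif(1, rng[1, f], rng[2, f])
  left <- idx[sub[, f] < sp]
  right <- idx[sub[, f] >= sp]
  if (length(left) == 0 || length(right) == 0) {
    return(list(leaf = TRUE, size = length(idx)))
  }
  list(leaf = FALSE, f = f, sp = sp,
       L = grow_itree(X, left, depth + 1, hmax),
       R = grow_itree(X, right, depth + 1, hmax))
}

# path lengths of query rows through one tree (c-adjusted at truncated leaves)
itree_paths <- function(node, X, idx, depth, out) {
  if (node$leaf) {
    out[idx] <- depth + c_factor(node$size)
    return(out)
  }
  go_left <- X[idx, node$f] < node$sp
  if (any(go_left)) out <- itree_paths(node$L, X, idx[go_left], depth + 1, out)
  if (any(!go_left)) out <- itree_paths(node$R, X, idx[!go_left], depth + 1, out)
  out
}

#' Fit an isolation-forest extrapolation-risk model
#'
#' Standard isolation forest: each tree is grown on a random subsample by
#' recursively choosing a random feature and a random split within its
#' range, until isolation or the height ceiling `ceiling(log2(psi))`.
#' Points in sparse or unfamiliar regions of feature space are isolated in
#' few splits; short average path lengths therefore signal extrapolation.
#'
#' @param X_train numeric matrix or data frame of training features.
#' @param n_trees number of isolation trees.
#' @param subsample subsample size psi per tree (capped at `nrow`).
#' @param seed integer seed.
#' @return object of class `risk_model` with the tree ensemble, psi, the
#'   normalizing constant `c(psi)` and the data-derived `threshold`
#'   (see [risk_threshold()]).
#' @export
fit_risk_model <- function(X_train, n_trees = 100, subsample = 256, seed = 1) {
  X <- as.matrix(X_train)
  if (all(apply(X, 2, function(v) max(v) == min(v)))) {
    stop("all features are constant; risk model undefined", call. = FALSE)
  }
  set.seed(seed)
  n <- nrow(X)
  psi <- min(subsample, n)
  hmax <- ceiling(log2(psi))
  trees <- lapply(seq_len(n_trees), function(t) {
    rows <- sample.int(n, psi)
    grow_itree(X, rows, 0, hmax)
  })
  model <- structure(list(trees = trees, psi = psi, n_trees = n_trees,
                          cpsi = c_factor(psi), seed = seed,
                          features = colnames(X), threshold = NA_real_),
                     class = "risk_model")
  model$threshold <- risk_threshold(model, X)
  model
}

# mean path length per query row over the ensemble
mean_path_length <- function(model, X) {
  X <- as.matrix(X)
  if (!is.null(model$features) && !is.null(colnames(X))) {
    if (!all(model$features %in% colnames(X))) {
      stop("feature mismatch between model and query data", call. = FALSE)
    }
    X <- X[, model$features, drop = FALSE]
  }
  if (ncol(X) != length(model$features %||% seq_len(ncol(X)))) {
    stop("feature mismatch between model and query data", call. = FALSE)
  }
  acc <- numeric(nrow(X))
  for (tr in model$trees) {
    acc <- acc + itree_paths(tr, X, seq_len(nrow(X)), 0, numeric(nrow(X)))
  }
  acc / length(model$trees)
}

# path length -> anomaly score on the (0,1) scale
score_from_path <- function(Eh, cpsi) 2^(-Eh / cpsi)

#' Extrapolation-risk scores
#'
#' The canonical isolation-forest anomaly score
#' `s = 2^(-E[h(x)] / c(psi))`, already a normalized 0-1 scale: `s = 0.5`
#' when the mean path length equals the dataset average `c(psi)`, and
#' `s -> 1` as the path length shrinks. Higher values mean greater
#' extrapolation risk.
#'
#' @param model a [fit_risk_model()] model.
#' @param X query features.
#' @return risk scores in (0, 1), one per row.
#' @export
risk_score <- function(model, X) {
  score_from_path(mean_path_length(model, X), model$cpsi)
}

#' Data-derived extrapolation threshold
#'
#' The average path length across the (training) dataset, mapped through
#' the same score transform: `2^(-mean(E[h]) / c(psi))`. Queries scoring
#' above the threshold are classified as extrapolated; the cut is
#' data-dependent and can be overridden by users.
#'
#' @param model a [fit_risk_model()] model.
#' @param X_train training features.
#' @return threshold score in (0, 1).
#' @export
risk_threshold <- function(model, X_train) {
  score_from_path(mean(mean_path_length(model, X_train)), model$cpsi)
}

#' Per-pixel extrapolation-risk layer
#'
#' Scores every grid cell of a feature stack at a given depth and year and
#' applies the classification threshold.
#'
#' @param model a [fit_risk_model()] model (trained on the same feature
#'   set the stack provides, plus `depth`).
#' @param stack a `feature_stack`.
#' @param depth depth in cm assigned to all pixels.
#' @param year calendar year selecting the dynamic layers.
#' @param threshold override of the model's stored threshold.
#' @return list with `risk` (matrix in (0,1)), `extrapolated` (logical
#'   matrix), `threshold`, `grid`.
#' @export
risk_grid <- function(model, stack, depth, year, threshold = NULL) {
  Xg <- pixel_features(stack, depth, year)
  missing <- setdiff(model$features, colnames(Xg))
  if (length(missing) > 0) {
    stop("stack lacks model features: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  s <- risk_score(model, Xg)
  thr <- threshold %||% model$threshold
  g <- stack$grid
  risk <- matrix(s, g$nrows, g$ncols)
  list(risk = risk, extrapolated = risk > thr, threshold = thr, grid = g)
}

# feature matrix over all cells of a stack (column-major), depth included
pixel_features <- function(stack, depth, year) {
  g <- stack$grid
  npix <- g$nrows * g$ncols
  dl <- stack$dynamic[[as.character(nearest_year(stack, year))]]
  cols <- c(list(depth = rep(depth, npix)),
            lapply(stack$static, as.vector),
            lapply(dl, as.vector))
  do.call(cbind, cols)
}
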