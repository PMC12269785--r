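#' Fit a joint mean + quantile forest
#'
#' Grows a random forest on the log1p-scale response (trees via
#' \pkg{ranger}) and retains, for every tree, the multiset of bootstrap
#' (in-bag) training responses in each terminal leaf. One fitted object
#' therefore serves both as a standard mean forest and as a quantile
#' regression forest: the conditional mean is the average over trees of
#' leaf means, and conditional quantiles come from the pooled leaf
#' response distributions, without refitting.
#'
#' @param matrix regression matrix from [spacetime_overlay()] (response on
#'   the log1p scale, feature columns named by its `features` attribute),
#'   or any data frame with a `response` column and a `features` attribute.
#' @param hyperparameters named list overriding defaults: `n_trees` (120),
#'   `splitrule` (`"variance"`), `max_depth` (0 = unlimited), `mtry_frac`
#'   (numeric fraction of features, or `"sqrt"`/`"log2"`; `NULL` = engine
#'   default), `min_node_size` (5).
#' @param seed integer seed; fitting is deterministic under it.
#' @return an object of class `joint_forest`.
#' @export
fit_joint_forest <- function(matrix, hyperparameters = list(), seed = 1) {
  feats <- rm_features(matrix)
  y <- matrix$response
  if (!all(is.finite(y))) stop("non-finite responses", call. = FALSE)
  if (nrow(matrix) < 50) stop("need at least 50 rows", call. = FALSE)
  hp <- utils::modifyList(
    list(n_trees = 120, splitrule = "variance", max_depth = 0,
         mtry_frac = NULL, min_node_size = 5),
    hyperparameters)
  rf <- ranger::ranger(
    x = matrix[feats], y = y,
    num.trees = hp$n_trees, splitrule = hp$splitrule,
    max.depth = hp$max_depth, min.node.size = hp$min_node_size,
    mtry = resolve_mtry(hp$mtry_frac, length(feats)),
    keep.inbag = TRUE, seed = seed, num.threads = 1)

  tn <- stats::predict(rf, matrix[feats], type = "terminalNodes",
                       num.threads = 1)$predictions
  ntree <- rf$num.trees
  leaf_ids <- vector("list", ntree)
  leaf_values <- vector("list", ntree)
  leaf_means <- vector("list", ntree)
  for (t in seq_len(ntree)) {
    cnt <- rf$inbag.counts[[t]]
    idx <- rep.int(seq_along(cnt), cnt)          # bootstrap multiplicity
    lv <- split(y[idx], tn[idx, t])
    leaf_ids[[t]] <- as.integer(names(lv))
    leaf_values[[t]] <- unname(lv)
    leaf_means[[t]] <- vapply(lv, mean, numeric(1), USE.NAMES = FALSE)
  }
  structure(list(rf = rf, features = feats, hyperparameters = hp,
                 seed = seed, n_trees = ntree,
                 leaf_ids = leaf_ids, leaf_values = leaf_values,
                 leaf_means = leaf_means),
            class = "joint_forest")
}

resolve_mtry <- function(frac, p) {
  if (is.null(frac)) return(NULL)
  if (is.character(frac)) {
    return(switch(frac,
                  sqrt = max(1L, floor(sqrt(p))),
                  log2 = max(1L, floor(log2(p))),
                  max(1L, floor(as.numeric(frac) * p))))
  }
  max(1L, floor(frac * p))
}

#' @export
print.joint_forest <- function(x, ...) {
  cat(sprintf("<joint_forest> %d trees on %d features, seed %d\n",
              x$n_trees, length(x$features), x$seed))
  invisible(x)
}

# per-tree leaf positions for query rows: list(tn = node ids, pos = index
# into leaf_* lists), both n x ntree matrices
query_leaves <- function(model, X) {
  X <- as.data.frame(X)
  missing <- setdiff(model$features, names(X))
  if (length(missing) > 0) {
    stop("missing feature columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tn <- stats::predict(model$rf, X[model$features], type = "terminalNodes",
                       num.threads = 1)$predictions
  pos <- matrix(NA_integer_, nrow(tn), ncol(tn))
  for (t in seq_len(ncol(tn))) {
    pos[, t] <- match(tn[, t], model$leaf_ids[[t]])
  }
  if (anyNA(pos)) stop("query reached an unknown leaf", call. = FALSE)
  pos
}

# matrix of per-tree leaf means for query rows (transform scale), n x ntree
leaf_mean_matrix <- function(model, pos) {
  M <- matrix(NA_real_, nrow(pos), ncol(pos))
  for (t in seq_len(ncol(pos))) {
    M[, t] <- model$leaf_means[[t]][pos[, t]]
  }
  M
}

#' Predict means and quantiles at point support
#'
#' The mean is the back-transformed average over trees of leaf means (the
#' standard forest prediction). Quantiles come in two modes:
#' `"leaf_pooled"` (default) pools the full in-bag leaf response multisets
#' of all trees and takes empirical quantiles — the quantile-regression-
#' forest reading, appropriate at point support; `"tree_ensemble"` takes
#' quantiles of the per-tree mean predictions — the spread of tree
#' ensembles, the reading used for spacetime blocks. Quantiles are computed
#' on the transform scale and back-transformed (monotone-invariant).
#'
#' @param model a [fit_joint_forest()] model.
#' @param X data frame with the training feature columns.
#' @param probs quantile probabilities in (0, 1); default the 95% interval
#'   bounds P0.025 and P0.975.
#' @param mode `"leaf_pooled"` or `"tree_ensemble"`.
#' @return data frame with `mean`, one column per quantile (`p025`, `p975`,
#'   ...) and, when both interval bounds are requested, `piw = p975 - p025`;
#'   all in kg/m3.
#' @export
predict_point <- function(model, X, probs = c(0.025, 0.975),
                          mode = c("leaf_pooled", "tree_ensemble")) {
  mode <- match.arg(mode)
  if (any(probs <= 0 | probs >= 1)) {
    stop("probs must lie strictly in (0, 1)", call. = FALSE)
  }
  pos <- query_leaves(model, X)
  M <- leaf_mean_matrix(model, pos)
  mean_t <- rowMeans(M)
  qm <- matrix(NA_real_, nrow(pos), length(probs))
  if (mode == "tree_ensemble") {
    for (i in seq_len(nrow(pos))) {
      qm[i, ] <- stats::quantile(M[i, ], probs, names = FALSE)
    }
  } else {
    for (i in seq_len(nrow(pos))) {
      pooled <- unlist(lapply(seq_len(ncol(pos)), function(t) {
        model$leaf_values[[t]][[pos[i, t]]]
      }), use.names = FALSE)
      qm[i, ] <- stats::quantile(pooled, probs, names = FALSE)
    }
  }
  finish_interval(mean_t, qm, probs)
}

finish_interval <- function(mean_t, qm, probs) {
  out <- data.frame(mean = expm1(mean_t))
  qb <- expm1(qm)
  colnames(qb) <- vapply(probs, prob_label, character(1))
  out <- cbind(out, as.data.frame(qb))
  if (all(c("p025", "p975") %in% names(out))) {
    out$piw <- out$p975 - out$p025
  }
  out
}

#' Specify a spacetime block
#'
#' A block is a set of N distinct (year, depth) nodes — typically the four
#' corners of a (year-interval x depth-interval) cell — whose per-tree
#' predictions are averaged before the ensemble distribution is taken.
#'
#' @param years,depths vectors of equal length (or scalars recycled
#'   crosswise via `expand = TRUE`) giving the node coordinates.
#' @param expand if `TRUE`, take the full years x depths cross product.
#' @return data frame of class `block_spec` with columns `year`, `depth`.
#' @export
block_spec <- function(years, depths, expand = TRUE) {
  nodes <- if (expand) expand.grid(year = years, depth = depths)
    else data.frame(year = years, depth = depths)
  structure(nodes, class = c("block_spec", "data.frame"))
}

#' Predict a spacetime block
#'
#' For each tree t, the block value is the average of the tree's leaf-mean
#' predictions over the N nodes; the block mean is the average of these
#' per-tree block values and the prediction interval is taken from their
#' ensemble distribution (back-transformed). Averaging N nodes with
#' independent errors shrinks the ensemble spread by about 1/sqrt(N).
#'
#' @param model a [fit_joint_forest()] model.
#' @param x_features data frame with one row per node, each carrying the
#'   node's year-specific dynamic features and its depth.
#' @param block optional [block_spec()] for validation (row count must
#'   match).
#' @param probs quantile probabilities in (0, 1).
#' @return single-row data frame as in [predict_point()].
#' @export
predict_block <- function(model, x_features, block = NULL,
                          probs = c(0.025, 0.975)) {
  if (!is.null(block) && nrow(block) != nrow(x_features)) {
    stop("x_features must supply one row per block node", call. = FALSE)
  }
  predict_block_batch(model, x_features, nrow(x_features), probs)
}

#' Batched spacetime-block prediction
#'
#' Vectorized form of [predict_block()]: `x_features` holds consecutive
#' groups of `n_nodes` rows, one group per block; used for map production.
#'
#' @inheritParams predict_block
#' @param n_nodes nodes per block; `nrow(x_features)` must be a multiple.
#' @return data frame with one row per block.
#' @export
predict_block_batch <- function(model, x_features, n_nodes,
                                probs = c(0.025, 0.975)) {
  if (any(probs <= 0 | probs >= 1)) {
    stop("probs must lie strictly in (0, 1)", call. = FALSE)
  }
  n <- nrow(x_features)
  if (n %% n_nodes != 0) stop("row count not a multiple of n_nodes",
                              call. = FALSE)
  pos <- query_leaves(model, x_features)
  M <- leaf_mean_matrix(model, pos)
  grp <- rep(seq_len(n / n_nodes), each = n_nodes)
  B <- rowsum(M, grp, reorder = FALSE) / n_nodes   # blocks x trees
  mean_t <- rowMeans(B)
  qm <- matrix(NA_real_, nrow(B), length(probs))
  for (i in seq_len(nrow(B))) {
    qm[i, ] <- stats::quantile(B[i, ], probs, names = FALSE)
  }
  finish_interval(mean_t, qm, probs)
}

#' Cumulative feature importance
#'
#' Sorts importances in descending order and normalizes their cumulative
#' sums to end at 1 — the quantity thresholded by [rscfi_select()].
#'
#' @param importances named nonnegative numeric vector, not all zero.
#' @return data frame with `feature`, `importance` (normalized), `cfi`.
#' @examples
#' cumulative_importance(c(a = 0.5, b = 0.3, c = 0.2))
#' @export
cumulative_importance <- function(importances) {
  if (any(importances < 0)) stop("negative importance", call. = FALSE)
  if (sum(importances) <= 0) stop("all importances are zero", call. = FALSE)
  o <- order(importances, decreasing = TRUE)
  imp <- importances[o] / sum(importances)
  data.frame(feature = names(imp) %||% as.character(o),
             importance = unname(imp), cfi = cumsum(unname(imp)),
             stringsAsFactors = FALSE)
}

#' Default hyperparameter search space
#'
#' The standard forest tuning space expressed in the terms of the tree
#' engine: split rule, maximum depth, feature fraction per split, and
#' minimum leaf size, with the ensemble size fixed at 120 trees.
#'
#' @return named list of candidate value vectors.
#' @export
default_hyperparameter_space <- function() {
  list(splitrule = c("variance", "extratrees"),
       max_depth = c(10, 20, 30),
       mtry_frac = c("0.3", "0.5", "0.7", "log2", "sqrt"),
       min_node_size = c(1, 2, 4))
}

space_row_to_hp <- function(row) {
  mf <- row$mtry_frac
  list(n_trees = 120,
       splitrule = as.character(row$splitrule),
       max_depth = as.numeric(row$max_depth),
       mtry_frac = if (mf %in% c("sqrt", "log2")) mf else as.numeric(mf),
       min_node_size = as.numeric(row$min_node_size))
}

# CCC of back-transformed CV predictions for a candidate, k random folds
cv_ccc <- function(matrix, hp, folds, seed) {
  m <- point_metrics_cv(matrix, hp, folds, seed)
  m$ccc
}

point_metrics_cv <- function(matrix, hp, folds, seed, feats = NULL) {
  feats <- feats %||% rm_features(matrix)
  set.seed(seed)
  n <- nrow(matrix)
  fold <- sample(rep_len(seq_len(folds), n))
  pred <- numeric(n)
  for (k in seq_len(folds)) {
    tr <- matrix[fold != k, , drop = FALSE]
    attr(tr, "features") <- feats
    fit <- fit_joint_forest(tr, hp, seed = seed + k)
    pos <- query_leaves(fit, matrix[fold == k, , drop = FALSE])
    pred[fold == k] <- expm1(rowMeans(leaf_mean_matrix(fit, pos)))
  }
  real <- !matrix$is_pseudo_zero
  point_metrics(matrix$socd[real], pred[real])
}

#' Tune forest hyperparameters by successive halving
#'
#' Random candidates from the space are evaluated on geometrically growing
#' training fractions (halving factor 3), keeping the top third at each
#' rung (scored by CCC on a fixed validation split); the surviving
#' candidates are ranked by k-fold cross-validated CCC on the full data
#' and the winner returned. Deterministic under `seed`.
#'
#' @param matrix regression matrix.
#' @param space candidate space as from [default_hyperparameter_space()].
#' @param folds folds for the final cross-validation.
#' @param n_candidates number of sampled candidates.
#' @param seed integer seed.
#' @return list with `best` (hyperparameter list for
#'   [fit_joint_forest()]), `best_ccc`, and `results` (per-candidate trace).
#' @export
tune_hyperparameters <- function(matrix, space = default_hyperparameter_space(),
                                 folds = 5, n_candidates = 12, seed = 1) {
  if (length(space) == 0 || any(lengths(space) == 0)) {
    stop("empty hyperparameter space", call. = FALSE)
  }
  set.seed(seed)
  grid <- expand.grid(space, stringsAsFactors = FALSE)
  cand <- grid[sample.int(nrow(grid), min(n_candidates, nrow(grid))), ,
               drop = FALSE]
  feats <- rm_features(matrix)
  n <- nrow(matrix)
  val <- sample.int(n, max(30, round(0.2 * n)))
  pool <- setdiff(seq_len(n), val)

  halving <- 3
  n_rungs <- max(0, ceiling(log(nrow(cand) / 3) / log(halving)))
  fracs <- if (n_rungs > 0) halving^(-(n_rungs:1)) else numeric()
  for (frac in fracs) {
    if (nrow(cand) <= 3) break
    tr_idx <- sample(pool, max(50, round(frac * length(pool))))
    score <- vapply(seq_len(nrow(cand)), function(i) {
      hp <- space_row_to_hp(cand[i, , drop = FALSE])
      tr <- matrix[tr_idx, , drop = FALSE]; attr(tr, "features") <- feats
      fit <- fit_joint_forest(tr, hp, seed = seed)
      pos <- query_leaves(fit, matrix[val, , drop = FALSE])
      pred <- expm1(rowMeans(leaf_mean_matrix(fit, pos)))
      real <- !matrix$is_pseudo_zero[val]
      point_metrics(matrix$socd[val][real], pred[real])$ccc
    }, numeric(1))
    keep <- order(score, decreasing = TRUE)[seq_len(ceiling(nrow(cand) / 3))]
    cand <- cand[keep, , drop = FALSE]
  }
  final <- vapply(seq_len(nrow(cand)), function(i) {
    cv_ccc(matrix, space_row_to_hp(cand[i, , drop = FALSE]), folds,
           seed = seed + 1000L)
  }, numeric(1))
  best_i <- which.max(final)
  cand$cv_ccc <- final
  list(best = space_row_to_hp(cand[best_i, , drop = FALSE]),
       best_ccc = final[best_i], results = cand)
}

#' Feature selection by repeated-subsampling cumulative importance (RSCFI)
#'
#' Iteratively: (a) fit default forests on `repeats` random half
#' subsamples and average their normalized impurity importances; (b) keep
#' the smallest descending-importance prefix whose cumulative importance
#' reaches `cfi_threshold` and drop the rest; (c) record k-fold CV metrics
#' (R2, CCC, MAE, MedAE) for the current feature set. Stops when no
#' feature is dropped or at most 2 remain, and returns the iteration's
#' feature set with the best cross-validated CCC. Unlike fixed-step
#' recursive elimination this removes many features at once when most
#' importance mass is concentrated, and slows down as the set tightens.
#'
#' @param matrix regression matrix.
#' @param cfi_threshold cumulative-importance mass to retain, in (0, 1].
#' @param repeats subsamples per iteration.
#' @param subsample_fraction row fraction per subsample.
#' @param folds folds for the per-iteration CV metrics.
#' @param seed integer seed.
#' @param n_trees trees per forest.
#' @return list with `selected` (character vector), `trace` (one row per
#'   iteration: feature count and CV metrics) and `importance` (final
#'   averaged importances).
#' @export
rscfi_select <- function(matrix, cfi_threshold = 0.99, repeats = 5,
                         subsample_fraction = 0.5, folds = 5, seed = 1,
                         n_trees = 120) {
  if (cfi_threshold <= 0 || cfi_threshold > 1) {
    stop("cfi_threshold must lie in (0, 1]", call. = FALSE)
  }
  feats <- rm_features(matrix)
  if (length(feats) < 2) stop("need at least 2 features", call. = FALSE)
  n <- nrow(matrix)
  sets <- list(); cccs <- numeric(); trace <- list()
  iter <- 0L
  repeat {
    iter <- iter + 1L
    set.seed(seed + iter)
    imp <- numeric(length(feats)); names(imp) <- feats
    for (r in seq_len(repeats)) {
      rows <- sample.int(n, max(50, round(subsample_fraction * n)))
      rf <- ranger::ranger(
        x = matrix[rows, feats, drop = FALSE], y = matrix$response[rows],
        num.trees = n_trees, importance = "impurity",
        seed = seed + 100L * iter + r, num.threads = 1)
      vi <- rf$variable.importance
      imp <- imp + vi / sum(vi)
    }
    imp <- imp / repeats
    cm <- point_metrics_cv(matrix, list(n_trees = n_trees), folds,
                           seed = seed + 999L, feats = feats)
    sets[[iter]] <- feats
    cccs[iter] <- cm$ccc
    trace[[iter]] <- data.frame(iteration = iter, n_features = length(feats),
                                r2 = cm$r2, ccc = cm$ccc, mae = cm$mae,
                                medae = cm$medae)
    ci <- cumulative_importance(imp)
    k <- which(ci$cfi >= cfi_threshold)[1]
    keep <- ci$feature[seq_len(k)]
    if (k == length(feats) || length(keep) <= 2) {
      if (length(keep) < length(feats)) {
        # record the terminal reduced set as well
        iter <- iter + 1L
        tr2 <- matrix; attr(tr2, "features") <- keep
        cm2 <- point_metrics_cv(tr2, list(n_trees = n_trees), folds,
                                seed = seed + 999L, feats = keep)
        sets[[iter]] <- keep
        cccs[iter] <- cm2$ccc
        trace[[iter]] <- data.frame(iteration = iter,
                                    n_features = length(keep),
                                    r2 = cm2$r2, ccc = cm2$ccc,
                                    mae = cm2$mae, medae = cm2$medae)
      }
      break
    }
    feats <- keep
  }
  best <- which.max(cccs)
  list(selected = sets[[best]], trace = do.call(rbind, trace),
       importance = imp)
}
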