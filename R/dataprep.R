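DEPTH_BREAKS <- c(0, 20, 50, 100, 200)
DEPTH_LABELS <- c("0-20", "20-50", "50-100", "100-200")

#' Assign a depth to its standard prediction interval
#'
#' Half-open binning `[0,20)`, `[20,50)`, `[50,100)`, `[100,200]` over the
#' four standard depth intervals.
#'
#' @param depth depth in cm, within `[0, 200]`.
#' @return factor with levels `0-20`, `20-50`, `50-100`, `100-200`.
#' @examples
#' assign_depth_interval(c(10, 20, 150))
#' @export
assign_depth_interval <- function(depth) {
  if (any(depth < 0 | depth > 200)) {
    stop("depth outside [0, 200] cm", call. = FALSE)
  }
  cut(depth, breaks = DEPTH_BREAKS, labels = DEPTH_LABELS,
      right = FALSE, include.lowest = TRUE)
}

#' Space-time overlay of points on a feature stack
#'
#' Joins each harmonized point with the feature values of its containing
#' grid cell (point-in-cell lookup, no interpolation): static layers once,
#' dynamic layers from the point's own year (years outside the stack range
#' are substituted by the nearest available year). Points outside the
#' raster extent are dropped and logged. The result is the regression
#' matrix: response on the log1p scale, depth as a feature, and a stratum
#' label (land cover x depth interval) for splitting and reporting.
#'
#' @param points harmonized-point data frame (see [harmonize_points()]).
#' @param stack a [make_feature_fields()] stack (or any `feature_stack`).
#' @return data frame with columns `id`, `x`, `y`, `year`, `depth`,
#'   `socd`, `response` (= log1p(socd)), `land_cover`, `depth_interval`,
#'   `stratum`, `is_pseudo_zero`, `weight`, and one column per feature;
#'   attribute `features` lists the model feature columns (depth first),
#'   attribute `dropped` the ids of out-of-extent points.
#' @export
spacetime_overlay <- function(points, stack) {
  g <- stack$grid
  ix <- cell_index(g, points$x, points$y)
  inside <- !is.na(ix$row)
  dropped <- data.frame(id = points$id[!inside],
                        reason = rep("outside_extent", sum(!inside)),
                        stringsAsFactors = FALSE)
  p <- points[inside, , drop = FALSE]
  row <- ix$row[inside]; col <- ix$col[inside]
  idx <- cbind(row, col)

  out <- data.frame(
    id = p$id, x = p$x, y = p$y, year = as.integer(p$year), depth = p$depth,
    socd = p$socd, response = transform_response(p$socd),
    land_cover = as.character(p$land_cover),
    depth_interval = as.character(assign_depth_interval(p$depth)),
    is_pseudo_zero = p$is_pseudo_zero, weight = 1,
    stringsAsFactors = FALSE)
  out$stratum <- paste(out$land_cover, out$depth_interval, sep = ":")

  for (f in names(stack$static)) out[[f]] <- stack$static[[f]][idx]
  dyn_names <- names(stack$dynamic[[1]])
  for (f in dyn_names) out[[f]] <- NA_real_
  for (yy in unique(out$year)) {
    sel <- out$year == yy
    dl <- stack$dynamic[[as.character(nearest_year(stack, yy))]]
    for (f in dyn_names) out[[f]][sel] <- dl[[f]][idx[sel, , drop = FALSE]]
  }

  feats <- c("depth", names(stack$static), dyn_names)
  complete <- stats::complete.cases(out[feats])
  if (any(!complete)) {
    dropped <- rbind(dropped, data.frame(id = out$id[!complete],
                                         reason = "missing_feature",
                                         stringsAsFactors = FALSE))
    out <- out[complete, , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "features") <- feats
  attr(out, "dropped") <- dropped
  out
}

#' Stratified calibration/training/test split
#'
#' Rows are split within strata (land cover x depth interval) so every
#' stratum contributes to each subset proportionally. Pseudo-zero rows are
#' never assigned to the test set (they are not real measurements and
#' cluster at the origin); strata smaller than 3 rows go entirely to
#' training. Default fractions mirror a roughly 11% calibration / 5% test
#' design with the remainder for training.
#'
#' @param matrix regression matrix from [spacetime_overlay()].
#' @param calibration,test subset fractions (sum must be < 1).
#' @param seed integer seed; the assignment is deterministic under it.
#' @return factor of length `nrow(matrix)` with levels
#'   `calibration`, `training`, `test`.
#' @export
stratified_split <- function(matrix, calibration = 0.11, test = 0.05,
                             seed = 1) {
  stopifnot(calibration >= 0, test >= 0, calibration + test < 1)
  set.seed(seed)
  n <- nrow(matrix)
  role <- rep("training", n)
  for (s in unique(matrix$stratum)) {
    rows <- which(matrix$stratum == s)
    if (length(rows) < 3) {
      if (length(rows) > 0 && (calibration > 0 || test > 0)) {
        warning("stratum '", s, "' has fewer than 3 rows; all to training",
                call. = FALSE)
      }
      next
    }
    testable <- rows[!matrix$is_pseudo_zero[rows]]
    n_test <- min(round(test * length(rows)), length(testable))
    test_rows <- if (n_test > 0) sample(testable, n_test) else integer()
    remaining <- setdiff(rows, test_rows)
    n_cal <- round(calibration * length(rows))
    cal_rows <- if (n_cal > 0) sample(remaining, min(n_cal, length(remaining)))
      else integer()
    role[test_rows] <- "test"
    role[cal_rows] <- "calibration"
  }
  factor(role, levels = c("calibration", "training", "test"))
}
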