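#' Standardize map residuals by the interval-width proxy sd
#'
#' The standard deviation of the map prediction error at each validation
#' point is approximated from the 95% interval width as
#' `sigma = (p975 - p025) / 4` (normal-interval reading). Residuals
#' `pred - obs` divided by this proxy should have a unit-sill variogram;
#' because the proxy is only approximate, the square root of the initially
#' fitted sill is applied as a correction factor to `sigma` and the
#' residuals are re-standardized so the re-fitted sill is close to 1.
#'
#' @param obs,pred observed and predicted SOCD, kg/m3.
#' @param p025,p975 interval bounds, `p975 > p025` elementwise.
#' @param coords two-column matrix/data frame of planar coordinates, m.
#' @param n_bins,max_lag variogram binning for the sill correction;
#'   `max_lag` defaults to half the maximum pairwise distance.
#' @param family variogram family for the correction fits.
#' @return list of class `std_residuals`: `z` (standardized residuals),
#'   `sigma` (corrected proxy sd, kg/m3), `coords`, `correction` (the
#'   sqrt-initial-sill factor), `variogram` (fit after re-standardization),
#'   `initial_variogram`.
#' @export
standardize_residuals <- function(obs, pred, p025, p975, coords,
                                  n_bins = 12, max_lag = NULL,
                                  family = "exponential") {
  if (any(p975 <= p025)) {
    stop("degenerate intervals: p975 must exceed p025", call. = FALSE)
  }
  coords <- as.matrix(as.data.frame(coords))
  sigma <- (p975 - p025) / 4
  z <- (pred - obs) / sigma
  ev <- empirical_variogram(coords, z, n_bins = n_bins, max_lag = max_lag)
  fit0 <- fit_variogram_model(ev, family = family)
  correction <- sqrt(fit0$sill)
  sigma <- sigma * correction
  z <- (pred - obs) / sigma
  ev2 <- empirical_variogram(coords, z, n_bins = n_bins, max_lag = max_lag)
  fit1 <- fit_variogram_model(ev2, family = family)
  structure(list(z = z, sigma = sigma, coords = coords,
                 correction = correction, variogram = fit1,
                 initial_variogram = fit0),
            class = "std_residuals")
}

#' Empirical (Matheron) variogram
#'
#' `gamma(h) = (1 / 2N(h)) * sum (z_i - z_j)^2` over point pairs whose
#' separation falls in each lag bin.
#'
#' @param coords two-column matrix of planar coordinates, m.
#' @param z values at the points.
#' @param n_bins number of equal-width lag bins up to `max_lag`.
#' @param max_lag maximum lag, m; default half the maximum pair distance.
#' @return data frame of class `empirical_variogram`: `h` (mean pair
#'   distance per bin), `gamma`, `count`; empty bins are dropped.
#' @export
empirical_variogram <- function(coords, z, n_bins = 12, max_lag = NULL) {
  coords <- as.matrix(as.data.frame(coords))
  n <- nrow(coords)
  if (n < 30) stop("need at least 30 points", call. = FALSE)
  d <- as.vector(stats::dist(coords))
  if (is.null(max_lag)) max_lag <- max(d) / 2
  if (max_lag <= 0) stop("max_lag must be positive", call. = FALSE)
  sq <- as.vector(stats::dist(z))^2   # (z_i - z_j)^2 over the same pairs
  keep <- d <= max_lag & d > 0
  d <- d[keep]; sq <- sq[keep]
  bin <- pmin(floor(d / (max_lag / n_bins)) + 1L, n_bins)
  out <- data.frame(
    h = as.numeric(tapply(d, bin, mean)),
    gamma = as.numeric(tapply(sq, bin, mean)) / 2,
    count = as.numeric(tapply(sq, bin, length)))
  out <- out[!is.na(out$gamma), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("empirical_variogram", "data.frame")
  out
}

# model semivariance at lags h
variogram_gamma <- function(nugget, psill, range, h, family) {
  structural <- switch(family,
    exponential = 1 - exp(-h / range),
    spherical = ifelse(h >= range, 1,
                       1.5 * h / range - 0.5 * (h / range)^3),
    stop("unknown variogram family: ", family, call. = FALSE))
  ifelse(h <= 0, 0, nugget + psill * structural)
}

#' Construct a variogram model
#'
#' @param nugget,psill,range model parameters (nugget and partial sill in
#'   variance units, range parameter in m; for the exponential family the
#'   effective range is about 3x the range parameter).
#' @param family `"exponential"` or `"spherical"`.
#' @return object of class `variogram_model` with `sill = nugget + psill`.
#' @export
variogram_model <- function(nugget, psill, range,
                            family = c("exponential", "spherical")) {
  family <- match.arg(family)
  stopifnot(nugget >= 0, psill >= 0, nugget + psill > 0, range > 0)
  structure(list(nugget = nugget, psill = psill, range = range,
                 sill = nugget + psill, family = family),
            class = "variogram_model")
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf("<variogram_model> %s: nugget %.3g, partial sill %.3g, range %.3g m\n",
              x$family, x$nugget, x$psill, x$range))
  invisible(x)
}

#' Fit a variogram model to an empirical variogram
#'
#' Weighted least squares with pair counts as weights, over nugget,
#' partial sill and range (bounded optimization from moment-based starts).
#'
#' @param empirical an [empirical_variogram()] result.
#' @param family `"exponential"` or `"spherical"`.
#' @return a [variogram_model()] with `convergence` and `objective`
#'   diagnostics attached.
#' @export
fit_variogram_model <- function(empirical,
                                family = c("exponential", "spherical")) {
  family <- match.arg(family)
  ev <- empirical[empirical$count > 0, , drop = FALSE]
  if (nrow(ev) < 4) stop("need at least 4 nonempty bins", call. = FALSE)
  obj <- function(p) {
    g <- variogram_gamma(p[1], p[2], p[3], ev$h, family)
    sum(ev$count * (ev$gamma - g)^2)
  }
  s0 <- mean(utils::tail(ev$gamma, 3))
  n0 <- max(min(ev$gamma[1], s0), 0)
  # optimize on transformed parameters: log for nugget/partial sill
  # (positive, nugget may approach 0) and a logistic map bounding the range
  # to 2x the maximum lag — beyond that a flat variogram makes the
  # (psill, range) pair unidentifiable and the sill diverges
  eps <- 1e-10
  max_h <- max(ev$h)
  obj_t <- function(q) {
    obj(c(exp(q[1]) - eps, exp(q[2]), 2 * max_h * stats::plogis(q[3])))
  }
  start <- c(log(max(0.5 * n0, 1e-4) + eps),
             log(max(s0 - 0.5 * n0, 0.1 * s0)),
             stats::qlogis(1 / 6))
  fit <- stats::optim(start, obj_t, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  restarts <- 0
  while (fit$convergence != 0 && restarts < 3) {   # restart from the best point
    fit <- stats::optim(fit$par, obj_t, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-10))
    restarts <- restarts + 1
  }
  if (fit$convergence != 0) {
    stop("variogram fit did not converge (code ", fit$convergence, ")",
         call. = FALSE)
  }
  p <- c(max(exp(fit$par[1]) - eps, 0), exp(fit$par[2]),
         2 * max_h * stats::plogis(fit$par[3]))
  vm <- variogram_model(p[1], p[2], p[3], family)
  vm$convergence <- fit$convergence
  vm$objective <- fit$value
  vm
}

#' Error correlation from a variogram
#'
#' `rho(h) = (sill - gamma(h)) / sill`, clipped to `[0, 1]`, with
#' `rho(0) = 1`: the nugget is read as measurement-scale noise excluded
#' from the point-to-point error correlation.
#'
#' @param model a [variogram_model()].
#' @param h separation distances, m.
#' @return correlations in `[0, 1]`.
#' @export
correlation_from_variogram <- function(model, h) {
  g <- variogram_gamma(model$nugget, model$psill, model$range, h,
                       model$family)
  rho <- (model$sill - g) / model$sill
  rho <- pmin(pmax(rho, 0), 1)
  rho[h <= 0] <- 1
  rho
}

#' Model-based uncertainty of a spatial aggregate
#'
#' The aggregate mean over an AOI is the mean prediction inside it; its
#' model-based standard deviation accounts for spatial autocorrelation of
#' the map errors:
#' `sd_MB = sqrt( (1/|B|^2) * sum_s sum_u sigma(s) sigma(u) rho(|s-u|) )`
#' where the double sum runs over `|B|` discretization points, one drawn
#' at random from each cell of a coarse grid (default 500 m) intersecting
#' the AOI, `sigma(.)` is the pixel error sd surface and `rho` the error
#' correlation from the residual variogram. Correlated errors average out
#' slowly (`rho == 1` gives no reduction); independent errors shrink as
#' `1/sqrt(|B|)`.
#'
#' @param pred_raster,sd_raster matrices of predictions and error sds on
#'   `grid_def` (`sd_raster` typically `PIW/4` times the sill correction).
#' @param grid_def the [grid_spec()] of the two rasters.
#' @param aoi_polygon two-column matrix of polygon vertices (m).
#' @param model a [variogram_model()], or a function `rho(h)` for custom
#'   correlation structures.
#' @param grid discretization cell size, m.
#' @param seed integer seed for the random point per cell.
#' @return list of class `block_estimate`: `mean`, `sd_mb`, `n_points`
#'   (`|B|`), `points`, `sigma`, `grid`.
#' @export
block_mean_sd <- function(pred_raster, sd_raster, grid_def, aoi_polygon,
                          model, grid = 500, seed = 1) {
  set.seed(seed)
  aoi <- as.matrix(aoi_polygon)
  cc <- cell_centers(grid_def)
  inside <- pracma::inpolygon(cc$x, cc$y, aoi[, 1], aoi[, 2])
  if (!any(inside)) stop("AOI does not intersect the raster", call. = FALSE)
  agg_mean <- mean(as.vector(pred_raster)[inside])

  # one random point per discretization cell, kept if inside the AOI
  xr <- range(aoi[, 1]); yr <- range(aoi[, 2])
  gx <- seq(xr[1], xr[2], by = grid)
  gy <- seq(yr[1], yr[2], by = grid)
  cells <- expand.grid(x0 = gx, y0 = gy)
  px <- cells$x0 + stats::runif(nrow(cells)) * grid
  py <- cells$y0 + stats::runif(nrow(cells)) * grid
  keep <- pracma::inpolygon(px, py, aoi[, 1], aoi[, 2])
  sig <- cell_value(grid_def, sd_raster, px[keep], py[keep])
  ok <- !is.na(sig)
  px <- px[keep][ok]; py <- py[keep][ok]; sig <- sig[ok]
  B <- length(px)
  if (B < 1) stop("no discretization points fall inside the AOI",
                  call. = FALSE)
  D <- as.matrix(stats::dist(cbind(px, py)))
  R <- if (is.function(model)) {
    matrix(model(as.vector(D)), B, B)
  } else {
    matrix(correlation_from_variogram(model, as.vector(D)), B, B)
  }
  diag(R) <- 1
  sd_mb <- sqrt(sum(outer(sig, sig) * R)) / B
  structure(list(mean = agg_mean, sd_mb = sd_mb, n_points = B,
                 points = cbind(x = px, y = py), sigma = sig, grid = grid),
            class = "block_estimate")
}

#' Design-based estimate of an aggregate mean
#'
#' Classical sample-mean standard error from measurements inside a region,
#' independent of any model:
#' `sd_DB = sqrt( sum (y_i - mean)^2 / (n (n-1)) )`.
#'
#' @param samples measured values within the region (n >= 2).
#' @return list of class `design_estimate`: `mean`, `sd_db`, `n`.
#' @export
design_based_estimate <- function(samples) {
  n <- length(samples)
  if (n < 2) stop("need at least 2 samples", call. = FALSE)
  m <- mean(samples)
  list(mean = m, sd_db = sqrt(sum((samples - m)^2) / (n * (n - 1))), n = n)
}
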