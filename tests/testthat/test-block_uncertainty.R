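test_that("the interval-width proxy sd and sill correction behave", {
  set.seed(1)
  n <- 120
  xy <- cbind(runif(n, 0, 10000), runif(n, 0, 10000))
  obs <- runif(n, 10, 30)
  pred <- obs + rnorm(n)            # residual sd 1
  # intervals of width 4 imply proxy sd exactly 1
  sr <- standardize_residuals(obs, pred, pred - 2, pred + 2, xy)
  expect_equal(sr$sigma / sr$correction, rep(1, n))
  # correctly scaled proxies need no correction
  expect_equal(sr$correction, 1, tolerance = 0.25)
  expect_equal(sr$variogram$sill, 1, tolerance = 0.3)
  # proxies understated by 2x are corrected back to a unit sill
  sr2 <- standardize_residuals(obs, pred, pred - 1, pred + 1, xy)
  expect_equal(sr2$correction, 2, tolerance = 0.5)
  expect_equal(sr2$variogram$sill, 1, tolerance = 0.3)
  expect_error(standardize_residuals(obs, pred, pred + 1, pred - 1, xy),
               "degenerate")
})

test_that("the empirical variogram matches all-pairs enumeration", {
  set.seed(2)
  n <- 40
  xy <- cbind(runif(n, 0, 100), runif(n, 0, 100))
  z <- rnorm(n)
  max_lag <- 60
  n_bins <- 5
  ev <- empirical_variogram(xy, z, n_bins = n_bins, max_lag = max_lag)
  # brute force: explicit double loop over pairs
  width <- max_lag / n_bins
  sums <- counts <- hsum <- numeric(n_bins)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    h <- sqrt(sum((xy[i, ] - xy[j, ])^2))
    if (h > max_lag || h == 0) next
    b <- min(floor(h / width) + 1, n_bins)
    sums[b] <- sums[b] + (z[i] - z[j])^2
    counts[b] <- counts[b] + 1
    hsum[b] <- hsum[b] + h
  }
  keep <- counts > 0
  expect_equal(ev$gamma, (sums / counts / 2)[keep])
  expect_equal(ev$count, counts[keep])
  expect_equal(ev$h, (hsum / counts)[keep])
})

test_that("variogram limiting cases: constant field and white noise", {
  set.seed(3)
  xy <- cbind(runif(100, 0, 1000), runif(100, 0, 1000))
  ev0 <- empirical_variogram(xy, rep(5, 100))
  expect_true(all(ev0$gamma == 0))
  evw <- empirical_variogram(xy, rnorm(100))
  expect_true(all(abs(evw$gamma - 1) < 0.6))   # flat near the unit sill
  expect_error(empirical_variogram(xy, rnorm(100), max_lag = -1), "max_lag")
  expect_error(empirical_variogram(xy[1:10, ], rnorm(10)), "30")
})

test_that("variogram fitting recovers parameters and handles flat inputs", {
  # clustered survey over a 60 km domain; median over 3 realizations
  sim_one <- function(seed) {
    set.seed(seed)
    px <- runif(100, 0, 60000); py <- runif(100, 0, 60000)
    x <- rep(px, each = 5) + rnorm(500, 0, 300)
    y <- rep(py, each = 5) + rnorm(500, 0, 300)
    D <- as.matrix(dist(cbind(x, y)))
    C <- 0.8 * exp(-D / 5000) + diag(0.2, 500)
    z <- drop(t(chol(C)) %*% rnorm(500))
    fit_variogram_model(empirical_variogram(cbind(x, y), z, n_bins = 12,
                                            max_lag = 12000))
  }
  fits <- lapply(1:3, sim_one)
  rng <- median(vapply(fits, `[[`, numeric(1), "range"))
  sill <- median(vapply(fits, `[[`, numeric(1), "sill"))
  expect_equal(rng, 5000, tolerance = 0.35)
  expect_equal(sill, 1, tolerance = 0.35)
  # fitted curve is nondecreasing in lag
  g <- socforest:::variogram_gamma(fits[[1]]$nugget, fits[[1]]$psill,
                                   fits[[1]]$range, seq(1, 20000, 500),
                                   "exponential")
  expect_true(all(diff(g) >= 0))
  # flat variogram: pure nugget (range tiny or nugget ~ sill)
  flat <- data.frame(h = c(1000, 2000, 3000, 4000, 5000),
                     gamma = rep(1, 5), count = rep(100, 5))
  class(flat) <- c("empirical_variogram", "data.frame")
  vf <- fit_variogram_model(flat)
  at_short <- socforest:::variogram_gamma(vf$nugget, vf$psill, vf$range,
                                          1000, "exponential")
  expect_equal(at_short, 1, tolerance = 0.1)
  expect_error(fit_variogram_model(flat[1:3, ]), "4 nonempty bins")
})

test_that("correlation from a variogram is the normalized sill deficit", {
  vm <- variogram_model(nugget = 0, psill = 2, range = 1000)
  # gamma = 0 -> rho = 1 (at h = 0)
  expect_equal(correlation_from_variogram(vm, 0), 1)
  # gamma = sill -> rho = 0 (far field)
  expect_equal(correlation_from_variogram(vm, 1e9), 0, tolerance = 1e-6)
  # hand arithmetic: sill 2, gamma 0.5 -> 0.75
  h <- -vm$range * log(1 - 0.5 / vm$psill)
  expect_equal(correlation_from_variogram(vm, h), 0.75)
  # clipping keeps rho in [0, 1]
  expect_true(all(correlation_from_variogram(vm, c(0, 10, 1e5)) >= 0))
  expect_true(all(correlation_from_variogram(vm, c(0, 10, 1e5)) <= 1))
})

test_that("block aggregation limits: |B| = 1, full and zero correlation", {
  g <- grid_spec(20, 20, 500)
  pred <- matrix(25, 20, 20)
  sdr <- matrix(2, 20, 20)
  aoi <- cbind(x = c(1000, 9000, 9000, 1000), y = c(1000, 1000, 9000, 9000))
  rho1 <- function(h) rep(1, length(h))
  rho0 <- function(h) ifelse(h == 0, 1, 0)
  # |B| = 1: sd equals sigma at the sampled point
  b1 <- block_mean_sd(pred, sdr, g, aoi, rho0, grid = 8000, seed = 1)
  expect_equal(b1$n_points, 1)
  expect_equal(b1$sd_mb, 2)
  # rho == 1 with equal sigma: no reduction
  bf <- block_mean_sd(pred, sdr, g, aoi, rho1, grid = 1000, seed = 1)
  expect_equal(bf$sd_mb, 2, tolerance = 1e-12)
  expect_equal(bf$mean, 25)
  # rho == 0 with equal sigma: sigma / sqrt(|B|)
  b0 <- block_mean_sd(pred, sdr, g, aoi, rho0, grid = 1000, seed = 1)
  expect_equal(b0$sd_mb, 2 / sqrt(b0$n_points), tolerance = 1e-12)
  expect_error(block_mean_sd(pred, sdr, g,
                             cbind(c(1e6, 2e6, 2e6), c(1e6, 1e6, 2e6)),
                             rho0), "intersect")
})

test_that("block sd equals the brute-force double loop and is monotone in range", {
  set.seed(6)
  g <- grid_spec(20, 20, 500)
  pred <- matrix(runif(400, 10, 40), 20, 20)
  # a smooth error-sd surface, as PIW/4 maps are in practice
  sdr <- outer(seq(1, 3, length.out = 20), seq(1, 2, length.out = 20))
  aoi <- cbind(x = c(500, 8000, 9500, 2000), y = c(1000, 500, 9000, 8500))
  vm <- variogram_model(0.2, 0.8, 2000)
  be <- block_mean_sd(pred, sdr, g, aoi, vm, grid = 800, seed = 2)
  expect_lte(be$n_points, 200)
  # oracle: explicit double loop over the same discretization points
  acc <- 0
  for (i in seq_len(be$n_points)) for (j in seq_len(be$n_points)) {
    h <- sqrt(sum((be$points[i, ] - be$points[j, ])^2))
    rho <- if (h <= 0) 1 else correlation_from_variogram(vm, h)
    acc <- acc + be$sigma[i] * be$sigma[j] * rho
  }
  expect_equal(be$sd_mb, sqrt(acc) / be$n_points, tolerance = 1e-12)
  # sd_mb never exceeds the mean sigma, and grows with the variogram range
  expect_lte(be$sd_mb, mean(be$sigma))
  sds <- vapply(c(100, 1000, 10000), function(r) {
    block_mean_sd(pred, sdr, g, aoi, variogram_model(0.2, 0.8, r),
                  grid = 800, seed = 2)$sd_mb
  }, numeric(1))
  expect_true(all(diff(sds) > 0))
  # different discretization seeds agree within 5%
  be2 <- block_mean_sd(pred, sdr, g, aoi, vm, grid = 800, seed = 99)
  expect_equal(be2$sd_mb, be$sd_mb, tolerance = 0.05)
})

test_that("design-based estimates match hand arithmetic", {
  db <- design_based_estimate(c(1, 2, 3))
  expect_equal(db$mean, 2)
  expect_equal(db$sd_db, sqrt(2 / 6))
  expect_equal(design_based_estimate(rep(7, 10))$sd_db, 0)
  expect_error(design_based_estimate(5), "2 samples")
  # sd of the mean shrinks like 1/sqrt(n)
  set.seed(8)
  y <- rnorm(4000)
  s1 <- design_based_estimate(y[1:1000])$sd_db
  s4 <- design_based_estimate(y)$sd_db
  expect_equal(s4 / s1, 0.5, tolerance = 0.1)
})
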