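#' Define a synthetic 3D+T scenario
#'
#' A scenario fixes everything the generator needs: grid geometry, years,
#' feature counts, the spatial correlation range of the Gaussian random
#' fields, the depth-decay rate of the latent SOCD surface, the noise model
#' and the sampling design. Defaults describe a mid-sized landscape (60 km
#' square at 1 km resolution over five years) with a right-skewed,
#' depth-declining SOCD field and moderately clustered sampling, the
#' qualitative structure observed in harmonized continental soil data.
#'
#' @param ncols,nrows,cell grid geometry (cells and cell size in m).
#' @param years integer calendar years covered by the dynamic layers.
#' @param n_static,n_dynamic counts of static and per-year dynamic features.
#' @param n_informative number of features with nonzero effect
#'   (`<= n_static + n_dynamic`).
#' @param informative_on where informative features live: `"both"`
#'   (alternating static/dynamic), `"static"`, or `"dynamic"`.
#' @param field_range spatial correlation range of the exponential-covariance
#'   feature fields, m.
#' @param ar1_persistence AR(1) coefficient of dynamic layers across years;
#'   1 = constant in time, 0 = independent years.
#' @param depth_decay decay rate k (1/cm) of the latent log1p-SOCD with depth.
#' @param intercept latent log1p-scale intercept.
#' @param beta_max,beta_decay effect sizes: informative feature j gets
#'   `|beta_j| = beta_max * beta_decay^(j-1)` with alternating signs.
#' @param noise_sd baseline observation noise sd on the log1p scale.
#' @param heteroscedastic if `TRUE`, noise sd grows linearly with the latent
#'   value: `sd = noise_sd + hetero_slope * log1p(socd_true)`.
#' @param hetero_slope slope of the heteroscedastic noise model.
#' @param cluster_fraction fraction of sample locations drawn from a
#'   parent-offspring cluster process (the rest are uniform).
#' @param cluster_sd within-cluster Gaussian spread, m.
#' @param pseudo_zero_fraction fraction of points placed as pseudo-zeros on
#'   bare cells.
#' @param seed integer seed; all generator randomness derives from it.
#' @return an object of class `synth_scenario`.
#' @export
synth_scenario <- function(ncols = 60, nrows = 60, cell = 1000,
                           years = 2000:2004,
                           n_static = 3, n_dynamic = 2, n_informative = 5,
                           informative_on = c("both", "static", "dynamic"),
                           field_range = 8000, ar1_persistence = 0.8,
                           depth_decay = 0.015, intercept = 2.9,
                           beta_max = 0.45, beta_decay = 0.85,
                           noise_sd = 0.30, heteroscedastic = TRUE,
                           hetero_slope = 0.03,
                           cluster_fraction = 0.4, cluster_sd = 2000,
                           pseudo_zero_fraction = 0.02, seed = 1) {
  informative_on <- match.arg(informative_on)
  stopifnot(n_static >= 0, n_dynamic >= 0, n_static + n_dynamic >= 1,
            n_informative >= 0, n_informative <= n_static + n_dynamic,
            length(years) >= 1, cluster_fraction >= 0, cluster_fraction <= 1,
            pseudo_zero_fraction >= 0, pseudo_zero_fraction < 1)
  structure(as.list(environment()), class = "synth_scenario")
}

# --- Gaussian random field via circulant embedding (FFT spectral method) ---
# Exponential covariance exp(-d / range); negative embedding eigenvalues are
# clipped, a standard approximation. Returned field is standardized later.
grf_field <- function(nrows, ncols, cell, range) {
  if (range <= 0) return(matrix(stats::rnorm(nrows * ncols), nrows, ncols))
  M <- 2^ceiling(log2(2 * nrows))
  N <- 2^ceiling(log2(2 * ncols))
  dy <- pmin(0:(M - 1), M - (0:(M - 1))) * cell
  dx <- pmin(0:(N - 1), N - (0:(N - 1))) * cell
  D <- sqrt(outer(dy^2, dx^2, "+"))
  C <- exp(-D / range)
  lambda <- Re(stats::fft(C))
  lambda[lambda < 0] <- 0
  xi <- matrix(stats::rnorm(M * N), M, N) +
    1i * matrix(stats::rnorm(M * N), M, N)
  z <- stats::fft(sqrt(lambda) * xi, inverse = TRUE) / sqrt(M * N)
  Re(z)[seq_len(nrows), seq_len(ncols)]
}

standardize <- function(m) (m - mean(m)) / stats::sd(as.vector(m))

#' Generate correlated feature fields for a scenario
#'
#' Static layers are independent Gaussian random fields with exponential
#' covariance at the scenario's correlation range; dynamic layers evolve
#' across years by an AR(1) process with fresh field innovations. Every
#' layer is standardized to mean 0, sd 1. Two auxiliary surfaces are also
#' derived: a land-cover map (quantile classification of a hidden field
#' into cropland/grassland/woodland) and a bare-surface mask (top 3% of a
#' second hidden field), used for strata and pseudo-zeros.
#'
#' @param scenario a [synth_scenario()].
#' @return an object of class `feature_stack`: `grid`, `years`,
#'   `static` (named list of matrices), `dynamic` (per-year named lists),
#'   `land_cover` (character matrix), `bare` (logical matrix).
#' @export
make_feature_fields <- function(scenario) {
  stopifnot(inherits(scenario, "synth_scenario"))
  if (scenario$ncols < 4 || scenario$nrows < 4) {
    stop("degenerate grid: need at least 4 x 4 cells", call. = FALSE)
  }
  set.seed(scenario$seed)
  g <- grid_spec(scenario$ncols, scenario$nrows, scenario$cell)
  nr <- g$nrows; nc <- g$ncols
  f <- function() standardize(grf_field(nr, nc, g$cell, scenario$field_range))

  static <- stats::setNames(
    lapply(seq_len(scenario$n_static), function(i) f()),
    if (scenario$n_static > 0) paste0("stat", seq_len(scenario$n_static))
    else character())

  phi <- scenario$ar1_persistence
  dynamic <- list()
  state <- lapply(seq_len(scenario$n_dynamic), function(i) f())
  for (y in scenario$years) {
    if (length(dynamic) > 0 && scenario$n_dynamic > 0) {
      state <- lapply(state, function(s) {
        if (phi >= 1) s else standardize(phi * s + sqrt(1 - phi^2) * f())
      })
    }
    dynamic[[as.character(y)]] <- stats::setNames(
      state, if (scenario$n_dynamic > 0)
        paste0("dyn", seq_len(scenario$n_dynamic)) else character())
  }

  lc_field <- grf_field(nr, nc, g$cell, scenario$field_range)
  q <- stats::quantile(lc_field, c(0.45, 0.75))
  land_cover <- matrix("cropland", nr, nc)
  land_cover[lc_field > q[1]] <- "grassland"
  land_cover[lc_field > q[2]] <- "woodland"
  bare_field <- grf_field(nr, nc, g$cell, scenario$field_range)
  bare <- bare_field > stats::quantile(bare_field, 0.97)
  land_cover[bare] <- "bareland_lichens_moss"

  structure(list(grid = g, years = scenario$years, static = static,
                 dynamic = dynamic, land_cover = land_cover, bare = bare),
            class = "feature_stack")
}

#' @export
print.feature_stack <- function(x, ...) {
  cat(sprintf("<feature_stack> %d static + %d dynamic layers, years %s, %d x %d cells\n",
              length(x$static), length(x$dynamic[[1]]),
              paste(range(x$years), collapse = "-"),
              x$grid$nrows, x$grid$ncols))
  invisible(x)
}

feature_names <- function(stack) {
  c(names(stack$static), names(stack$dynamic[[1]]))
}

# nearest available year in the stack (missing years copied from neighbours)
nearest_year <- function(stack, year) {
  ys <- stack$years
  ys[which.min(abs(ys - year))]
}

#' Attach the known ground truth to a feature stack
#'
#' The latent surface on the log1p scale is
#' `intercept + sum_j beta_j f_j + lc_effect - k * depth`, truncated at 0,
#' and `socd_true = expm1(.)`. Only `n_informative` features receive a
#' nonzero coefficient (magnitudes `beta_max * beta_decay^(j-1)`,
#' alternating signs). Land-cover strata shift the mean (grassland and
#' woodland above cropland; bare surfaces pushed to ~0), and the latent
#' value declines exponentially with depth, yielding the right-skewed,
#' depth-declining response the analysis assumes.
#'
#' @param stack a [make_feature_fields()] stack.
#' @param scenario the generating [synth_scenario()].
#' @return an object of class `synth_truth` with the coefficient vector,
#'   depth-decay rate, land-cover effects and a vectorized
#'   `socd_true(x, y, year, depth)` function.
#' @export
make_truth <- function(stack, scenario) {
  nm <- feature_names(stack)
  beta <- stats::setNames(numeric(length(nm)), nm)
  k <- scenario$n_informative
  if (k > 0) {
    stat_nm <- names(stack$static)
    dyn_nm <- names(stack$dynamic[[1]])
    pool <- switch(scenario$informative_on,
      static = stat_nm,
      dynamic = dyn_nm,
      both = {
        # alternate static / dynamic for a balanced informative set
        out <- character(0); i <- 1; j <- 1
        while (length(out) < k && (i <= length(stat_nm) || j <= length(dyn_nm))) {
          if (i <= length(stat_nm)) { out <- c(out, stat_nm[i]); i <- i + 1 }
          if (length(out) < k && j <= length(dyn_nm)) {
            out <- c(out, dyn_nm[j]); j <- j + 1
          }
        }
        out
      })
    if (length(pool) < k) stop("not enough features on the requested side",
                               call. = FALSE)
    sel <- pool[seq_len(k)]
    mag <- scenario$beta_max * scenario$beta_decay^(seq_len(k) - 1)
    beta[sel] <- mag * (-1)^(seq_len(k) - 1)
  }
  lc_effects <- c(cropland = 0, grassland = 0.25, woodland = 0.45,
                  bareland_lichens_moss = -6)
  grid <- stack$grid
  linpred_cells <- function(rows, cols, year, depth) {
    y <- nearest_year(stack, year[1])
    idx <- cbind(rows, cols)
    lin <- rep(scenario$intercept, length(rows))
    for (f in names(stack$static)) lin <- lin + beta[f] * stack$static[[f]][idx]
    dl <- stack$dynamic[[as.character(y)]]
    for (f in names(dl)) lin <- lin + beta[f] * dl[[f]][idx]
    lin <- lin + lc_effects[stack$land_cover[idx]]
    lin - scenario$depth_decay * depth
  }
  socd_true <- function(x, y, year, depth) {
    ix <- cell_index(grid, x, y)
    out <- rep(NA_real_, length(x))
    for (yy in unique(year)) {
      sel <- which(year == yy & !is.na(ix$row))
      if (length(sel) == 0) next
      lin <- linpred_cells(ix$row[sel], ix$col[sel], yy, depth[sel])
      out[sel] <- expm1(pmax(lin, 0))
    }
    out
  }
  structure(list(beta = beta, depth_decay = scenario$depth_decay,
                 intercept = scenario$intercept, lc_effects = lc_effects,
                 informative = names(beta)[beta != 0],
                 socd_true = socd_true),
            class = "synth_truth")
}

#' Sample space-time-depth soil points from a synthetic landscape
#'
#' Locations come from a mixture of complete spatial randomness and a
#' parent-offspring cluster process (`cluster_fraction`); depths are
#' surface-weighted (exponential with mean 25 cm, truncated at 200 cm) so
#' most observations sit in the topsoil; observed SOCD is
#' `expm1(log1p(socd_true) + noise)` with optional heteroscedastic noise.
#' A `pseudo_zero_fraction` of points is placed on bare cells as zero-SOCD
#' surface records.
#'
#' @param stack a [make_feature_fields()] stack.
#' @param truth the matching [make_truth()] object.
#' @param n number of points.
#' @param scenario the generating [synth_scenario()].
#' @return harmonized-point data frame (`id`, `x`, `y`, `year`, `depth`,
#'   `socd`, `land_cover`, `is_pseudo_zero`, `derivation`) with the extra
#'   column `socd_true`.
#' @export
sample_points <- function(stack, truth, n, scenario) {
  stopifnot(n > 0)
  g <- stack$grid
  if (n > 50 * g$ncols * g$nrows) stop("n exceeds grid capacity", call. = FALSE)
  set.seed(scenario$seed + 1L)

  n_pz <- round(scenario$pseudo_zero_fraction * n)
  n_reg <- n - n_pz
  n_clu <- round(scenario$cluster_fraction * n_reg)
  n_uni <- n_reg - n_clu

  runif_xy <- function(m) list(x = stats::runif(m, g$xmin, g$xmax),
                               y = stats::runif(m, g$ymin, g$ymax))
  u <- runif_xy(n_uni)
  x <- u$x; y <- u$y
  if (n_clu > 0) {
    per <- 20
    n_par <- max(1L, ceiling(n_clu / per))
    par <- runif_xy(n_par)
    pid <- sample.int(n_par, n_clu, replace = TRUE)
    cx <- par$x[pid] + stats::rnorm(n_clu, 0, scenario$cluster_sd)
    cy <- par$y[pid] + stats::rnorm(n_clu, 0, scenario$cluster_sd)
    # reflect offspring back into the domain
    cx <- pmin(pmax(cx, g$xmin), g$xmax - 1e-6)
    cy <- pmin(pmax(cy, g$ymin), g$ymax - 1e-6)
    x <- c(x, cx); y <- c(y, cy)
  }
  year <- sample(scenario$years, n_reg, replace = TRUE)
  depth <- stats::qexp(stats::runif(n_reg) * stats::pexp(200, 1 / 25), 1 / 25)

  st <- truth$socd_true(x, y, year, depth)
  lt <- log1p(st)
  sd_i <- scenario$noise_sd +
    if (scenario$heteroscedastic) scenario$hetero_slope * lt else 0
  obs <- expm1(lt + stats::rnorm(n_reg, 0, sd_i))
  obs <- pmax(obs, 0)
  ix <- cell_index(g, x, y)
  lc <- stack$land_cover[cbind(ix$row, ix$col)]

  pts <- data.frame(
    id = paste0("s", seq_len(n_reg)), x = x, y = y,
    year = as.integer(year), depth = depth, socd = obs, land_cover = lc,
    is_pseudo_zero = FALSE, derivation = "eq1_mass",
    socd_true = st, stringsAsFactors = FALSE)

  if (n_pz > 0) {
    bare_cells <- which(stack$bare, arr.ind = TRUE)
    if (nrow(bare_cells) == 0) stop("no bare cells available for pseudo-zeros",
                                    call. = FALSE)
    bi <- bare_cells[sample.int(nrow(bare_cells), n_pz, replace = TRUE), ,
                     drop = FALSE]
    px <- g$xmin + (bi[, "col"] - stats::runif(n_pz)) * g$cell
    py <- g$ymin + (bi[, "row"] - stats::runif(n_pz)) * g$cell
    pz <- make_pseudo_zeros(data.frame(
      x = px, y = py, year = sample(scenario$years, n_pz, replace = TRUE)))
    pz$socd_true <- 0
    pts <- rbind(pts, pz)
  }
  rownames(pts) <- NULL
  pts
}

#' Named registry of benchmark scenarios
#'
#' Fixed study designs used throughout the test-suite and vignette:
#' \describe{
#'   \item{coverage}{well-specified heteroscedastic scenario (all 5 features
#'     informative) for prediction-interval calibration checks.}
#'   \item{selection}{5 informative among 25 features for feature-selection
#'     recovery.}
#'   \item{blocks}{dynamic-only signal with AR(1) persistence 0, so block
#'     nodes in different years carry independent errors (1/sqrt(N) checks).}
#'   \item{aggregate}{dense 500 m grid with an AOI polygon attribute for
#'     block-support aggregation.}
#' }
#'
#' @param name scenario name; `NULL` returns the full named list.
#' @param seed seed installed into the returned scenario(s).
#' @return a `synth_scenario` (or named list of them).
#' @export
make_benchmark_scenarios <- function(name = NULL, seed = 1) {
  reg <- list(
    coverage = synth_scenario(
      n_static = 3, n_dynamic = 2, n_informative = 5,
      heteroscedastic = TRUE, pseudo_zero_fraction = 0, seed = seed),
    selection = synth_scenario(
      n_static = 13, n_dynamic = 12, n_informative = 5,
      informative_on = "both", noise_sd = 0.3, heteroscedastic = FALSE,
      pseudo_zero_fraction = 0, seed = seed),
    blocks = synth_scenario(
      years = 2000:2003, n_static = 1, n_dynamic = 5, n_informative = 5,
      informative_on = "dynamic", ar1_persistence = 0, depth_decay = 0,
      noise_sd = 0.35, heteroscedastic = FALSE,
      pseudo_zero_fraction = 0, seed = seed),
    aggregate = synth_scenario(
      ncols = 80, nrows = 80, cell = 500, years = 2020,
      n_static = 4, n_dynamic = 1, n_informative = 4, field_range = 6000,
      pseudo_zero_fraction = 0, seed = seed))
  # rectangular AOI over the central 20 x 20 km of the aggregate landscape
  reg$aggregate$aoi <- cbind(x = c(10000, 30000, 30000, 10000),
                             y = c(10000, 10000, 30000, 30000))
  if (is.null(name)) return(reg)
  if (!name %in% names(reg)) stop("unknown scenario: ", name, call. = FALSE)
  reg[[name]]
}
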