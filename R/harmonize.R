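# LUCAS main land-cover classes accepted on ingest
LAND_COVERS <- c("cropland", "grassland", "woodland", "shrubland",
                 "bareland_lichens_moss", "artificial", "water_wetland",
                 "unknown")

# land covers on which a zero SOCD is physically plausible (bare surfaces)
BARE_COVERS <- "bareland_lichens_moss"

SOC_METHODS <- c("dry_combustion", "walkley_black", "springer_klee",
                 "loi", "unknown")

#' Soil organic carbon density from total bulk density (mass-based fragments)
#'
#' SOCD (kg/m3) from SOC content, total bulk density and coarse-fragment
#' mass fraction:
#' `socd = soc * bd_total * (1 - 0.01 * cf_mass)`.
#' With SOC in g/kg and BD in g/cm3 the product is directly kg/m3.
#'
#' @param soc soil organic carbon content, g/kg (>= 0).
#' @param bd_total total bulk density, g/cm3 (0, 2.8].
#' @param cf_mass coarse fragments (> 2 mm) as % of total mass, [0, 100].
#' @return SOCD in kg/m3.
#' @seealso [compute_socd_fine()] for the fine-earth variant.
#' @examples
#' compute_socd_mass(20, 1.3, 10)  # 23.4
#' @export
compute_socd_mass <- function(soc, bd_total, cf_mass) {
  check_range(soc, 0, Inf, "soc")
  check_range(bd_total, 1e-9, 2.8, "bd_total")
  check_range(cf_mass, 0, 100, "cf_mass")
  soc * bd_total * (1 - 0.01 * cf_mass)
}

#' Soil organic carbon density from fine-earth bulk density (volume fragments)
#'
#' SOCD (kg/m3) from SOC content, fine-earth bulk density and coarse-fragment
#' volume fraction: `socd = soc * bd_fine * (1 - 0.01 * cf_vol)`.
#'
#' @param soc soil organic carbon content, g/kg (>= 0).
#' @param bd_fine fine-earth bulk density, g/cm3 (0, 2.8].
#' @param cf_vol coarse fragments (> 2 mm) as % of total volume, [0, 100].
#' @return SOCD in kg/m3.
#' @examples
#' compute_socd_fine(15, 1.2, 20)  # 14.4
#' @export
compute_socd_fine <- function(soc, bd_fine, cf_vol) {
  check_range(soc, 0, Inf, "soc")
  check_range(bd_fine, 1e-9, 2.8, "bd_fine")
  check_range(cf_vol, 0, 100, "cf_vol")
  soc * bd_fine * (1 - 0.01 * cf_vol)
}

#' Harmonize SOC measurement method to dry-combustion equivalents
#'
#' Walkley-Black SOC values are multiplied by the recognized conversion
#' factor 1.3; dry combustion and Springer & Klee are treated as compatible
#' and passed through unchanged. Loss-on-ignition and unknown methods are
#' incompatible (conversion factors vary too much across studies) and raise
#' an error; upstream screening rejects such records.
#'
#' @param soc SOC content, g/kg.
#' @param method one of `"dry_combustion"`, `"walkley_black"`,
#'   `"springer_klee"`; `"loi"`/`"unknown"` are rejected.
#' @return SOC in dry-combustion-equivalent g/kg.
#' @examples
#' harmonize_soc_method(10, "walkley_black")  # 13
#' @export
harmonize_soc_method <- function(soc, method) {
  method <- as.character(method)
  bad <- !method %in% SOC_METHODS
  if (any(bad)) stop("unknown soc_method: ", method[bad][1], call. = FALSE)
  inc <- method %in% c("loi", "unknown")
  if (any(inc)) {
    stop("incompatible soc_method '", method[inc][1],
         "': no reliable conversion to dry combustion", call. = FALSE)
  }
  factor <- ifelse(method == "walkley_black", 1.3, 1.0)
  soc * factor
}

#' Harmonize depth records to a single representative depth
#'
#' A single recorded depth is used directly; where upper and lower limits
#' are recorded their midpoint is used.
#'
#' @param depth_top,depth_bottom layer limits in cm (both or neither).
#' @param depth_single single recorded depth in cm.
#' @return depth in cm.
#' @examples
#' harmonize_depth(0, 20)          # 10
#' harmonize_depth(depth_single = 5)  # 5
#' @export
harmonize_depth <- function(depth_top = NA, depth_bottom = NA,
                            depth_single = NA) {
  n <- max(length(depth_top), length(depth_bottom), length(depth_single))
  depth_top <- rep_len(depth_top, n)
  depth_bottom <- rep_len(depth_bottom, n)
  depth_single <- rep_len(depth_single, n)
  has_pair <- !is.na(depth_top) & !is.na(depth_bottom)
  if (any(has_pair & (depth_bottom < depth_top | depth_top < 0))) {
    stop("invalid depth limits: require depth_bottom >= depth_top >= 0",
         call. = FALSE)
  }
  out <- ifelse(!is.na(depth_single), depth_single,
                ifelse(has_pair, (depth_top + depth_bottom) / 2, NA_real_))
  if (anyNA(out)) stop("record lacks depth information", call. = FALSE)
  if (any(out < 0)) stop("negative depth", call. = FALSE)
  out
}

#' Screen raw soil records against the harmonization rules
#'
#' Applies the screening rules rowwise and returns a machine-readable
#' decision per record. A record is kept iff it has a sampling year and
#' coordinates, depth information, a complete SOCD triplet (either
#' `{soc, bd_total, cf_mass}` or `{soc, bd_fine, cf_vol}`), a compatible SOC
#' method, and its computed SOCD is not zero on a non-bare land cover
#' (pseudo-zeros on bare surfaces are exempt).
#'
#' @param records data frame of raw records; see [harmonize_points()] for
#'   the column contract.
#' @return character vector, `"keep"` or a rejection reason code among
#'   `missing_time`, `missing_coords`, `missing_depth`,
#'   `missing_properties`, `incompatible_method`, `zero_on_soil`.
#' @export
screen_records <- function(records) {
  n <- nrow(records)
  get <- function(nm) if (nm %in% names(records)) records[[nm]] else rep(NA, n)
  reason <- rep("keep", n)
  flag <- function(cond, code) reason <<- ifelse(reason == "keep" & cond,
                                                 code, reason)

  flag(is.na(get("year")), "missing_time")
  flag(is.na(get("x")) | is.na(get("y")), "missing_coords")
  has_depth <- !is.na(get("depth_single")) |
    (!is.na(get("depth_top")) & !is.na(get("depth_bottom")))
  flag(!has_depth, "missing_depth")

  eq1 <- !is.na(get("soc")) & !is.na(get("bd_total")) & !is.na(get("cf_mass"))
  eq2 <- !is.na(get("soc")) & !is.na(get("bd_fine")) & !is.na(get("cf_vol"))
  flag(!(eq1 | eq2), "missing_properties")

  method <- as.character(get("soc_method"))
  flag(is.na(method) | method %in% c("loi", "unknown") |
         !method %in% SOC_METHODS, "incompatible_method")

  # zero-SOCD screening needs the computed density; evaluate on survivors
  ok <- reason == "keep"
  if (any(ok)) {
    soc_h <- rep(NA_real_, n)
    soc_h[ok] <- harmonize_soc_method(get("soc")[ok], method[ok])
    socd <- rep(NA_real_, n)
    use1 <- ok & eq1
    socd[use1] <- compute_socd_mass(soc_h[use1], get("bd_total")[use1],
                                    get("cf_mass")[use1])
    use2 <- ok & !eq1 & eq2
    socd[use2] <- compute_socd_fine(soc_h[use2], get("bd_fine")[use2],
                                    get("cf_vol")[use2])
    lc <- as.character(get("land_cover"))
    flag(ok & socd == 0 & !(lc %in% BARE_COVERS), "zero_on_soil")
  }
  reason
}

#' Harmonize raw soil records into analysis-ready SOCD points
#'
#' Full ingest driver: screening, method conversion, depth midpoints and
#' SOCD derivation. Records with a complete `{soc, bd_total, cf_mass}`
#' triplet use the total-bulk-density path; otherwise the fine-earth path.
#'
#' @param records data frame with columns `id`, `x`, `y` (m, projected; or
#'   lon/lat with `lonlat = TRUE`), `year`, `soc` (g/kg), `soc_method`,
#'   `land_cover`, optional `depth_top`/`depth_bottom`/`depth_single` (cm),
#'   `bd_total`/`bd_fine` (g/cm3), `cf_mass`/`cf_vol` (%).
#' @param lonlat if `TRUE`, `x`/`y` are lon/lat degrees and are projected
#'   with [project_lonlat()].
#' @return list with `points` (harmonized data frame: `id`, `x`, `y`,
#'   `year`, `depth` cm, `socd` kg/m3, `land_cover`, `is_pseudo_zero`,
#'   `derivation`) and `rejections` (`id`, `reason`).
#' @export
harmonize_points <- function(records, lonlat = FALSE) {
  stopifnot(is.data.frame(records))
  if (!"id" %in% names(records)) records$id <- seq_len(nrow(records))
  reason <- screen_records(records)
  keep <- reason == "keep"
  rej <- data.frame(id = records$id[!keep], reason = reason[!keep],
                    stringsAsFactors = FALSE)
  r <- records[keep, , drop = FALSE]
  if (nrow(r) == 0) {
    return(list(points = empty_points(), rejections = rej))
  }
  if (lonlat) {
    p <- project_lonlat(r$x, r$y)
    r$x <- p$x; r$y <- p$y
  }
  get <- function(nm) if (nm %in% names(r)) r[[nm]] else rep(NA, nrow(r))
  depth <- harmonize_depth(get("depth_top"), get("depth_bottom"),
                           get("depth_single"))
  soc_h <- harmonize_soc_method(r$soc, as.character(r$soc_method))
  eq1 <- !is.na(get("bd_total")) & !is.na(get("cf_mass"))
  socd <- ifelse(eq1,
                 soc_h * get("bd_total") * (1 - 0.01 * get("cf_mass")),
                 soc_h * get("bd_fine") * (1 - 0.01 * get("cf_vol")))
  pts <- data.frame(
    id = r$id, x = r$x, y = r$y, year = as.integer(r$year), depth = depth,
    socd = socd, land_cover = as.character(r$land_cover),
    is_pseudo_zero = FALSE,
    derivation = ifelse(eq1, "eq1_mass", "eq2_volume"),
    stringsAsFactors = FALSE)
  list(points = pts, rejections = rej)
}

empty_points <- function() {
  data.frame(id = integer(), x = numeric(), y = numeric(), year = integer(),
             depth = numeric(), socd = numeric(), land_cover = character(),
             is_pseudo_zero = logical(), derivation = character(),
             stringsAsFactors = FALSE)
}

#' Create pseudo-zero surface points on bare locations
#'
#' Bare rock and shifting-sand locations carry no soil; placing zero-SOCD
#' surface points there teaches the model the covariate patterns of
#' non-soil environments, which otherwise tend to be overestimated.
#' Pseudo-zeros are used only at the surface (depth <= 5 cm) and only for
#' training, never for metric computation.
#'
#' @param locations data frame with `x`, `y`, `year` of bare-surface sites.
#' @param depth surface depth assigned to the points, cm; must be <= 5.
#' @return harmonized-point data frame with `socd = 0`,
#'   `is_pseudo_zero = TRUE`, `derivation = "pseudo_zero"`.
#' @export
make_pseudo_zeros <- function(locations, depth = 2.5) {
  if (depth > 5 || depth < 0) {
    stop("pseudo-zero points are surface-only: depth must be in [0, 5] cm",
         call. = FALSE)
  }
  if (nrow(locations) == 0) return(empty_points())
  data.frame(
    id = if ("id" %in% names(locations)) locations$id else
      paste0("pz", seq_len(nrow(locations))),
    x = locations$x, y = locations$y, year = as.integer(locations$year),
    depth = depth, socd = 0, land_cover = "bareland_lichens_moss",
    is_pseudo_zero = TRUE, derivation = "pseudo_zero",
    stringsAsFactors = FALSE)
}

#' Response transform for SOCD modelling
#'
#' SOCD is strongly right-skewed; models operate on the `log1p` scale and
#' predictions are back-transformed with `expm1` before presentation.
#'
#' @param socd SOCD in kg/m3 (>= 0).
#' @return transformed value, `log(1 + socd)`.
#' @examples
#' transform_response(61.95)  # 4.14 (2 dp)
#' @export
transform_response <- function(socd) {
  if (any(socd < 0, na.rm = TRUE)) {
    stop("socd must be nonnegative", call. = FALSE)
  }
  log1p(socd)
}

#' @rdname transform_response
#' @param value value on the transform (log1p) scale.
#' @export
back_transform <- function(value) expm1(value)
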