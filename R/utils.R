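# internal helpers shared across modules

check_range <- function(x, lo, hi, field, allow_na = FALSE) {
  bad <- !is.na(x) & (x < lo | x > hi)
  if (any(bad)) {
    stop(sprintf("field '%s' out of range [%g, %g]: e.g. %g",
                 field, lo, hi, x[which(bad)[1]]), call. = FALSE)
  }
  if (!allow_na && anyNA(x)) {
    stop(sprintf("field '%s' contains missing values", field), call. = FALSE)
  }
  invisible(x)
}

# feature column names carried on a regression matrix
rm_features <- function(x) {
  f <- attr(x, "features")
  if (is.null(f)) stop("object carries no 'features' attribute", call. = FALSE)
  f
}

# weighted median (linear interpolation on the weighted ECDF)
weighted_median <- function(x, w = NULL) {
  if (is.null(w)) return(stats::median(x))
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  i <- which(cw >= 0.5)[1]
  x[i]
}

# quantile label: 0.025 -> "p025", 0.975 -> "p975", 0.5 -> "p5"
prob_label <- function(p) {
  paste0("p", sub("^0\\.", "", formatC(p, format = "fg")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
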