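#' Quantile anchor sets for the study cohort
#'
#' The published cohort characteristics report, for each candidate variable,
#' its value at the 1st, 25th, 50th, 75th and 99th percentiles. These five
#' (percentile, value) pairs are the anchors from which each variable's
#' quantile function is reconstructed by piecewise-linear interpolation.
#'
#' `quantile_anchors()` builds one anchor set; `default_anchors()` returns
#' the full published set for all 19 candidate variables.
#'
#' Vigorous physical activity is heavily zero-inflated: its 1st through 75th
#' percentiles are all 0 (only participants above roughly the 80th
#' percentile performed vigorous activity), with 7200 MET-min/wk at the
#' 99th percentile.
#'
#' @param variable Variable name.
#' @param percentiles Strictly increasing percentile ranks in (0, 100).
#' @param values Matching non-decreasing values in natural units.
#' @return An object of class `quantile_anchors`.
#' @export
#' @examples
#' a <- default_anchors()
#' a$multidimensional_balance$values  # 12 28 32 35 40
quantile_anchors <- function(variable, percentiles, values) {
  stopifnot(length(percentiles) == length(values), length(values) >= 2)
  if (any(diff(percentiles) <= 0) || any(percentiles <= 0) ||
      any(percentiles >= 100)) {
    stop("percentile ranks must be strictly increasing in (0, 100)",
         call. = FALSE)
  }
  if (any(diff(values) < 0)) {
    stop("anchor values must be non-decreasing (monotone quantile function)",
         call. = FALSE)
  }
  structure(list(variable = variable,
                 percentiles = as.numeric(percentiles),
                 values = as.numeric(values)),
            class = "quantile_anchors")
}

#' @rdname quantile_anchors
#' @export
default_anchors <- function() {
  p <- c(1, 25, 50, 75, 99)
  raw <- list(
    lower_body_strength      = c(7, 13, 15, 18, 30),
    upper_body_strength      = c(6, 13, 17, 20, 29),
    lower_body_flexibility   = c(-32.0, -8.0, 0.0, 3.0, 18.5),
    upper_body_flexibility   = c(-37.0, -18.0, -10.0, -2.0, 13.0),
    agility_dynamic_balance  = c(3.9, 5.1, 5.7, 6.6, 12.2),
    aerobic_endurance        = c(240, 438, 499, 550, 714),
    multidimensional_balance = c(12, 28, 32, 35, 40),
    body_weight              = c(44.9, 61.0, 68.6, 77.4, 108.1),
    body_height              = c(137.0, 150.0, 155.0, 162.9, 176.0),
    body_mass_index          = c(20.5, 25.6, 28.0, 31.1, 39.6),
    lean_body_mass           = c(26.3, 37.1, 42.2, 48.9, 67.9),
    fat_body_mass            = c(15.5, 32.6, 38.3, 43.3, 48.5),
    walking_pa               = c(0, 297, 578, 990, 2772),
    moderate_pa              = c(0, 960, 1680, 2400, 10080),
    vigorous_pa              = c(0, 0, 0, 0, 7200),
    total_pa                 = c(170, 1646, 2473, 3884, 12797),
    rest_period_weekdays     = c(0.6, 3.0, 4.3, 5.5, 10.0),
    health_conditions        = c(0, 2, 3, 5, 12),
    environmental_hazards    = c(0, 4, 6, 9, 21)
  )
  out <- lapply(names(raw), function(v) quantile_anchors(v, p, raw[[v]]))
  names(out) <- names(raw)
  out
}

#' @export
print.quantile_anchors <- function(x, ...) {
  cat("Quantile anchors for '", x$variable, "':\n", sep = "")
  print(stats::setNames(x$values, paste0("P", x$percentiles)))
  invisible(x)
}

#' Interpolate a quantile from anchor points
#'
#' Piecewise-linear interpolation of a variable's quantile function between
#' its published percentile anchors. Exact at the anchors and monotone
#' non-decreasing in `p`.
#'
#' @param anchors A [quantile_anchors()] object.
#' @param p Percentile rank(s) in `[1, 99]`.
#' @return Interpolated value(s) in the variable's natural units.
#' @export
#' @examples
#' a <- default_anchors()
#' interp_quantile(a$multidimensional_balance, 50)  # 32
#' interp_quantile(a$multidimensional_balance, 45)  # 31.2
interp_quantile <- function(anchors, p) {
  stopifnot(inherits(anchors, "quantile_anchors"))
  lo <- min(anchors$percentiles)
  hi <- max(anchors$percentiles)
  if (any(!is.finite(p)) || any(p < lo) || any(p > hi)) {
    stop("percentile rank must lie within [", lo, ", ", hi, "]",
         call. = FALSE)
  }
  stats::approx(anchors$percentiles, anchors$values, xout = p,
                ties = "ordered")$y
}

# Internal: quantile function extended beyond the outermost anchors for
# sampling. Below the first / above the last anchor the nearest segment's
# slope is continued linearly; the result is truncated at the variable's
# physical bounds. Degenerate (zero-length or flat) edge segments extend
# as constants.
extended_quantile <- function(anchors, p, lower = -Inf, upper = Inf) {
  pc <- anchors$percentiles
  v <- anchors$values
  k <- length(pc)
  out <- numeric(length(p))
  inside <- p >= pc[1] & p <= pc[k]
  if (any(inside)) {
    out[inside] <- stats::approx(pc, v, xout = p[inside],
                                 ties = "ordered")$y
  }
  slope_lo <- (v[2] - v[1]) / (pc[2] - pc[1])
  slope_hi <- (v[k] - v[k - 1]) / (pc[k] - pc[k - 1])
  below <- p < pc[1]
  above <- p > pc[k]
  out[below] <- v[1] + slope_lo * (p[below] - pc[1])
  out[above] <- v[k] + slope_hi * (p[above] - pc[k])
  pmin(pmax(out, lower), upper)
}
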