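#' Probability cutoffs for the four risk strata
#'
#' The probability-of-falling cutoffs that define the four risk strata:
#' low risk \eqn{\pi < 0.25}; moderate \eqn{0.25 \le \pi <} the
#' sensitivity+specificity-maximizing cutoff (study value 0.35939); high
#' risk up to \eqn{\pi < 0.50}; very high \eqn{\pi \ge 0.50}.
#'
#' @param low_mod Low/moderate probability boundary (default 0.25).
#' @param mod_high Moderate/high boundary (default the study's Youden
#'   cutoff 0.35939; in "re-derive" mode pass the Youden cutoff computed
#'   from a cohort).
#' @param high_vhigh High/very-high boundary (default 0.50).
#' @return A `cut_probabilities` list.
#' @export
cut_probabilities <- function(low_mod = 0.25, mod_high = 0.35939,
                              high_vhigh = 0.50) {
  if (!(low_mod > 0 && low_mod < mod_high && mod_high < high_vhigh &&
        high_vhigh < 1)) {
    stop("need 0 < low_mod < mod_high < high_vhigh < 1", call. = FALSE)
  }
  structure(list(low_mod = low_mod, mod_high = mod_high,
                 high_vhigh = high_vhigh),
            class = "cut_probabilities")
}

# Internal: check that model coefficient signs agree with registry
# directions for the key factors, so the joint profile probability is
# monotone; names the offending factor otherwise.
assert_sign_consistent <- function(model, registry = variable_registry()) {
  dirs <- registry$direction[match(model$variables, registry$name)]
  bad <- model$variables[(dirs == "protective" & model$coefficients > 0) |
                           (dirs == "risk" & model$coefficients < 0)]
  bad <- bad[!is.na(bad)]
  if (length(bad) > 0) {
    stop("model sign inconsistent with risk direction for: ",
         paste(bad, collapse = ", "),
         "; joint-profile probability would not be monotone",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Build the joint risk profile at percentile p
#'
#' The joint risk profile places every protective key factor
#' (multidimensional balance, lean body mass, total physical activity) at
#' its own percentile `p` and every risk factor (fat body mass, rest
#' period, health conditions, environmental hazards) at percentile
#' `100 - p`, so the whole vector describes one coherent "better/worse"
#' axis: large `p` is a fit, low-risk profile. Vigorous physical activity
#' is 0 throughout the stratification range (only participants above
#' roughly the 80th percentile performed any). Quantiles are interpolated
#' linearly from the published anchors; physical activity is converted to
#' 100 MET-min/wk model units.
#'
#' @param anchors Named list of [quantile_anchors()].
#' @param registry Variable registry.
#' @param p Percentile in `[1, 99]`.
#' @return Named numeric vector over the eight key factors (PA variables in
#'   100 MET-min/wk model units).
#' @export
#' @examples
#' round(build_profile(p = 45), 3)
build_profile <- function(anchors = default_anchors(),
                          registry = variable_registry(), p) {
  stopifnot(length(p) == 1)
  if (!is.finite(p) || p < 1 || p > 99) {
    stop("percentile must lie within [1, 99]", call. = FALSE)
  }
  keys <- key_factor_names()
  out <- vapply(keys, function(v) {
    if (v == "vigorous_pa") return(0)
    i <- match(v, registry$name)
    side <- if (registry$direction[i] == "protective") p else 100 - p
    interp_quantile(anchors[[v]], side) * registry$model_scale[i]
  }, numeric(1))
  out
}

#' Fall probability along the joint risk profile
#'
#' Evaluates the fall model at [build_profile()] for percentile `p`. By
#' construction (protective coefficients negative, risk coefficients
#' positive, quantiles monotone) the probability is decreasing in `p`.
#'
#' @param model A `fitted_logistic_model` over the eight key factors
#'   (default: the published equation with intercept 0).
#' @param anchors Named list of [quantile_anchors()].
#' @param registry Variable registry.
#' @param p Percentile in `[1, 99]`.
#' @return Fall probability in (0, 1).
#' @export
#' @examples
#' profile_probability(p = 45)  # ~0.3599, the study's 0.35939 cutoff
profile_probability <- function(model = fall_model(),
                                anchors = default_anchors(),
                                registry = variable_registry(), p) {
  assert_sign_consistent(model, registry)
  prof <- build_profile(anchors, registry, p)
  eta <- model$intercept +
    sum(model$coefficients[model$variables] * prof[model$variables])
  stats::plogis(eta)
}

#' Invert the profile probability for a cut probability
#'
#' Finds, by bisection, the percentile `p*` at which the fall probability
#' along the joint risk profile equals the cut probability `c`; unique by
#' monotonicity. Protective factors are then read at `p*`, risk factors at
#' `100 - p*` (complement symmetry).
#'
#' @param model A `fitted_logistic_model` (default the published equation).
#' @param anchors Named list of [quantile_anchors()].
#' @param registry Variable registry.
#' @param c Cut probability, strictly between the attainable extremes
#'   `profile_probability(p = 99)` and `profile_probability(p = 1)`.
#' @param tol Bisection tolerance on `|pi - c|`.
#' @return The percentile root `p*`.
#' @export
#' @examples
#' solve_percentile(c = 0.35939)  # ~45
solve_percentile <- function(model = fall_model(),
                             anchors = default_anchors(),
                             registry = variable_registry(), c,
                             tol = 1e-10) {
  f <- function(p) profile_probability(model, anchors, registry, p)
  pi_hi <- f(1); pi_lo <- f(99)
  if (!(c > pi_lo && c < pi_hi)) {
    stop("cut probability ", c, " outside the attainable range (",
         format(pi_lo, digits = 6), ", ", format(pi_hi, digits = 6), ")",
         call. = FALSE)
  }
  lo <- 1; hi <- 99
  repeat {
    mid <- (lo + hi) / 2
    val <- f(mid)
    if (abs(val - c) < tol || (hi - lo) < 1e-13) return(mid)
    if (val > c) lo <- mid else hi <- mid  # f decreasing in p
  }
}

# Internal: round a boundary to a factor's presentation precision.
# Physical activity presents as hundreds of MET-min/wk, rounded up.
round_boundary <- function(x, precision) {
  if (precision == 100) met_round_up_hundred(x)
  else round(x / precision) * precision
}

# Internal: stratum of value v given rounded boundaries r = c(r1, r2, r3)
# in risk order and the factor direction. A value equal to a rounded
# boundary falls in the riskier stratum of that cut; when two boundaries
# collide the shared value goes to the less risky of the claimants
# (checked in increasing-risk order).
classify_from_boundaries <- function(v, r, direction) {
  if (direction == "protective") {
    if (v > r[1]) "low"
    else if (v > r[2] || v == r[1]) "moderate"
    else if (v > r[3] || v == r[2]) "high"
    else "very_high"
  } else {
    if (v < r[1]) "low"
    else if (v < r[2] || v == r[1]) "moderate"
    else if (v < r[3] || v == r[2]) "high"
    else "very_high"
  }
}

#' Derive per-factor stratified cutoffs from the fall model
#'
#' The core stratification step: each probability cutoff is inverted along
#' the joint risk-profile percentile curve ([solve_percentile()]), and
#' every key factor is evaluated at its own side of the profile
#' (protective factors at `p*`, risk factors at `100 - p*`), yielding
#' three continuous boundaries per factor. Boundaries are then rounded to
#' the factor's presentation precision (integers for balance, lean mass,
#' fat mass and the two counts; one decimal for the rest period; hundreds
#' of MET-min/wk, rounded up, for total physical activity), and the four
#' presented strata follow from the rounded boundaries with the
#' boundary-in-the-riskier-stratum closure. Vigorous physical activity is
#' identically zero over the relevant percentile band and is therefore
#' excluded from the cutoff table (while remaining in the model).
#'
#' @param model A `fitted_logistic_model` (default the published equation
#'   with intercept 0, "reproduce" mode).
#' @param anchors Named list of [quantile_anchors()].
#' @param registry Variable registry.
#' @param cuts A [cut_probabilities()].
#' @return A `cutoff_table`: per factor, the percentile roots, continuous
#'   and rounded boundaries (risk-ordered: low/moderate, moderate/high,
#'   high/very-high), direction and precision.
#' @export
#' @examples
#' tab <- derive_cutoffs()
#' tab$factors$lean_body_mass$rounded  # 44 41 39
derive_cutoffs <- function(model = fall_model(),
                           anchors = default_anchors(),
                           registry = variable_registry(),
                           cuts = cut_probabilities()) {
  assert_sign_consistent(model, registry)
  cut_probs <- c(low_mod = cuts$low_mod, mod_high = cuts$mod_high,
                 high_vhigh = cuts$high_vhigh)
  p_star <- vapply(cut_probs, function(cc) {
    solve_percentile(model, anchors, registry, cc)
  }, numeric(1))
  factors <- setdiff(key_factor_names(), "vigorous_pa")
  fac_list <- lapply(factors, function(v) {
    i <- match(v, registry$name)
    dir <- registry$direction[i]
    side <- if (dir == "protective") p_star else 100 - p_star
    cont <- vapply(side, function(pp) interp_quantile(anchors[[v]], pp),
                   numeric(1))
    rounded <- vapply(cont, round_boundary,
                      precision = registry$precision[i], numeric(1))
    list(factor = v, label = registry$label[i], units = registry$units[i],
         direction = dir, precision = registry$precision[i],
         p_star = stats::setNames(side, names(cut_probs)),
         continuous = stats::setNames(cont, names(cut_probs)),
         rounded = stats::setNames(rounded, names(cut_probs)))
  })
  names(fac_list) <- factors
  structure(list(cuts = cuts,
                 p_star_protective = p_star,
                 p_star_risk = 100 - p_star,
                 factors = fac_list,
                 source = "derived"),
            class = "cutoff_table")
}

#' Published interval reference values
#'
#' The published per-factor reference intervals for stratified fall risk,
#' encoded verbatim as rounded boundaries under the same closure convention
#' used by [derive_cutoffs()] (e.g. multidimensional balance: low > 33,
#' moderate 32-33, high 30-31, very high < 30). Useful for profiling
#' individuals against the published table rather than a re-derived one.
#'
#' @return A `cutoff_table` with `source = "published"`.
#' @export
published_cutoffs <- function() {
  reg <- variable_registry()
  spec <- list(
    multidimensional_balance = c(33, 31, 29),
    lean_body_mass           = c(44, 41, 38),
    fat_body_mass            = c(37, 39, 43),
    total_pa                 = c(2800, 2300, 1800),
    rest_period_weekdays     = c(4.0, 4.5, 5.1),
    health_conditions        = c(3, 4, 6),
    environmental_hazards    = c(5, 6, 9)
  )
  fac_list <- lapply(names(spec), function(v) {
    i <- match(v, reg$name)
    list(factor = v, label = reg$label[i], units = reg$units[i],
         direction = reg$direction[i], precision = reg$precision[i],
         p_star = c(low_mod = NA_real_, mod_high = NA_real_,
                    high_vhigh = NA_real_),
         continuous = c(low_mod = NA_real_, mod_high = NA_real_,
                        high_vhigh = NA_real_),
         rounded = stats::setNames(spec[[v]],
                                   c("low_mod", "mod_high", "high_vhigh")))
  })
  names(fac_list) <- names(spec)
  structure(list(cuts = cut_probabilities(),
                 p_star_protective = c(low_mod = NA_real_,
                                       mod_high = NA_real_,
                                       high_vhigh = NA_real_),
                 p_star_risk = c(low_mod = NA_real_, mod_high = NA_real_,
                                 high_vhigh = NA_real_),
                 factors = fac_list,
                 source = "published"),
            class = "cutoff_table")
}

# Internal: representable interval (lo, hi) of each stratum for a factor
# entry, consistent with classify_from_boundaries. Extreme strata extend
# to +/-Inf; an empty stratum gets NA bounds.
stratum_intervals <- function(entry) {
  r <- entry$rounded
  s <- entry$precision
  grid <- seq(min(r) - 2 * s, max(r) + 2 * s, by = s)
  grid <- round(grid / s) * s  # guard against fp drift in seq()
  cls <- vapply(grid, classify_from_boundaries, r = r,
                direction = entry$direction, FUN.VALUE = character(1))
  strata <- c("low", "moderate", "high", "very_high")
  out <- lapply(strata, function(st) {
    vals <- grid[cls == st]
    if (length(vals) == 0) return(c(lo = NA_real_, hi = NA_real_))
    lo <- min(vals); hi <- max(vals)
    # extend the outermost strata to infinity
    if (lo == min(grid)) lo <- -Inf
    if (hi == max(grid)) hi <- Inf
    c(lo = lo, hi = hi)
  })
  names(out) <- strata
  out
}

#' Render a cutoff table
#'
#' Produces the presented four-interval reference values per factor (e.g.
#' "low: > 33; moderate: 32-33; high: 30-31; very high: < 30") at each
#' factor's precision, together with a machine-readable data frame.
#'
#' @param table A `cutoff_table` from [derive_cutoffs()] or
#'   [published_cutoffs()].
#' @return A data frame with one row per factor and stratum (`factor`,
#'   `stratum`, `lo`, `hi`, `text`), with the full per-factor report lines
#'   in `attr(, "report")`.
#' @export
present_cutoffs <- function(table) {
  stopifnot(inherits(table, "cutoff_table"))
  fmt <- function(x, s) {
    if (s == 0.1) sprintf("%.1f", x) else sprintf("%.0f", x)
  }
  rows <- list()
  report <- character()
  for (entry in table$factors) {
    iv <- stratum_intervals(entry)
    s <- entry$precision
    pieces <- character()
    for (st in names(iv)) {
      lo <- iv[[st]]["lo"]; hi <- iv[[st]]["hi"]
      txt <- if (is.na(lo)) {
        "(empty)"
      } else if (is.infinite(lo) && is.infinite(hi)) {
        "any value"
      } else if (is.infinite(lo)) {
        paste0("< ", fmt(hi + s, s))
      } else if (is.infinite(hi)) {
        paste0("> ", fmt(lo - s, s))
      } else if (lo == hi) {
        paste0("= ", fmt(lo, s))
      } else {
        paste0(fmt(lo, s), "-", fmt(hi, s))
      }
      rows[[length(rows) + 1]] <- data.frame(
        factor = entry$factor, stratum = st,
        lo = unname(lo), hi = unname(hi), text = txt,
        stringsAsFactors = FALSE)
      pieces <- c(pieces, paste0(sub("_", " ", st), " risk: ", txt))
    }
    report <- c(report, paste0(entry$label, " (", entry$units, "): ",
                               paste(pieces, collapse = ", ")))
  }
  out <- do.call(rbind, rows)
  attr(out, "report") <- report
  out
}

#' @export
print.cutoff_table <- function(x, ...) {
  cat("Stratified fall-risk cutoffs (", x$source, ")\n", sep = "")
  if (!anyNA(x$p_star_protective)) {
    cat("percentile roots (protective side): ",
        paste(sprintf("%s=%.2f", names(x$p_star_protective),
                      x$p_star_protective), collapse = ", "), "\n", sep = "")
  }
  cat(paste(attr(present_cutoffs(x), "report"), collapse = "\n"), "\n")
  invisible(x)
}
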