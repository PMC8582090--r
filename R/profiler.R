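#' Classify one factor value into a risk stratum
#'
#' Looks up which presented interval of the cutoff table contains the
#' value. Values outside the factor's plausible range are clamped to it
#' with a warning.
#'
#' @param value Measurement in natural units.
#' @param factor Factor name (e.g. `"multidimensional_balance"`).
#' @param cutoff_table A `cutoff_table` from [derive_cutoffs()] or
#'   [published_cutoffs()].
#' @param registry Variable registry (for the plausible range).
#' @return One of `"low"`, `"moderate"`, `"high"`, `"very_high"`.
#' @export
#' @examples
#' classify_factor(29, "multidimensional_balance", published_cutoffs())
classify_factor <- function(value, factor, cutoff_table,
                            registry = variable_registry()) {
  entry <- cutoff_table$factors[[factor]]
  if (is.null(entry)) {
    stop("factor '", factor, "' is not in the cutoff table", call. = FALSE)
  }
  i <- match(factor, registry$name)
  lo <- registry$lower[i]; hi <- registry$upper[i]
  if (value < lo || value > hi) {
    warning("value ", value, " outside the plausible range [", lo, ", ",
            hi, "] for ", factor, "; clamped", call. = FALSE)
    value <- min(max(value, lo), hi)
  }
  classify_from_boundaries(value, entry$rounded, entry$direction)
}

#' Individual fall probability
#'
#' Evaluates the fall model for one person from measurements in natural
#' units (MET-min/wk for physical activity; the conversion to 100
#' MET-min/wk model units is applied internally). With the published
#' equation the intercept is 0 ("reproduce" mode).
#'
#' @param model A `fitted_logistic_model` (default the published equation).
#' @param measurements Named list or vector covering every model variable.
#' @param registry Variable registry.
#' @return Fall probability in (0, 1).
#' @export
#' @examples
#' median_person <- c(multidimensional_balance = 32, lean_body_mass = 42.2,
#'   fat_body_mass = 38.3, total_pa = 2473, vigorous_pa = 0,
#'   rest_period_weekdays = 4.3, health_conditions = 3,
#'   environmental_hazards = 6)
#' individual_probability(measurements = median_person)  # ~0.309
individual_probability <- function(model = fall_model(), measurements,
                                   registry = variable_registry()) {
  m <- as.list(measurements)
  missing_vars <- setdiff(model$variables, names(m))
  if (length(missing_vars) > 0) {
    stop("missing factor(s): ", paste(missing_vars, collapse = ", "),
         call. = FALSE)
  }
  data <- as.data.frame(m[model$variables])
  predict_probability(model, data, registry)
}

#' Minimum improvements to reach lower-risk strata
#'
#' For a factor value, computes the minimum change - in the factor's
#' representable precision steps (1 point, 1 kg, 1 %, 100 MET-min/wk,
#' 0.1 hr, 1 count) - that moves the value into each strictly lower-risk
#' stratum, all other factors untouched. Deltas are sign-aware: positive
#' for protective factors (increase the value), negative for risk factors
#' (decrease it). A factor already at low risk yields an empty result;
#' an empty stratum is skipped.
#'
#' @param value Measurement in natural units.
#' @param factor Factor name.
#' @param cutoff_table A `cutoff_table`.
#' @param registry Variable registry.
#' @return Named numeric of signed deltas (names: target strata).
#' @export
#' @examples
#' improvement_deltas(29, "multidimensional_balance", published_cutoffs())
#' # high +1, moderate +3, low +5
improvement_deltas <- function(value, factor, cutoff_table,
                               registry = variable_registry()) {
  entry <- cutoff_table$factors[[factor]]
  if (is.null(entry)) {
    stop("factor '", factor, "' is not in the cutoff table", call. = FALSE)
  }
  s <- entry$precision
  d <- if (entry$direction == "protective") 1 else -1
  strata <- c("low", "moderate", "high", "very_high")
  current <- classify_factor(value, factor, cutoff_table, registry)
  better <- strata[seq_len(match(current, strata) - 1)]
  if (length(better) == 0) return(stats::setNames(numeric(0), character(0)))
  r <- entry$rounded
  k_max <- ceiling((max(r) - min(r)) / s) + ceiling(abs(value - min(r)) / s) + 4
  out <- numeric(0)
  for (target in rev(better)) {  # nearest (least ambitious) first
    hit <- NA_real_
    for (k in seq_len(k_max)) {
      if (classify_from_boundaries(value + d * k * s, r,
                                   entry$direction) == target) {
        hit <- d * k * s
        break
      }
    }
    if (!is.na(hit)) out[target] <- hit
  }
  out
}

#' Full individual risk profile
#'
#' Aggregates the profiler: per-factor strata against the cutoff table,
#' the overall fall probability from the model, the overall stratum from
#' the probability cutoffs (half-open: low \eqn{\pi <} `low_mod`; moderate
#' up to but excluding `mod_high`; high up to but excluding `high_vhigh`;
#' very high \eqn{\pi \ge} `high_vhigh`), and the per-factor improvement
#' deltas.
#'
#' @param model A `fitted_logistic_model`.
#' @param cutoff_table A `cutoff_table`.
#' @param measurements Named list/vector in natural units covering every
#'   model variable.
#' @param cuts A [cut_probabilities()].
#' @param registry Variable registry.
#' @return A `risk_profile` list: `inputs`, `per_factor_stratum`,
#'   `probability`, `overall_stratum`, `deltas`.
#' @export
profile_report <- function(model = fall_model(),
                           cutoff_table = published_cutoffs(),
                           measurements,
                           cuts = cut_probabilities(),
                           registry = variable_registry()) {
  prob <- individual_probability(model, measurements, registry)
  overall <- if (prob < cuts$low_mod) "low"
  else if (prob < cuts$mod_high) "moderate"
  else if (prob < cuts$high_vhigh) "high"
  else "very_high"
  factors <- names(cutoff_table$factors)
  m <- as.list(measurements)
  per_factor <- vapply(factors, function(v) {
    classify_factor(m[[v]], v, cutoff_table, registry)
  }, character(1))
  deltas <- lapply(factors, function(v) {
    as.list(improvement_deltas(m[[v]], v, cutoff_table, registry))
  })
  names(deltas) <- factors
  structure(list(inputs = m[union(model$variables, factors)],
                 per_factor_stratum = as.list(per_factor),
                 probability = prob,
                 overall_stratum = overall,
                 deltas = deltas),
            class = "risk_profile")
}

#' @export
print.risk_profile <- function(x, ...) {
  cat("Individual fall-risk profile\n")
  cat(sprintf("  fall probability: %.3f -> overall %s risk\n",
              x$probability, sub("_", " ", x$overall_stratum)))
  for (v in names(x$per_factor_stratum)) {
    line <- sprintf("  %-26s %-10s (value %s)", v,
                    sub("_", " ", x$per_factor_stratum[[v]]),
                    format(x$inputs[[v]]))
    d <- x$deltas[[v]]
    if (length(d) > 0) {
      line <- paste0(line, "  improve: ",
                     paste(sprintf("%+g to %s", unlist(d),
                                   sub("_", " ", names(d))),
                           collapse = ", "))
    }
    cat(line, "\n")
  }
  invisible(x)
}

#' Serialize / restore a risk profile as JSON
#'
#' @param profile A `risk_profile`.
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return `risk_profile_json()`: JSON string or `path`;
#'   `risk_profile_from_json()`: the restored `risk_profile`.
#' @export
risk_profile_json <- function(profile, path = NULL) {
  stopifnot(inherits(profile, "risk_profile"))
  json <- jsonlite::toJSON(unclass(profile), auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(path)
}

#' @rdname risk_profile_json
#' @param json JSON string or path produced by [risk_profile_json()].
#' @export
risk_profile_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = TRUE,
                          simplifyDataFrame = FALSE)
  x$deltas <- lapply(x$deltas, function(d) lapply(d, as.numeric))
  structure(x, class = "risk_profile")
}
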