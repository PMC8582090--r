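#' Candidate risk-factor variable registry
#'
#' Returns the registry of the 19 candidate fall-risk variables assessed in
#' the study cohort: physical fitness (Senior Fitness Test battery and the
#' Fullerton Advanced Balance scale), body composition, physical activity
#' (IPAQ metabolic expenditure), the weekday seated rest period, and counts
#' of health conditions and environmental hazards.
#'
#' Each variable carries:
#' \describe{
#'   \item{name}{canonical snake_case identifier used in cohort files}
#'   \item{label}{human-readable label}
#'   \item{units}{measurement units}
#'   \item{direction}{`"protective"` (a higher value lowers fall probability)
#'     or `"risk"` (a higher value raises it), consistent with the sign of
#'     the fitted odds ratios}
#'   \item{precision}{presentation granularity for cutoff tables: `1`
#'     (integer), `0.1` (one decimal), or `100` (hundreds of MET-min/wk)}
#'   \item{model_scale}{factor applied before model evaluation; `0.01` for
#'     the physical-activity variables so the model sees 100 MET-min/wk
#'     units, `1` otherwise}
#'   \item{key_factor}{whether the variable enters the eight-factor
#'     multivariate fall model}
#'   \item{integer_valued}{whether the variable only takes integer values}
#'   \item{lower, upper}{physical bounds (`-Inf`/`Inf` when unbounded)}
#' }
#'
#' @return A data frame with one row per candidate variable.
#' @export
#' @examples
#' reg <- variable_registry()
#' reg[reg$key_factor, c("name", "units", "direction")]
variable_registry <- function() {
  reg <- data.frame(
    name = c(
      "lower_body_strength", "upper_body_strength",
      "lower_body_flexibility", "upper_body_flexibility",
      "agility_dynamic_balance", "aerobic_endurance",
      "multidimensional_balance", "body_weight", "body_height",
      "body_mass_index", "lean_body_mass", "fat_body_mass",
      "walking_pa", "moderate_pa", "vigorous_pa", "total_pa",
      "rest_period_weekdays", "health_conditions", "environmental_hazards"
    ),
    label = c(
      "Lower body strength", "Upper body strength",
      "Lower body flexibility", "Upper body flexibility",
      "Agility and dynamic balance", "Aerobic endurance",
      "Multidimensional balance score", "Body weight", "Body height",
      "Body mass index", "Lean body mass", "Fat body mass",
      "Walking physical activity", "Moderate physical activity",
      "Vigorous physical activity", "Total physical activity",
      "Rest period weekdays", "Health conditions", "Environmental hazards"
    ),
    units = c(
      "rep", "rep", "cm", "cm", "sec", "m", "point", "kg", "cm",
      "kg/m2", "kg", "%", "MET-min/wk", "MET-min/wk", "MET-min/wk",
      "MET-min/wk", "hr/day", "count", "count"
    ),
    direction = c(
      "protective", "protective", "risk", "protective", "risk",
      "protective", "protective", "protective", "protective", "risk",
      "protective", "risk", "protective", "protective", "risk",
      "protective", "risk", "risk", "risk"
    ),
    precision = c(
      1, 1, 0.1, 0.1, 0.1, 1, 1, 0.1, 0.1, 0.1, 1, 1,
      100, 100, 100, 100, 0.1, 1, 1
    ),
    model_scale = c(
      1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1,
      0.01, 0.01, 0.01, 0.01, 1, 1, 1
    ),
    key_factor = c(
      FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE,
      FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE
    ),
    integer_valued = c(
      TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE,
      FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE
    ),
    lower = c(
      0, 0, -Inf, -Inf, 0, 0, 0, 0, 0, 0, 0, 0,
      0, 0, 0, 0, 0, 0, 0
    ),
    upper = c(
      Inf, Inf, Inf, Inf, Inf, Inf, 40, Inf, Inf, Inf, Inf, 100,
      Inf, Inf, Inf, Inf, 24, Inf, 34
    ),
    stringsAsFactors = FALSE
  )
  stopifnot(!anyDuplicated(reg$name), all(reg$model_scale > 0))
  reg
}

#' Names of the eight key model factors
#'
#' The eight covariates of the multivariate fall-probability model, in the
#' order they appear in its linear predictor: multidimensional balance (B),
#' lean body mass (L), fat body mass (F), total physical activity (TPA),
#' vigorous physical activity (VPA), rest period weekdays (R), health
#' conditions (HC), environmental hazards (H).
#'
#' @return Character vector of length 8.
#' @export
key_factor_names <- function() {
  c("multidimensional_balance", "lean_body_mass", "fat_body_mass",
    "total_pa", "vigorous_pa", "rest_period_weekdays",
    "health_conditions", "environmental_hazards")
}

#' Convert MET-min/wk to model units (hundreds)
#'
#' The fall model expresses physical-activity expenditure in units of
#' 100 MET-min/wk.
#'
#' @param met Non-negative metabolic expenditure in MET-min/wk.
#' @return `met / 100`, unrounded.
#' @export
#' @examples
#' met_to_model_units(1887)  # 18.87
met_to_model_units <- function(met) {
  if (any(!is.finite(met)) || any(met < 0)) {
    stop("metabolic expenditure must be finite and non-negative", call. = FALSE)
  }
  met / 100
}

#' Round metabolic expenditure up to the next hundred
#'
#' Presentation rule for physical-activity cutoffs: values are rounded up to
#' the nearest hundred MET-min/wk (e.g. 18.87 model units, i.e. 1887
#' MET-min/wk, presents as 1900).
#'
#' @param met Non-negative metabolic expenditure in MET-min/wk.
#' @return Smallest multiple of 100 that is `>= met`.
#' @export
#' @examples
#' met_round_up_hundred(1887)  # 1900
met_round_up_hundred <- function(met) {
  if (any(!is.finite(met)) || any(met < 0)) {
    stop("metabolic expenditure must be finite and non-negative", call. = FALSE)
  }
  100 * ceiling(met / 100)
}

# Internal: validate a cohort data frame against the registry invariants.
# Returns the data frame invisibly; stops with row/column context otherwise.
validate_cohort <- function(data, registry = variable_registry()) {
  required <- c(registry$name, "faller")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in required) {
    x <- data[[col]]
    if (!is.numeric(x)) {
      stop("column '", col, "' is not numeric", call. = FALSE)
    }
    if (anyNA(x)) {
      stop("column '", col, "' has missing value(s) at row(s) ",
           paste(utils::head(which(is.na(x)), 5), collapse = ", "),
           "; missing data are rejected, not imputed", call. = FALSE)
    }
  }
  if (!all(data$faller %in% c(0, 1))) {
    bad <- which(!(data$faller %in% c(0, 1)))
    stop("column 'faller' must be 0 or 1; violated at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  for (i in seq_len(nrow(registry))) {
    spec <- registry[i, ]
    x <- data[[spec$name]]
    if (any(x < spec$lower) || any(x > spec$upper)) {
      bad <- which(x < spec$lower | x > spec$upper)
      stop("column '", spec$name, "' outside [", spec$lower, ", ",
           spec$upper, "] at row(s) ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
    if (spec$integer_valued && any(x != round(x))) {
      bad <- which(x != round(x))
      stop("column '", spec$name, "' must be integer-valued; violated at row(s) ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
  }
  if (any(data$total_pa < data$vigorous_pa)) {
    bad <- which(data$total_pa < data$vigorous_pa)
    stop("total_pa < vigorous_pa at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  invisible(data)
}

#' Load a cohort file
#'
#' Reads a comma-separated cohort file (UTF-8, header row, one participant
#' per row) whose header names every registry variable plus the binary
#' `faller` outcome (1 = fell at least once in the previous 12 months).
#' Optional columns (`id`, `sex`, `age`, `education`) are carried through
#' untouched. All registry invariants are enforced at load: no missing
#' cells, `faller` in \{0, 1\}, counts are non-negative integers
#' (environmental hazards at most 34), the balance score lies in [0, 40],
#' physical-activity values are non-negative, and total PA is at least
#' vigorous PA.
#'
#' @param path Path to a CSV file.
#' @param registry Variable registry, see [variable_registry()].
#' @return A `fall_cohort`: a data frame of participants with the registry
#'   attached as an attribute.
#' @seealso [write_cohort()], [simulate_cohort()]
#' @export
load_cohort <- function(path, registry = variable_registry()) {
  data <- utils::read.csv(path, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  validate_cohort(data, registry)
  as_fall_cohort(data, registry)
}

#' Write a cohort file
#'
#' Writes a cohort as CSV with full numeric precision, so that
#' `load_cohort(write_cohort(x, path))` reproduces every value exactly.
#' The `faller` column is placed last by convention.
#'
#' @param cohort A `fall_cohort` or compatible data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  data <- as.data.frame(cohort)
  ord <- c(setdiff(names(data), "faller"), "faller")
  data <- data[, ord, drop = FALSE]
  out <- data
  for (col in names(out)) {
    if (is.numeric(out[[col]])) {
      # %.17g round-trips any double exactly through text
      out[[col]] <- ifelse(out[[col]] == round(out[[col]]) &
                             abs(out[[col]]) < 1e15,
                           sprintf("%.0f", out[[col]]),
                           sprintf("%.17g", out[[col]]))
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

# Internal constructor: attach class and registry.
as_fall_cohort <- function(data, registry = variable_registry()) {
  structure(data,
            registry = registry,
            class = c("fall_cohort", "data.frame"))
}

#' @export
print.fall_cohort <- function(x, ...) {
  cat("Fall-risk cohort: ", nrow(x), " participants, ",
      sum(x$faller), " fallers (",
      sprintf("%.1f%%", 100 * mean(x$faller)), ")\n", sep = "")
  utils::str(as.data.frame(x), give.attr = FALSE, vec.len = 3)
  invisible(x)
}

#' Export the variable registry as JSON
#'
#' @param path Output path for a JSON document listing every variable
#'   specification.
#' @param registry Variable registry.
#' @return `path`, invisibly.
#' @export
export_registry_json <- function(path, registry = variable_registry()) {
  jsonlite::write_json(registry, path, dataframe = "rows", digits = NA,
                       pretty = TRUE)
  invisible(path)
}
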