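#' Default latent correlation matrix for the cohort generator
#'
#' The published cohort reports only marginal percentiles, so the joint
#' structure of the generator is a modelling choice: protective
#' physical-fitness variables are mutually correlated at +0.4 on the latent
#' Gaussian scale, fat body mass is correlated at -0.3 with each of them,
#' and the two count variables (health conditions, environmental hazards)
#' at +0.2 with each other; all other pairs are uncorrelated. The defaults
#' exist so the joint distribution is non-degenerate; they are fully
#' configurable.
#'
#' @param registry Variable registry.
#' @return A symmetric positive-definite correlation matrix over the 19
#'   registry variables.
#' @export
default_correlation <- function(registry = variable_registry()) {
  vars <- registry$name
  k <- length(vars)
  R <- diag(k)
  dimnames(R) <- list(vars, vars)
  fitness <- c("lower_body_strength", "upper_body_strength",
               "upper_body_flexibility", "aerobic_endurance",
               "multidimensional_balance", "lean_body_mass", "total_pa")
  R[fitness, fitness] <- 0.4
  R["fat_body_mass", fitness] <- -0.3
  R[fitness, "fat_body_mass"] <- -0.3
  R["health_conditions", "environmental_hazards"] <- 0.2
  R["environmental_hazards", "health_conditions"] <- 0.2
  diag(R) <- 1
  R
}

#' Generator configuration
#'
#' Bundles everything the synthetic-cohort generator needs: cohort size,
#' seed, per-variable quantile anchors, latent correlation, the outcome
#' model used to label fallers, the target faller prevalence (study value
#' 0.372), and the fraction of the cohort with zero vigorous physical
#' activity (study value 0.80: only participants above the 80th percentile
#' performed vigorous activity).
#'
#' @param n Cohort size (study value 500).
#' @param seed Integer seed; the generator is fully deterministic given the
#'   configuration and seed.
#' @param anchors Named list of [quantile_anchors()] (default: published
#'   anchors).
#' @param correlation Latent correlation matrix (default:
#'   [default_correlation()]).
#' @param outcome_model Model used to label fallers (default: the published
#'   equation, whose intercept is then calibrated to `target_prevalence`).
#' @param target_prevalence Target faller fraction in (0, 1).
#' @param vigorous_zero_fraction Fraction with vigorous PA = 0.
#' @param registry Variable registry.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n = 500, seed = 1,
                             anchors = default_anchors(),
                             correlation = default_correlation(registry),
                             outcome_model = fall_model(),
                             target_prevalence = 0.372,
                             vigorous_zero_fraction = 0.80,
                             registry = variable_registry()) {
  stopifnot(n >= 1, target_prevalence > 0, target_prevalence < 1,
            vigorous_zero_fraction >= 0, vigorous_zero_fraction < 1)
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 anchors = anchors, correlation = correlation,
                 outcome_model = outcome_model,
                 target_prevalence = target_prevalence,
                 vigorous_zero_fraction = vigorous_zero_fraction,
                 registry = registry),
            class = "generator_config")
}

# Internal: check a correlation matrix; on failure suggest the nearest PSD
# matrix via Matrix::nearPD.
check_correlation <- function(R, vars) {
  if (!isTRUE(all.equal(unname(R), unname(t(R)), tolerance = 1e-10))) {
    stop("correlation matrix must be symmetric", call. = FALSE)
  }
  if (any(abs(diag(R) - 1) > 1e-12)) {
    stop("correlation matrix must have unit diagonal", call. = FALSE)
  }
  ev <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -1e-10) {
    near <- Matrix::nearPD(R, corr = TRUE)
    stop("correlation matrix is not positive semidefinite (min eigenvalue ",
         format(ev, digits = 3),
         "); consider Matrix::nearPD(R, corr = TRUE), which converges in ",
         near$iterations, " iterations here", call. = FALSE)
  }
  R[vars, vars]
}

#' Sample cohort covariates by a Gaussian copula
#'
#' Draws correlated latent standard normals, transforms them to uniforms,
#' and maps each variable through the inverse of its reconstructed quantile
#' function (piecewise linear between the published anchors, linear tail
#' extension beyond the 1st/99th anchors truncated at physical bounds).
#' Vigorous physical activity is structurally zero for
#' `vigorous_zero_fraction` of the latent scale and shares total physical
#' activity's latent rank (vigorous expenditure is a component of the
#' total, so within a person the two move together); with the published
#' anchors this makes the invariant TPA >= VPA hold by construction while
#' preserving both printed marginals. Integer-valued variables are rounded.
#'
#' @param config A [generator_config()].
#' @return A `fall_cohort` without outcome labels (no `faller` column).
#' @export
sample_covariates <- function(config) {
  reg <- config$registry
  vars <- reg$name
  R <- check_correlation(config$correlation, vars)
  n <- config$n
  set.seed(config$seed)
  L <- chol(R + diag(1e-12, length(vars)))
  Z <- matrix(stats::rnorm(n * length(vars)), nrow = n) %*% L
  U <- stats::pnorm(Z)
  colnames(U) <- vars
  data <- as.data.frame(matrix(NA_real_, n, length(vars),
                               dimnames = list(NULL, vars)))
  zf <- config$vigorous_zero_fraction
  for (i in seq_along(vars)) {
    v <- vars[i]
    a <- config$anchors[[v]]
    if (is.null(a)) stop("no anchors for variable '", v, "'", call. = FALSE)
    if (v == "vigorous_pa") {
      # structural zeros up to the zero fraction, then linear to the top
      # anchor value over the remaining percentile range; the latent rank
      # is total PA's, so vigorous activity rises with total expenditure
      top <- a$values[length(a$values)]
      top_p <- a$percentiles[length(a$percentiles)]
      p <- 100 * U[, "total_pa"]
      x <- numeric(n)
      active <- p > 100 * zf
      slope <- top / (top_p - 100 * zf)
      x[active] <- pmax(0, slope * (p[active] - 100 * zf))
      data[[v]] <- x
    } else {
      data[[v]] <- extended_quantile(a, 100 * U[, v],
                                     lower = reg$lower[i],
                                     upper = reg$upper[i])
    }
  }
  int_vars <- reg$name[reg$integer_valued]
  for (v in int_vars) data[[v]] <- round(data[[v]])
  data$total_pa <- pmax(data$total_pa, data$vigorous_pa)
  data <- cbind(id = seq_len(n), data)
  structure(data, registry = reg, class = c("fall_cohort", "data.frame"))
}

#' Calibrate the outcome-model intercept to a target prevalence
#'
#' The published equation carries no intercept, so the generator treats the
#' intercept as a free parameter: this finds the value `b0` such that the
#' cohort mean of `plogis(b0 + eta)` (with `eta` the published linear
#' predictor) equals the target faller prevalence, by monotone scalar
#' root-finding to within `tol`.
#'
#' @param outcome_model A `fitted_logistic_model`.
#' @param covariate_cohort Cohort data (natural units) without outcomes.
#' @param target_prevalence Target mean fall probability in (0, 1).
#' @param registry Variable registry.
#' @param tol Tolerance on the achieved mean probability.
#' @return The calibrated intercept (scalar).
#' @export
calibrate_intercept <- function(outcome_model, covariate_cohort,
                                target_prevalence,
                                registry = variable_registry(),
                                tol = 1e-6) {
  if (nrow(covariate_cohort) == 0) stop("empty cohort", call. = FALSE)
  if (!is.finite(target_prevalence) || target_prevalence <= 0 ||
      target_prevalence >= 1) {
    stop("target prevalence must lie strictly in (0, 1)", call. = FALSE)
  }
  eta <- linear_predictor(outcome_model, covariate_cohort, registry) -
    outcome_model$intercept
  f <- function(b0) mean(stats::plogis(b0 + eta)) - target_prevalence
  root <- stats::uniroot(f, interval = c(-40, 40), tol = 1e-12,
                         extendInt = "upX")$root
  if (abs(f(root)) > tol) {
    stop("intercept calibration did not reach tolerance ", tol, call. = FALSE)
  }
  root
}

#' Label fallers from the outcome model
#'
#' Draws each participant's faller status as Bernoulli with probability
#' given by the outcome model at the calibrated intercept; deterministic
#' given the seed.
#'
#' @param cohort Covariate cohort (no outcome needed).
#' @param outcome_model A `fitted_logistic_model`.
#' @param intercept Calibrated intercept, see [calibrate_intercept()].
#' @param seed Integer seed for the Bernoulli draws.
#' @param registry Variable registry.
#' @return The cohort with a `faller` column appended.
#' @export
label_outcomes <- function(cohort, outcome_model, intercept, seed,
                           registry = variable_registry()) {
  eta <- linear_predictor(outcome_model, cohort, registry) -
    outcome_model$intercept + intercept
  p <- stats::plogis(eta)
  set.seed(seed)
  out <- as.data.frame(cohort)
  out$faller <- stats::rbinom(nrow(out), 1, p)
  structure(out, registry = registry,
            class = c("fall_cohort", "data.frame"))
}

#' Simulate a complete labelled cohort
#'
#' Convenience pipeline: sample covariates from the Gaussian copula,
#' calibrate the outcome-model intercept to the target prevalence on the
#' realized covariates, and draw faller labels. Fully deterministic given
#' the configuration.
#'
#' @param n Cohort size.
#' @param seed Integer seed.
#' @param config Optional [generator_config()]; `n` and `seed` override its
#'   fields.
#' @return A labelled `fall_cohort` with attributes `intercept` (the
#'   calibrated value) and `config`.
#' @export
#' @examples
#' coh <- simulate_cohort(n = 200, seed = 42)
#' mean(coh$faller)
simulate_cohort <- function(n = 500, seed = 1, config = NULL) {
  if (is.null(config)) config <- generator_config(n = n, seed = seed)
  config$n <- as.integer(n)
  config$seed <- as.integer(seed)
  cov <- sample_covariates(config)
  b0 <- calibrate_intercept(config$outcome_model, cov,
                            config$target_prevalence, config$registry)
  out <- label_outcomes(cov, config$outcome_model, b0, seed = seed + 1L,
                        registry = config$registry)
  attr(out, "intercept") <- b0
  attr(out, "config") <- config
  out
}
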