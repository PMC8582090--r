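#' The published multivariate fall-probability model
#'
#' The eight-factor binary logistic model relating fall occurrence to
#' multidimensional balance (B, points), lean body mass (L, kg), fat body
#' mass (F, %), total physical activity (TPA, 100 MET-min/wk), vigorous
#' physical activity (VPA, 100 MET-min/wk), weekday rest period (R,
#' hr/day), number of health conditions (HC), and number of environmental
#' hazards (H):
#'
#' \deqn{\pi(x) = \frac{\exp(\eta)}{1 + \exp(\eta)}, \quad
#'   \eta = -0.053B - 0.026L + 0.027F - 0.012\,TPA + 0.034\,VPA
#'          + 0.125R + 0.112\,HC + 0.063H}
#'
#' The published equation carries no intercept; `intercept` defaults to 0
#' ("reproduce" mode). The synthetic-cohort generator instead calibrates a
#' free intercept against the target faller prevalence.
#'
#' @param intercept Intercept on the log-odds scale (default 0).
#' @return A `fitted_logistic_model` with the published coefficients.
#' @export
#' @examples
#' m <- fall_model()
#' exp(coef(m))  # multivariate odds ratios per model unit
fall_model <- function(intercept = 0) {
  new_logistic_model(
    coefficients = c(
      multidimensional_balance = -0.053,
      lean_body_mass           = -0.026,
      fat_body_mass            =  0.027,
      total_pa                 = -0.012,
      vigorous_pa              =  0.034,
      rest_period_weekdays     =  0.125,
      health_conditions        =  0.112,
      environmental_hazards    =  0.063
    ),
    intercept = intercept,
    vcov = NULL, n_obs = NA_integer_, converged = TRUE,
    log_likelihood = NA_real_, iterations = 0L
  )
}

# Internal constructor for fitted_logistic_model objects.
new_logistic_model <- function(coefficients, intercept, vcov, n_obs,
                               converged, log_likelihood, iterations,
                               removal_log = NULL) {
  structure(list(
    variables = names(coefficients),
    coefficients = coefficients,
    intercept = intercept,
    vcov = vcov,
    n_obs = n_obs,
    converged = converged,
    log_likelihood = log_likelihood,
    iterations = iterations,
    removal_log = removal_log
  ), class = "fitted_logistic_model")
}

#' @export
coef.fitted_logistic_model <- function(object, ...) object$coefficients

#' @export
vcov.fitted_logistic_model <- function(object, ...) object$vcov

#' @export
logLik.fitted_logistic_model <- function(object, ...) {
  structure(object$log_likelihood,
            df = length(object$coefficients) + !is.null(object$vcov),
            class = "logLik")
}

#' @export
print.fitted_logistic_model <- function(x, ...) {
  cat("Binary logistic fall model (", length(x$coefficients),
      " covariates, intercept ", format(x$intercept), ")\n", sep = "")
  print(round(x$coefficients, 4))
  if (!is.na(x$log_likelihood)) {
    cat("log-likelihood:", format(x$log_likelihood),
        " n =", x$n_obs,
        if (isTRUE(x$converged)) " (converged)" else " (NOT converged)",
        "\n")
  }
  invisible(x)
}

# Internal: design matrix in model units (registry model_scale applied),
# no intercept column.
model_matrix_scaled <- function(data, variables,
                                registry = variable_registry()) {
  missing_vars <- setdiff(variables, names(data))
  if (length(missing_vars) > 0) {
    stop("cohort lacks model variable(s): ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  }
  X <- as.matrix(as.data.frame(data)[, variables, drop = FALSE])
  scl <- registry$model_scale[match(variables, registry$name)]
  scl[is.na(scl)] <- 1  # variables outside the registry (e.g. age) unscaled
  sweep(X, 2, scl, `*`)
}

#' Linear predictor and fall probability
#'
#' Evaluates a fitted (or published) logistic model on participant data in
#' natural units; physical-activity variables are converted to 100
#' MET-min/wk model units via the registry before evaluation.
#'
#' @param model A `fitted_logistic_model`.
#' @param data Data frame with one column per model variable, natural units.
#' @param registry Variable registry.
#' @return `predict_probability()` returns fall probabilities in (0, 1);
#'   `linear_predictor()` the log-odds.
#' @export
predict_probability <- function(model, data, registry = variable_registry()) {
  stats::plogis(linear_predictor(model, data, registry))
}

#' @rdname predict_probability
#' @export
linear_predictor <- function(model, data, registry = variable_registry()) {
  X <- model_matrix_scaled(data, model$variables, registry)
  drop(model$intercept + X %*% model$coefficients)
}

# Internal binomial log-likelihood at probabilities p.
binomial_loglik <- function(y, eta) {
  sum(y * eta - log1p(exp(eta)))
}

#' Fit a binary logistic regression by IRLS
#'
#' Maximum-likelihood logistic regression fitted from scratch by
#' iteratively reweighted least squares (Newton-Raphson on the binomial
#' log-likelihood), with step-halving whenever a full Newton step would
#' decrease the likelihood. Convergence is declared when the score
#' (gradient) norm falls below `tol`; the coefficient covariance is the
#' inverse observed information at the optimum.
#'
#' Physical-activity covariates are rescaled to 100 MET-min/wk model units
#' before fitting, so coefficients (and odds ratios) are per 100 MET-min/wk
#' for those variables.
#'
#' @param cohort A `fall_cohort` or data frame with a `faller` column.
#' @param variables Covariate names; default the eight key model factors.
#' @param include_intercept Fit an intercept (default `TRUE`).
#' @param registry Variable registry (provides model-unit scaling).
#' @param tol Convergence tolerance on the score norm.
#' @param max_iter Maximum IRLS iterations.
#' @return A `fitted_logistic_model` with coefficients, covariance,
#'   log-likelihood and convergence diagnostics.
#' @export
fit_logistic <- function(cohort, variables = key_factor_names(),
                         include_intercept = TRUE,
                         registry = variable_registry(),
                         tol = 1e-8, max_iter = 100) {
  y <- cohort$faller
  if (is.null(y)) stop("cohort has no 'faller' column", call. = FALSE)
  if (length(unique(y)) < 2) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  X <- model_matrix_scaled(cohort, variables, registry)
  if (include_intercept) {
    X <- cbind(`(intercept)` = 1, X)
  }
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("more parameters than observations", call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  beta <- numeric(p)
  ll <- binomial_loglik(y, drop(X %*% beta))
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    score <- drop(crossprod(X, y - mu))
    if (sqrt(sum(score^2)) < tol) { converged <- TRUE; break }
    w <- mu * (1 - mu)
    info <- crossprod(X * w, X)
    step <- tryCatch(solve(info, score),
                     error = function(e) {
                       stop("information matrix singular (possible separation)",
                            call. = FALSE)
                     })
    # step-halving: never accept a likelihood decrease
    lambda <- 1
    repeat {
      beta_new <- beta + lambda * step
      ll_new <- binomial_loglik(y, drop(X %*% beta_new))
      if (ll_new >= ll - 1e-12 || lambda < 1e-10) break
      lambda <- lambda / 2
    }
    beta <- beta_new
    ll <- ll_new
  }
  # perfect-separation check on the standardized scale
  sds <- apply(X, 2, stats::sd)
  sds[sds == 0] <- 1
  if (any(abs(beta * sds) > 15)) {
    bad <- colnames(X)[abs(beta * sds) > 15]
    stop("coefficients diverging (|beta| > 15 on standardized scale) for: ",
         paste(bad, collapse = ", "),
         "; data are likely perfectly separated", call. = FALSE)
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  info <- crossprod(X * (mu * (1 - mu)), X)
  vc <- solve(info)
  dimnames(vc) <- list(colnames(X), colnames(X))
  names(beta) <- colnames(X)
  intercept <- if (include_intercept) beta[["(intercept)"]] else 0
  coefs <- beta[setdiff(colnames(X), "(intercept)")]
  new_logistic_model(coefficients = coefs, intercept = intercept,
                     vcov = vc, n_obs = n, converged = converged,
                     log_likelihood = ll, iterations = iter)
}

# Internal: Wald standard errors for the non-intercept coefficients.
wald_se <- function(model) {
  vc <- model$vcov
  sqrt(diag(vc))[model$variables]
}

#' Odds-ratio table from a fitted model
#'
#' Exponentiates coefficients to odds ratios with Wald 95% confidence
#' intervals (z multiplier 1.959964) and a percent-change presentation
#' `100 * (OR - 1)`. For physical-activity variables the OR is per
#' 100 MET-min/wk.
#'
#' @param model A converged `fitted_logistic_model` with covariance.
#' @param level Confidence level (default 0.95).
#' @return Data frame with `variable`, `beta`, `se`, `or`, `ci_lower`,
#'   `ci_upper`, `percent_change`, `p_value`.
#' @export
#' @examples
#' odds_ratio_report(fall_model(0))["rest_period_weekdays", "or"]  # 1.133
odds_ratio_report <- function(model, level = 0.95) {
  beta <- model$coefficients
  if (!is.null(model$vcov)) {
    se <- wald_se(model)
    z <- beta / se
    pval <- 2 * stats::pnorm(-abs(z))
  } else {
    se <- rep(NA_real_, length(beta))
    pval <- rep(NA_real_, length(beta))
  }
  zq <- stats::qnorm(1 - (1 - level) / 2)
  out <- data.frame(
    variable = names(beta),
    beta = unname(beta),
    se = unname(se),
    or = exp(unname(beta)),
    ci_lower = exp(unname(beta) - zq * unname(se)),
    ci_upper = exp(unname(beta) + zq * unname(se)),
    percent_change = 100 * (exp(unname(beta)) - 1),
    p_value = unname(pval),
    stringsAsFactors = FALSE
  )
  rownames(out) <- out$variable
  out
}

#' Univariate odds ratios for candidate variables
#'
#' Fits one single-covariate logistic regression (with intercept) per
#' candidate variable and reports the odds ratio with its 95% confidence
#' interval, mirroring the exploratory univariate screen of candidate fall
#' risk factors. Physical-activity variables are scaled so the OR is per
#' 100 MET-min/wk. A failure for one variable (e.g. separation) is recorded
#' as `NA` for that row without aborting the table.
#'
#' @param cohort A `fall_cohort` or data frame with `faller`.
#' @param variables Candidate variable names (default: all 19 registry
#'   variables).
#' @param registry Variable registry.
#' @return Data frame with one row per variable: `or`, `ci_lower`,
#'   `ci_upper`, `p_value`, `error` (message or `NA`).
#' @export
univariate_or_table <- function(cohort, variables = variable_registry()$name,
                                registry = variable_registry()) {
  rows <- lapply(variables, function(v) {
    res <- tryCatch({
      fit <- fit_logistic(cohort, v, include_intercept = TRUE,
                          registry = registry)
      rep <- odds_ratio_report(fit)
      data.frame(variable = v, or = rep$or, ci_lower = rep$ci_lower,
                 ci_upper = rep$ci_upper, p_value = rep$p_value,
                 error = NA_character_, stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(variable = v, or = NA_real_, ci_lower = NA_real_,
                 ci_upper = NA_real_, p_value = NA_real_,
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- out$variable
  out
}

#' Backward elimination on Wald p-values
#'
#' Starts from the full multivariate model and iteratively removes the
#' covariate with the largest Wald p-value above `alpha`, refitting after
#' each removal, until every remaining covariate has p <= `alpha`. Ties are
#' broken by the larger p-value, then by candidate order. The removal order
#' is recorded on the returned model (`$removal_log`). An empty surviving
#' set yields an intercept-only model.
#'
#' @param cohort A `fall_cohort` or data frame with `faller`.
#' @param candidates Candidate covariate names.
#' @param alpha Retention threshold on the Wald p-value (default 0.05).
#' @param include_intercept Fit an intercept (default `TRUE`).
#' @param registry Variable registry.
#' @return A `fitted_logistic_model` for the surviving covariates, with a
#'   `removal_log` data frame (`variable`, `p_value`, `step`).
#' @export
backward_select <- function(cohort, candidates = key_factor_names(),
                            alpha = 0.05, include_intercept = TRUE,
                            registry = variable_registry()) {
  stopifnot(length(candidates) > 0)
  current <- candidates
  removed <- data.frame(variable = character(), p_value = numeric(),
                        step = integer(), stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    if (length(current) == 0) {
      fit <- fit_logistic(cohort, character(0), include_intercept = TRUE,
                          registry = registry)
      fit$removal_log <- removed
      return(fit)
    }
    fit <- fit_logistic(cohort, current, include_intercept, registry)
    rep <- odds_ratio_report(fit)
    pvals <- rep$p_value
    if (all(pvals <= alpha)) {
      fit$removal_log <- removed
      return(fit)
    }
    # drop the largest p; ties broken by candidate order (first match wins)
    worst <- which(pvals == max(pvals))[1]
    step <- step + 1L
    removed <- rbind(removed, data.frame(variable = current[worst],
                                         p_value = pvals[worst],
                                         step = step,
                                         stringsAsFactors = FALSE))
    current <- current[-worst]
  }
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Ranks participants by predicted fall probability, splits them into
#' `n_groups` near-equal groups ("deciles of risk" for the default 10),
#' keeping tied probabilities together in the lower group, and compares
#' observed with expected events and non-events by a Pearson chi-square
#' statistic on `n_groups - 2` degrees of freedom.
#'
#' @param model A `fitted_logistic_model`.
#' @param cohort A `fall_cohort` or data frame with `faller`.
#' @param n_groups Number of risk groups (default 10).
#' @param registry Variable registry.
#' @return List with `statistic`, `df`, `p_value`, and the per-group
#'   `table` (observed/expected events and sizes).
#' @export
hosmer_lemeshow <- function(model, cohort, n_groups = 10,
                            registry = variable_registry()) {
  y <- cohort$faller
  n <- length(y)
  if (n < 5 * n_groups) {
    stop("need at least ", 5 * n_groups, " observations for ", n_groups,
         " groups", call. = FALSE)
  }
  p <- predict_probability(model, cohort, registry)
  ord <- order(p)
  p <- p[ord]; y <- y[ord]
  # near-equal groups by rank; tied probabilities collapse into the lower
  # group wholesale
  g <- ceiling(seq_len(n) / (n / n_groups))
  for (i in 2:n) if (p[i] == p[i - 1]) g[i] <- g[i - 1]
  groups <- sort(unique(g))
  obs1 <- tapply(y, g, sum)
  exp1 <- tapply(p, g, sum)
  size <- tapply(rep(1, n), g, sum)
  obs0 <- size - obs1
  exp0 <- size - exp1
  if (any(exp1 < .Machine$double.eps) || any(exp0 < .Machine$double.eps)) {
    stop("expected count of zero in a risk group; use fewer groups",
         call. = FALSE)
  }
  stat <- sum((obs1 - exp1)^2 / exp1 + (obs0 - exp0)^2 / exp0)
  df <- length(groups) - 2
  list(statistic = unname(stat), df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       table = data.frame(group = groups, n = as.numeric(size),
                          observed = as.numeric(obs1),
                          expected = as.numeric(exp1)))
}
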