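#' ROC curve and trapezoidal AUC
#'
#' Computes the receiver operating characteristic of a score against a
#' binary label by a single descending sort and cumulative counting. A
#' participant is classified positive when `score >= threshold`; the
#' candidate thresholds are the distinct score values plus an `Inf`
#' sentinel, so the curve always passes through (0, 0) and (1, 1). The AUC
#' is the trapezoidal area, which equals the Mann-Whitney probability of
#' correct ranking (ties counted one half).
#'
#' @param scores Finite numeric scores (e.g. predicted fall probabilities).
#' @param labels Binary labels (1 = event/faller).
#' @return A `roc_result` list: `thresholds` (descending), `sensitivity`,
#'   `specificity` (aligned with thresholds), and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop("both classes must be present", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- unname(scores[ord]); y <- unname(labels[ord])
  # collapse tied scores: one ROC point per distinct threshold
  last_of_run <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y)[last_of_run]
  fp <- cumsum(1 - y)[last_of_run]
  thresholds <- c(Inf, s[last_of_run])
  sens <- c(0, tp / n1)
  spec <- c(1, 1 - fp / n0)
  fpr <- 1 - spec
  auc <- sum(diff(fpr) * (sens[-1] + sens[-length(sens)]) / 2)
  structure(list(thresholds = thresholds, sensitivity = sens,
                 specificity = spec, auc = auc, n1 = n1, n0 = n0),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("ROC curve: ", x$n1, " events / ", x$n0, " non-events, AUC = ",
      sprintf("%.3f", x$auc), "\n", sep = "")
  invisible(x)
}

# Internal: DeLong placement values and AUC variance components.
delong_components <- function(scores, labels) {
  x <- scores[labels == 1]  # events
  y <- scores[labels == 0]
  m <- length(x); n <- length(y)
  # placement of each event among non-events and vice versa
  v10 <- vapply(x, function(xi) (sum(xi > y) + 0.5 * sum(xi == y)) / n,
                numeric(1))
  v01 <- vapply(y, function(yi) (sum(x > yi) + 0.5 * sum(x == yi)) / m,
                numeric(1))
  auc <- mean(v10)
  var_auc <- stats::var(v10) / m + stats::var(v01) / n
  list(auc = auc, var = var_auc)
}

#' DeLong confidence interval for the AUC
#'
#' Normal-theory confidence interval for the area under the ROC curve using
#' the DeLong structural-components variance estimate, truncated to [0, 1].
#'
#' @param scores Finite numeric scores.
#' @param labels Binary labels (1 = event), at least two per class.
#' @param level Confidence level (default 0.95).
#' @return List with `auc`, `lower`, `upper`, `se`.
#' @export
auc_ci <- function(scores, labels, level = 0.95) {
  if (sum(labels == 1) < 2 || sum(labels == 0) < 2) {
    stop("need at least two members of each class", call. = FALSE)
  }
  dc <- delong_components(scores, labels)
  if (!is.finite(dc$var) || dc$var <= 0) {
    if (stats::var(scores) == 0) {
      stop("degenerate variance: all scores are tied", call. = FALSE)
    }
    dc$var <- max(dc$var, 0)
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(dc$var)
  list(auc = dc$auc,
       lower = max(0, dc$auc - z * se),
       upper = min(1, dc$auc + z * se),
       se = se)
}

#' Sensitivity/specificity-maximizing probability cutoff
#'
#' Returns the threshold maximizing Youden's J = sensitivity + specificity
#' - 1 over the candidate thresholds of the ROC curve (the distinct score
#' values); among tied maximizers the smallest finite threshold is
#' returned, so the reported cutoff is itself an attained score value.
#'
#' @param scores Finite numeric scores.
#' @param labels Binary labels (1 = event).
#' @return List with `cutoff`, `sensitivity`, `specificity`, `youden_j`.
#' @export
youden_cutoff <- function(scores, labels) {
  roc <- roc_curve(scores, labels)
  j <- roc$sensitivity + roc$specificity - 1
  finite <- is.finite(roc$thresholds)
  jmax <- max(j[finite])
  cand <- which(finite & j >= jmax - 1e-12)
  best <- cand[which.min(roc$thresholds[cand])]
  list(cutoff = roc$thresholds[best],
       sensitivity = roc$sensitivity[best],
       specificity = roc$specificity[best],
       youden_j = j[best])
}

# Internal: random equal partition into k folds (remainder spread one per
# fold); refolds until each fold holds both classes.
make_folds <- function(labels, k, max_attempts = 20) {
  n <- length(labels)
  for (attempt in seq_len(max_attempts)) {
    fold <- sample(rep(seq_len(k), length.out = n))
    ok <- all(vapply(seq_len(k), function(f) {
      yy <- labels[fold == f]
      any(yy == 1) && any(yy == 0)
    }, logical(1)))
    if (ok) return(fold)
  }
  stop("could not build ", k, " folds with both classes after ",
       max_attempts, " attempts", call. = FALSE)
}

#' Cross-validated AUC
#'
#' Internal validation of the fall model: participants are clustered into
#' `k` equal groups by random sampling without replacement, the model is
#' refitted on each training complement, and the pooled out-of-fold
#' predicted probabilities form a single ROC curve whose AUC and DeLong
#' confidence interval are reported.
#'
#' @param cohort A labelled `fall_cohort`.
#' @param model_variables Covariates to refit in each fold (default the
#'   eight key factors).
#' @param k Number of folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @param include_intercept Fit an intercept in each fold (default `TRUE`).
#' @param registry Variable registry.
#' @param level Confidence level for the AUC interval.
#' @param model Optional pre-trained `fitted_logistic_model`; with
#'   `refit = FALSE` its out-of-fold predictions are pooled without any
#'   refitting, in which case the cross-validated AUC coincides with the
#'   apparent AUC (no training leakage to remove).
#' @param refit Refit the model on each training complement (default
#'   `TRUE`).
#' @return List with `auc`, `lower`, `upper`, `fold` assignment and pooled
#'   out-of-fold `probabilities`.
#' @export
crossval_auc <- function(cohort, model_variables = key_factor_names(),
                         k = 10, seed = 1, include_intercept = TRUE,
                         registry = variable_registry(), level = 0.95,
                         model = NULL, refit = TRUE) {
  y <- cohort$faller
  if (!refit && is.null(model)) {
    stop("refit = FALSE requires a pre-trained model", call. = FALSE)
  }
  set.seed(seed)
  fold <- make_folds(y, k)
  p <- rep(NA_real_, length(y))
  for (f in seq_len(k)) {
    if (refit) {
      train <- as.data.frame(cohort)[fold != f, , drop = FALSE]
      fit <- fit_logistic(train, model_variables, include_intercept,
                          registry)
    } else {
      fit <- model
    }
    test <- as.data.frame(cohort)[fold == f, , drop = FALSE]
    p[fold == f] <- predict_probability(fit, test, registry)
  }
  ci <- auc_ci(p, y, level)
  list(auc = ci$auc, lower = ci$lower, upper = ci$upper,
       fold = fold, probabilities = p)
}
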