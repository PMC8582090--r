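test_that("a null covariate is estimated near zero", {
  set.seed(1)
  d <- data.frame(x = rnorm(10000), faller = rbinom(10000, 1, 0.4))
  fit <- fit_logistic(d, "x")
  se <- sqrt(diag(fit$vcov))[["x"]]
  expect_lt(abs(fit$coefficients[["x"]]), 3 * se)
  expect_true(fit$converged)
})

test_that("IRLS attains the likelihood optimum on a brute-force grid", {
  d <- data.frame(x = c(-1.5, -1, -0.5, 0, 0.5, 1, 1.5, 2),
                  faller = c(0, 0, 1, 0, 1, 0, 1, 1))
  fit <- fit_logistic(d, "x")
  ll <- function(b0, b1) {
    eta <- b0 + b1 * d$x
    sum(d$faller * eta - log1p(exp(eta)))
  }
  grid <- expand.grid(b0 = seq(-3, 3, length.out = 40),
                      b1 = seq(-3, 5, length.out = 25))
  grid_ll <- mapply(ll, grid$b0, grid$b1)
  expect_gte(fit$log_likelihood, max(grid_ll))
})

test_that("coefficients agree with the reference fitter to 1e-6", {
  for (seed in 1:20) {
    d <- tiny_logistic_data(n = 80, seed = seed)
    fit <- fit_logistic(d, c("x1", "x2"))
    ref <- suppressWarnings(
      glm(faller ~ x1 + x2, data = d, family = binomial())
    )
    expect_lt(max(abs(c(fit$intercept, fit$coefficients) - coef(ref))),
              1e-6)
  }
})

test_that("the score equations hold at convergence", {
  coh <- simulate_cohort(n = 800, seed = 12)
  fit <- fit_logistic(coh)
  X <- cbind(1, fallstrat:::model_matrix_scaled(coh, fit$variables))
  mu <- predict_probability(fit, coh)
  expect_lt(max(abs(crossprod(X, coh$faller - mu))), 1e-6)
})

test_that("separation and collinearity are detected", {
  d <- data.frame(x = c(-2, -1, -0.5, 0.5, 1, 2),
                  faller = c(0, 0, 0, 1, 1, 1))
  expect_error(fit_logistic(d, "x"), "separat")
  d2 <- tiny_logistic_data(60, seed = 2)
  d2$x3 <- 2 * d2$x1
  expect_error(fit_logistic(d2, c("x1", "x2", "x3")), "x3")
})

test_that("odds-ratio presentation matches the analytic identities", {
  rep <- odds_ratio_report(fall_model())
  expect_equal(round(rep["rest_period_weekdays", "or"], 3), 1.133)
  expect_equal(round(rep["lean_body_mass", "or"], 3), 0.974)
  expect_equal(sprintf("%.1f", rep["rest_period_weekdays",
                                   "percent_change"]), "13.3")
  m0 <- fall_model()
  m0$coefficients[] <- 0
  rep0 <- odds_ratio_report(m0)
  expect_true(all(rep0$or == 1) && all(rep0$percent_change == 0))
})

test_that("univariate ORs recover a known single-variable effect", {
  set.seed(4)
  n <- 4000
  x <- rnorm(n, 10, 3)
  d <- data.frame(marker = x,
                  faller = rbinom(n, 1, plogis(-2 + 0.18 * x)))
  tab <- univariate_or_table(d, "marker")
  expect_true(tab["marker", "ci_lower"] < exp(0.18) &&
                exp(0.18) < tab["marker", "ci_upper"])
  # a degenerate variable is reported as a row error, not an abort
  d$flat <- 1
  tab2 <- univariate_or_table(d, c("marker", "flat"))
  expect_false(is.na(tab2["marker", "or"]))
  expect_true(is.na(tab2["flat", "or"]))
  expect_false(is.na(tab2["flat", "error"]))
})

test_that("backward elimination drops noise and keeps signal", {
  dropped_noise <- kept_signal <- 0
  for (seed in 1:20) {
    set.seed(seed)
    n <- 2000
    d <- data.frame(signal = rnorm(n), noise = rnorm(n))
    d$faller <- rbinom(n, 1, plogis(-0.5 + 0.6 * d$signal))
    sel <- backward_select(d, c("signal", "noise"))
    dropped_noise <- dropped_noise + !("noise" %in% sel$variables)
    kept_signal <- kept_signal + ("signal" %in% sel$variables)
  }
  expect_gte(dropped_noise, 16)  # noise retained ~alpha of the time
  expect_equal(kept_signal, 20)
})

test_that("age and sex are eliminated when outcomes come from the key factors", {
  coh <- as.data.frame(simulate_cohort(n = 2000, seed = 77))
  set.seed(78)
  coh$age <- rnorm(nrow(coh), 72.2, 5.4)
  coh$sex <- rbinom(nrow(coh), 1, 362 / 500)
  sel <- backward_select(coh, c(key_factor_names(), "age", "sex"))
  expect_false("age" %in% sel$variables)
  expect_false("sex" %in% sel$variables)
  expect_true(all(c("age", "sex") %in% sel$removal_log$variable))
})

test_that("an empty surviving set yields the intercept-only model", {
  set.seed(10)
  d <- data.frame(pure_noise = rnorm(1500),
                  faller = rbinom(1500, 1, 0.4))
  sel <- backward_select(d, "pure_noise", alpha = 1e-6)
  expect_length(sel$coefficients, 0)
  expect_lt(abs(plogis(sel$intercept) - mean(d$faller)), 1e-8)
})

test_that("Hosmer-Lemeshow detects gross misspecification but not the truth", {
  set.seed(21)
  n <- 2000
  x <- rnorm(n)
  d_true <- data.frame(x = x, faller = rbinom(n, 1, plogis(-0.4 + 0.9 * x)))
  fit <- fit_logistic(d_true, "x")
  hl <- hosmer_lemeshow(fit, d_true)
  expect_equal(hl$df, 8)
  expect_gt(hl$p_value, 0.01)
  # strong curvature fitted linearly
  d_bad <- data.frame(x = x, faller = rbinom(n, 1, plogis(-1.5 + 2 * x^2)))
  fit_bad <- fit_logistic(d_bad, "x")
  expect_lt(hosmer_lemeshow(fit_bad, d_bad)$p_value, 1e-4)
  expect_error(hosmer_lemeshow(fit, d_true[1:30, ]), "at least")
})
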