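# Brute-force Mann-Whitney AUC: (concordant pairs + half ties) / (n1 * n0).
pairwise_auc <- function(scores, labels) {
  x <- scores[labels == 1]
  y <- scores[labels == 0]
  total <- 0
  for (xi in x) total <- total + sum(xi > y) + 0.5 * sum(xi == y)
  total / (length(x) * length(y))
}

# Small random two-covariate cohort with a logistic outcome; covariate
# names are outside the registry so no model-unit scaling applies.
tiny_logistic_data <- function(n, beta0 = -0.3, beta = c(0.8, -0.5),
                               seed = 1) {
  set.seed(seed)
  x1 <- rnorm(n)
  x2 <- rnorm(n)
  eta <- beta0 + beta[1] * x1 + beta[2] * x2
  data.frame(x1 = x1, x2 = x2, faller = rbinom(n, 1, plogis(eta)))
}

# The published cohort medians in natural units.
median_person <- c(
  multidimensional_balance = 32, lean_body_mass = 42.2,
  fat_body_mass = 38.3, total_pa = 2473, vigorous_pa = 0,
  rest_period_weekdays = 4.3, health_conditions = 3,
  environmental_hazards = 6
)
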