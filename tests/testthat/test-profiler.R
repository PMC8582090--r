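test_that("factor classification follows the published interval semantics", {
  tab <- published_cutoffs()
  expect_equal(classify_factor(29, "multidimensional_balance", tab),
               "very_high")
  expect_equal(classify_factor(34, "multidimensional_balance", tab), "low")
  expect_equal(classify_factor(33, "multidimensional_balance", tab),
               "moderate")
  expect_equal(classify_factor(30, "multidimensional_balance", tab), "high")
  expect_equal(classify_factor(3, "health_conditions", tab), "moderate")
  expect_equal(classify_factor(42, "fat_body_mass", tab), "high")
  expect_equal(classify_factor(43, "fat_body_mass", tab), "very_high")
  expect_warning(out <- classify_factor(45, "multidimensional_balance", tab),
                 "clamped")
  expect_equal(out, "low")
  expect_error(classify_factor(1, "vigorous_pa", tab), "not in the cutoff")
})

test_that("per-factor strata are monotone in the factor value", {
  for (tab in list(published_cutoffs(), derive_cutoffs())) {
    for (v in names(tab$factors)) {
      entry <- tab$factors[[v]]
      vals <- seq(min(entry$rounded) - 3 * entry$precision,
                  max(entry$rounded) + 3 * entry$precision,
                  by = entry$precision / 2)
      vals <- vals[vals >= 0]
      ranks <- match(vapply(vals, classify_factor, factor = v,
                            cutoff_table = tab, FUN.VALUE = character(1)),
                     c("low", "moderate", "high", "very_high"))
      if (entry$direction == "protective") {
        expect_true(all(diff(ranks) <= 0), info = v)
      } else {
        expect_true(all(diff(ranks) >= 0), info = v)
      }
    }
  }
})

test_that("the median person sits at moderate overall risk", {
  p <- individual_probability(measurements = median_person)
  expect_equal(p, 0.309, tolerance = 1e-3)
  rep <- profile_report(measurements = median_person)
  expect_equal(rep$overall_stratum, "moderate")
  expect_equal(rep$probability, p)
  expect_true(all(lengths(rep$per_factor_stratum) == 1))
})

test_that("individual probability is strict about inputs and monotone in hazards", {
  incomplete <- median_person[setdiff(names(median_person),
                                      "lean_body_mass")]
  expect_error(individual_probability(measurements = incomplete),
               "lean_body_mass")
  more_hazards <- median_person
  more_hazards[["environmental_hazards"]] <-
    more_hazards[["environmental_hazards"]] + 1
  expect_gt(individual_probability(measurements = more_hazards),
            individual_probability(measurements = median_person))
})

test_that("the overall stratum uses half-open probability intervals", {
  p <- individual_probability(measurements = median_person)
  # place each cutoff exactly at the person's probability in turn
  at_mod_high <- profile_report(measurements = median_person,
                                cuts = cut_probabilities(0.05, p, 0.9))
  expect_equal(at_mod_high$overall_stratum, "high")
  at_low_mod <- profile_report(measurements = median_person,
                               cuts = cut_probabilities(p, 0.5, 0.9))
  expect_equal(at_low_mod$overall_stratum, "moderate")
  at_vhigh <- profile_report(measurements = median_person,
                             cuts = cut_probabilities(0.05, 0.1, p))
  expect_equal(at_vhigh$overall_stratum, "very_high")
})

test_that("improvement deltas match the published worked example", {
  tab <- published_cutoffs()
  d <- improvement_deltas(29, "multidimensional_balance", tab)
  expect_equal(d[["high"]], 1)
  expect_equal(d[["moderate"]], 3)
  expect_equal(d[["low"]], 5)
  # risk factors improve downwards
  expect_equal(improvement_deltas(44, "fat_body_mass", tab)[["high"]], -2)
  # already at low risk: nothing to improve
  expect_length(improvement_deltas(38, "multidimensional_balance", tab), 0)
})

test_that("applying an improvement delta lands exactly in the target stratum", {
  for (tab in list(published_cutoffs(), derive_cutoffs())) {
    for (v in names(tab$factors)) {
      entry <- tab$factors[[v]]
      set.seed(101)
      vals <- unique(round(runif(
        8, max(0, min(entry$rounded) - 2 * entry$precision),
        max(entry$rounded) + 2 * entry$precision) / entry$precision) *
          entry$precision)
      for (val in vals) {
        d <- improvement_deltas(val, v, tab)
        expect_true(all(d[names(d) != "very_high"] != 0))
        # deltas grow with the ambition of the target (nearest listed first)
        if (length(d) > 1) expect_true(all(diff(abs(unname(d))) >= 0))
        for (target in names(d)) {
          expect_equal(classify_factor(val + d[[target]], v, tab), target,
                       info = paste(v, val, target))
        }
      }
    }
  }
})

test_that("risk profiles round-trip through JSON", {
  rep <- profile_report(measurements = median_person)
  back <- risk_profile_from_json(risk_profile_json(rep))
  expect_equal(back$probability, rep$probability)
  expect_equal(back$overall_stratum, rep$overall_stratum)
  expect_equal(back$per_factor_stratum, rep$per_factor_stratum)
  expect_equal(back$deltas, rep$deltas)
  expect_equal(back$inputs, rep$inputs)
})

test_that("a person beyond every low-risk threshold profiles low everywhere", {
  fit_person <- c(
    multidimensional_balance = 36, lean_body_mass = 48,
    fat_body_mass = 30, total_pa = 4000, vigorous_pa = 0,
    rest_period_weekdays = 2.0, health_conditions = 1,
    environmental_hazards = 2
  )
  rep <- profile_report(measurements = fit_person)
  expect_true(all(unlist(rep$per_factor_stratum) == "low"))
  expect_equal(rep$overall_stratum, "low")
  expect_true(all(lengths(rep$deltas) == 0))
})
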