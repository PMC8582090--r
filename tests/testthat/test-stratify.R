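test_that("cut probabilities validate their ordering", {
  cuts <- cut_probabilities()
  expect_equal(cuts$mod_high, 0.35939)
  expect_error(cut_probabilities(0.5, 0.3, 0.6), "low_mod < mod_high")
  expect_error(cut_probabilities(0.25, 0.36, 1.0), "high_vhigh < 1")
})

test_that("the joint profile places factors on complementary percentile sides", {
  prof <- build_profile(p = 45)
  expect_equal(prof[["multidimensional_balance"]], 31.2)
  expect_equal(prof[["lean_body_mass"]], 41.18)
  expect_equal(prof[["total_pa"]], 23.076)       # 100 MET-min/wk units
  expect_equal(prof[["fat_body_mass"]], 39.3)    # risk side, 55th
  expect_equal(prof[["rest_period_weekdays"]], 4.54)
  expect_equal(prof[["health_conditions"]], 3.4)
  expect_equal(prof[["environmental_hazards"]], 6.6)
  expect_equal(prof[["vigorous_pa"]], 0)
  # at the median both sides coincide with the printed medians
  med <- build_profile(p = 50)
  expect_equal(med[["multidimensional_balance"]], 32)
  expect_equal(med[["fat_body_mass"]], 38.3)
  expect_equal(med[["total_pa"]], 24.73)
  # vigorous PA stays zero across the whole profile range
  for (p in c(1, 30, 60, 79, 99)) {
    expect_equal(build_profile(p = p)[["vigorous_pa"]], 0)
  }
  expect_error(build_profile(p = 0.5), "\\[1, 99\\]")
})

test_that("the profile probability reproduces the study cutoff at p = 45", {
  expect_lt(abs(profile_probability(p = 45) - 0.35939), 0.001)
  expect_equal(profile_probability(p = 50), 0.309, tolerance = 1e-3)
})

test_that("the profile probability is strictly decreasing in p", {
  p <- seq(1, 99, by = 0.5)
  pi_p <- vapply(p, function(pp) profile_probability(p = pp), numeric(1))
  expect_true(all(diff(pi_p) < 0))
})

test_that("a sign-inconsistent model is rejected with the offender named", {
  bad <- fall_model()
  bad$coefficients[["multidimensional_balance"]] <- 0.05
  expect_error(profile_probability(bad, p = 45),
               "multidimensional_balance")
})

test_that("percentile inversion is consistent with the forward map", {
  for (c in c(0.25, 0.35939, 0.50)) {
    p_star <- solve_percentile(c = c)
    expect_lt(abs(profile_probability(p = p_star) - c), 1e-10)
  }
  c50 <- profile_probability(p = 50)
  expect_equal(solve_percentile(c = c50), 50, tolerance = 1e-8)
  expect_error(solve_percentile(c = 0.99), "attainable")
  expect_error(solve_percentile(c = 0.001), "attainable")
})

test_that("derived cutoffs respect ordering, symmetry and the known boundaries", {
  tab <- derive_cutoffs()
  # percentile roots fall as the cut probability rises (higher pi = worse)
  expect_true(tab$p_star_protective[["low_mod"]] >
                tab$p_star_protective[["mod_high"]])
  expect_true(tab$p_star_protective[["mod_high"]] >
                tab$p_star_protective[["high_vhigh"]])
  # complement symmetry between the protective and risk sides
  expect_equal(unname(tab$p_star_protective + tab$p_star_risk),
               rep(100, 3), tolerance = 1e-10)
  for (entry in tab$factors) {
    b <- entry$continuous
    if (entry$direction == "protective") {
      expect_true(b[["low_mod"]] > b[["mod_high"]] &&
                    b[["mod_high"]] > b[["high_vhigh"]])
    } else {
      expect_true(b[["low_mod"]] < b[["mod_high"]] &&
                    b[["mod_high"]] < b[["high_vhigh"]])
    }
  }
  # boundaries that reproduce the published reference values
  expect_equal(unname(tab$factors$lean_body_mass$rounded[["low_mod"]]), 44)
  expect_equal(unname(
    tab$factors$multidimensional_balance$rounded[["low_mod"]]), 33)
  expect_equal(unname(
    tab$factors$fat_body_mass$rounded[["high_vhigh"]]), 42)
  expect_equal(unname(
    tab$factors$environmental_hazards$rounded[["high_vhigh"]]), 8)
  # vigorous PA is excluded from the table but kept in the model
  expect_false("vigorous_pa" %in% names(tab$factors))
})

test_that("presented strata partition each factor's range without overlap", {
  for (tab in list(derive_cutoffs(), published_cutoffs())) {
    pres <- present_cutoffs(tab)
    for (v in unique(pres$factor)) {
      rows <- pres[pres$factor == v & !is.na(pres$lo), ]
      entry <- tab$factors[[v]]
      # order strata along the value axis and check they abut exactly
      rows <- rows[order(rows$lo), ]
      s <- entry$precision
      if (nrow(rows) > 1) {
        gaps <- rows$lo[-1] - rows$hi[-nrow(rows)]
        expect_equal(unname(gaps), rep(s, nrow(rows) - 1), tolerance = 1e-9,
                     info = v)
      }
      expect_true(is.infinite(rows$lo[1]) &&
                    is.infinite(rows$hi[nrow(rows)]), info = v)
    }
  }
})

test_that("the balance row renders exactly as the published intervals", {
  pres <- present_cutoffs(derive_cutoffs())
  bal <- pres[pres$factor == "multidimensional_balance", ]
  expect_equal(bal$text[bal$stratum == "low"], "> 33")
  expect_equal(bal$text[bal$stratum == "moderate"], "32-33")
  expect_equal(bal$text[bal$stratum == "high"], "30-31")
  expect_equal(bal$text[bal$stratum == "very_high"], "< 30")
})

test_that("published reference intervals encode the printed table", {
  pres <- present_cutoffs(published_cutoffs())
  get <- function(v, st) pres$text[pres$factor == v & pres$stratum == st]
  expect_equal(get("lean_body_mass", "low"), "> 44")
  expect_equal(get("lean_body_mass", "moderate"), "42-44")
  expect_equal(get("lean_body_mass", "high"), "39-41")
  expect_equal(get("lean_body_mass", "very_high"), "< 39")
  expect_equal(get("fat_body_mass", "high"), "39-42")
  expect_equal(get("fat_body_mass", "very_high"), "> 42")
  expect_equal(get("health_conditions", "moderate"), "= 3")
  expect_equal(get("health_conditions", "high"), "4-5")
  expect_equal(get("environmental_hazards", "high"), "6-8")
  expect_equal(get("rest_period_weekdays", "moderate"), "4.0-4.4")
  expect_equal(get("total_pa", "very_high"), "< 1900")
})
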