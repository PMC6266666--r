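test_that("PD50 fitting recovers a bracketed dose and scales with dose units", {
  obs <- data.frame(dose = c(0.5, 1, 2, 4, 8, 16), n_injected = 20,
                    n_paralysed = c(1, 4, 9, 15, 19, 20))
  fit <- fit_pd50(obs)
  expect_false(fit$unstable)
  expect_gt(fit$pd50, 0.5); expect_lt(fit$pd50, 16)
  expect_true(fit$ci_low <= fit$pd50 && fit$pd50 <= fit$ci_high)
  expect_gt(fit$slope, 0)

  # doubling all doses doubles the PD50 exactly (log-dose equivariance)
  obs2 <- obs; obs2$dose <- obs2$dose * 2
  fit2 <- fit_pd50(obs2)
  expect_equal(fit2$pd50, 2 * fit$pd50, tolerance = 1e-6)
  expect_equal(fit2$slope, fit$slope, tolerance = 1e-6)

  # probit link gives a nearby but distinct estimate
  fitp <- fit_pd50(obs, link = "probit")
  expect_equal(fitp$pd50, fit$pd50, tolerance = 0.1)
})

test_that("complete separation is flagged and reported as a dose bracket", {
  obs <- data.frame(dose = c(1, 2, 4, 8), n_injected = 10,
                    n_paralysed = c(0, 10, 10, 10))
  fit <- fit_pd50(obs)
  expect_true(fit$unstable)
  expect_true(is.na(fit$pd50))
  expect_equal(fit$ci_low, 1)
  expect_equal(fit$ci_high, 2)
  expect_error(fit_pd50(data.frame(dose = c(1, 2), n_injected = 10,
                                   n_paralysed = c(2, 5))),
               "3 distinct")
})

test_that("dose unit conversions are exact", {
  expect_equal(per_gram(1.16, 0.025), 46.4)
  expect_equal(per_gram(15.58, 0.025), 623.2)
  expect_equal(per_gram(3.3, 1), 3.3)
  expect_equal(per_gram(per_gram(7, 0.025), 1 / 0.025), 7)
  expect_error(per_gram(1, 0), "positive")
  expect_equal(dose_from_concentration(10.5), 22.05)
  expect_equal(doses_per_harvest(400, 15.58), 400 / 15.58)
})

test_that("composition fractions are percentages summing to 100", {
  one <- data.frame(family_label = "f1", precursor_count_intensity = 5,
                    expression = 2)
  expect_equal(composition_fractions(one)$intensity_pct, 100)
  two <- data.frame(family_label = c("f1", "f2"),
                    precursor_count_intensity = c(3, 3),
                    expression = c(8, 8))
  cf <- composition_fractions(two)
  expect_equal(cf$intensity_pct, c(50, 50))
  expect_equal(cf$expression_pct, c(50, 50))

  spec <- synthetic_venom_spec(seed = 3)
  planted <- composition_fractions(planted_family_abundances(spec))
  planted <- planted[match(spec$family_profiles$family,
                           planted$family_label), ]
  expect_equal(planted$intensity_pct, spec$family_profiles$share)
  expect_equal(planted$expression_pct, spec$family_profiles$share)
  expect_equal(sum(planted$intensity_pct), 100, tolerance = 1e-9)
  expect_equal(sum(planted$expression_pct), 100, tolerance = 1e-9)

  zero <- data.frame(family_label = "f", precursor_count_intensity = 0,
                     expression = 0)
  expect_error(composition_fractions(zero), "positive")
})

test_that("correlation handles proportional, anti-proportional and degenerate input", {
  rec <- data.frame(precursor_count_intensity = c(1, 2, 3, 4),
                    expression = c(2, 4, 6, 8))
  expect_equal(expression_intensity_correlation(rec)$r, 1)
  rec$expression <- -rec$expression
  expect_equal(expression_intensity_correlation(rec)$r, -1)
  flat <- data.frame(precursor_count_intensity = c(1, 1, 1),
                     expression = c(1, 2, 3))
  expect_error(expression_intensity_correlation(flat), "variance")
  expect_error(expression_intensity_correlation(rec[1:2, ]), "3 records")
  expect_error(expression_intensity_correlation(rec, log = TRUE), "positive")
})
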