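test_that("the spec validates its invariants", {
  expect_error(synthetic_venom_spec(), "seed is mandatory")
  bad <- default_family_profiles()
  bad$share[1] <- 50
  expect_error(synthetic_venom_spec(seed = 1, family_profiles = bad),
               "sum to 100")
  infeasible <- default_family_profiles()
  infeasible$mature_min[1] <- 5
  infeasible$mature_max[1] <- 5
  expect_error(synthetic_venom_spec(seed = 1, family_profiles = infeasible),
               "infeasible")
})

test_that("generators are fully deterministic under a fixed seed", {
  run <- function() {
    spec <- synthetic_venom_spec(seed = 123)
    gen <- generate_precursors(spec)
    list(gen = gen,
         masses = generate_mass_lists(gen, spec),
         psm = generate_psm_table(gen, spec),
         dr = generate_dose_response(spec),
         ab = generate_expression(spec))
  }
  expect_identical(run(), run())
})

test_that("the planted repertoire realises the family cysteine census", {
  spec <- synthetic_venom_spec(seed = 8)
  gen <- generate_precursors(spec)
  fp <- spec$family_profiles
  expect_identical(nrow(gen$precursors), sum(fp$n_members))
  census <- table(gen$truth$family, gen$truth$n_cys)
  for (f in seq_len(nrow(fp))) {
    expect_identical(unname(census[fp$family[f], as.character(fp$n_cys[f])]),
                     as.integer(fp$n_members[f]))
  }
  # every mature sequence really contains its family's cysteine count,
  # at non-adjacent positions
  for (i in seq_len(nrow(gen$truth))) {
    pos <- which(strsplit(gen$truth$mature_seq[i], "")[[1]] == "C")
    expect_identical(length(pos), as.integer(gen$truth$n_cys[i]))
    if (length(pos) > 1L) expect_true(all(diff(pos) > 1L))
  }
  # a >90%-identity subtype pair is planted for the nomenclature stage
  expect_gt(max(identity_matrix(gen$precursors$sequence)[
    upper.tri(diag(nrow(gen$precursors)))]), 90)
})

test_that("noise-free mass lists shift by exactly n_cys per-cysteine deltas", {
  spec <- synthetic_venom_spec(seed = 14, mass_noise_sd = 0)
  gen <- generate_precursors(spec)
  ml <- generate_mass_lists(gen, spec)
  n <- nrow(gen$truth)
  delta <- ml$ra$mass[seq_len(n)] - ml$native$mass[seq_len(n)]
  expect_equal(delta, gen$truth$n_cys * mass_constants()$delta_ra_per_cys,
               tolerance = 1e-9)
})

test_that("decoy-only lists yield no cysteine assignments", {
  spec <- synthetic_venom_spec(seed = 25)
  gen <- generate_precursors(spec)
  ml <- generate_mass_lists(gen, spec)
  n <- nrow(gen$truth)
  res <- pair_conditions(ml$native[-seq_len(n), ], ml$ra[-seq_len(n), ],
                         tolerance = 0.05)
  expect_identical(nrow(res$assignments), 0L)
})

test_that("dose-response draws follow the planted logistic curve", {
  spec <- synthetic_venom_spec(seed = 33, pd50_truth = list("1 min" = 3.07),
                               doses = 3.07, n_per_dose = 4000L)
  dr <- generate_dose_response(spec)
  expect_equal(dr$n_paralysed / dr$n_injected, 0.5, tolerance = 0.05)

  steep <- synthetic_venom_spec(seed = 33, pd50_truth = list("1 min" = 3.07),
                                pd50_slope = 1e6, n_per_dose = 50L)
  dr2 <- generate_dose_response(steep)
  expect_identical(dr2$n_paralysed,
                   ifelse(dr2$dose > 3.07, dr2$n_injected, 0L))
})

test_that("expression tables hit the correlation target", {
  exact1 <- synthetic_venom_spec(seed = 2, expression_correlation_target = 1,
                                 empirical_correlation = FALSE)
  r1 <- expression_intensity_correlation(generate_expression(exact1),
                                         log = TRUE)$r
  expect_gt(r1, 0.99)

  pinned <- synthetic_venom_spec(seed = 2)
  expect_equal(expression_intensity_correlation(generate_expression(pinned),
                                                log = TRUE)$r,
               0.51, tolerance = 1e-9)

  # population-correlation mode: the mean sample r over seeds approaches the
  # target
  rs <- vapply(1:50, function(s) {
    spec <- synthetic_venom_spec(seed = 30000 + s,
                                 empirical_correlation = FALSE)
    expression_intensity_correlation(generate_expression(spec), log = TRUE)$r
  }, numeric(1))
  expect_equal(mean(rs), 0.51, tolerance = 0.05)

  null <- vapply(1:50, function(s) {
    spec <- synthetic_venom_spec(seed = 40000 + s,
                                 expression_correlation_target = 0,
                                 empirical_correlation = FALSE)
    expression_intensity_correlation(generate_expression(spec), log = TRUE)$r
  }, numeric(1))
  expect_lt(abs(mean(null)), 0.05)
})
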