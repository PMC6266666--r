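# A deterministic signal peptide used to build precursors around known
# mature sequences.
SIG <- "MKLLVLAVLFATSALA"

make_precursor <- function(id, mature, family = "fam1", expression = 100) {
  data.frame(id = id, sequence = paste0(SIG, mature),
             signal_end = nchar(SIG), family = family,
             expression = expression, stringsAsFactors = FALSE)
}

test_that("enumeration yields the signal-cleaved form and its trimmed subtypes", {
  mature <- "KNDRECKKIAEVCYRHEECCSFQCPSYWGKCVS"  # 33-residue 6-Cys peptide
  p <- make_precursor("p1", mature)
  cand <- enumerate_candidates(p, max_n_trim = 2, max_c_trim = 0,
                               allow_pyroglu = FALSE)
  expect_true(mature %in% cand$sequence)
  expect_true("DRECKKIAEVCYRHEECCSFQCPSYWGKCVS" %in% cand$sequence)  # 2-trim
  expect_identical(nrow(cand), 3L)
  expect_true(all(cand$start >= p$signal_end & cand$end <= nchar(p$sequence)))
  # predicted masses are consistent with the mass module
  full <- cand[cand$provenance == "signal_cleaved", ]
  expect_equal(full$predicted_native,
               peptide_mass(mature, modifications(n_disulfides = 3)))
  expect_equal(full$predicted_ra, ra_mass(mature))
})

test_that("candidate counts follow the enumeration formula with domains", {
  mature <- paste0(strrep("ACDEFGHIKL", 8))  # 80 residues, no Q starts
  p <- make_precursor("p1", mature)
  se <- nchar(SIG)
  domains <- data.frame(id = "p1", start = se + c(0, 20, 40, 60) + 10,
                        end = se + c(0, 20, 40, 60) + 20)
  cand <- enumerate_candidates(p, domains = domains, max_n_trim = 4,
                               max_c_trim = 2, allow_pyroglu = TRUE)
  # 1 full + 4 N-trims + 2 C-trims + 4 domains, no Q-start pyroGlu variants
  expect_identical(nrow(cand), 11L)
  expect_identical(sum(cand$provenance == "domain_excised"), 4L)
})

test_that("pyroGlu variants appear only for glutamine starts, and duplicates collapse", {
  mature <- "QACDEFGHIKLMNPQRSTVWY"
  p <- make_precursor("p1", mature)
  cand <- enumerate_candidates(p, max_n_trim = 0, max_c_trim = 0)
  expect_identical(nrow(cand), 2L)
  expect_identical(sort(unique(cand$provenance)),
                   c("pyroglu_variant", "signal_cleaved"))
  pv <- cand[cand$provenance == "pyroglu_variant", ]
  expect_equal(pv$predicted_native,
               cand$predicted_native[cand$provenance == "signal_cleaved"] +
                 mass_constants()$delta_pyroglu)
  # a domain annotation equal to the mature region deduplicates away
  dup_dom <- data.frame(id = "p1", start = nchar(SIG),
                        end = nchar(p$sequence))
  cand2 <- enumerate_candidates(p, domains = dup_dom, max_n_trim = 0,
                                max_c_trim = 0)
  expect_identical(nrow(cand2), nrow(cand))
})

test_that("a precursor without a signal annotation is rejected", {
  p <- data.frame(id = "p1", sequence = "MKAGASDE", signal_end = NA,
                  family = "f", expression = 1)
  expect_error(enumerate_candidates(p), "signal_end")
  expect_identical(nrow(enumerate_candidates(
    make_precursor("p1", "ACDEFGHIK"), max_n_trim = 0, max_c_trim = 0)), 1L)
})

test_that("peaks match candidates within tolerance with signed deltas", {
  mature <- "ITCDLIGNERLCVLHCLAKGFRGGWCDGRKVCNCRR"
  cand <- enumerate_candidates(make_precursor("dg3a", mature),
                               max_n_trim = 0, max_c_trim = 0)
  peaks <- data.frame(mass = 4057.87, intensity = 100, condition = "native")
  m <- match_candidates(cand, peaks, tolerance = 0.15)
  expect_identical(nrow(m), 1L)
  expect_equal(m$delta, 4057.87 - cand$predicted_native, tolerance = 1e-9)
  expect_lt(m$delta, 0)

  exact <- data.frame(mass = cand$predicted_native, intensity = 1,
                      condition = "native")
  expect_equal(match_candidates(cand, exact, tolerance = 0.15)$delta, 0)

  # RA peaks are compared against the reduced/alkylated prediction
  ra_peak <- data.frame(mass = cand$predicted_ra, intensity = 1,
                        condition = "reduced_alkylated")
  expect_identical(nrow(match_candidates(cand, ra_peak, tolerance = 0.15)), 1L)
  expect_identical(nrow(match_candidates(cand, peaks, tolerance = 1e-6)), 0L)
})

test_that("greedy matching recovers planted peaks, ignores decoys, and is optimal here", {
  set.seed(23)
  matures <- replicate(10, {
    base <- strsplit(random_peptide_seq(30), "")[[1]]
    base[seq(2, 12, by = 2)] <- "C"
    paste(base, collapse = "")
  })
  pre <- do.call(rbind, lapply(seq_along(matures), function(i) {
    make_precursor(paste0("p", i), matures[i])
  }))
  cand <- enumerate_all_candidates(pre, max_n_trim = 0, max_c_trim = 0,
                                   allow_pyroglu = FALSE)
  decoys <- cand$predicted_native[1:5] + runif(5, 1, 5)
  peaks <- data.frame(mass = c(cand$predicted_native, decoys),
                      intensity = runif(15, 1, 100), condition = "native")
  m <- match_candidates(cand, peaks, tolerance = 0.15)
  expect_identical(nrow(m), 10L)
  expect_true(all(m$peak_mass %in% cand$predicted_native))
  expect_identical(
    max_matching_oracle(cand$predicted_native, peaks$mass, 0.15), 10L)
})

test_that("matching is a partial injection, invariant to input order", {
  set.seed(31)
  spec <- synthetic_venom_spec(seed = 31)
  gen <- generate_precursors(spec)
  ml <- generate_mass_lists(gen, spec)
  cand <- enumerate_all_candidates(gen$precursors)
  m <- match_candidates(cand, ml$native, tolerance = 0.15)
  key <- function(x) {
    x <- x[order(x$precursor_id, x$start, x$peak_mass), ]
    paste(x$precursor_id, x$start, x$end, x$pyroglu, round(x$peak_mass, 6))
  }
  expect_false(anyDuplicated(paste(m$precursor_id, m$start, m$end, m$pyroglu)) > 0)
  expect_false(anyDuplicated(m$peak_mass) > 0)
  m2 <- match_candidates(cand[sample(nrow(cand)), ],
                         ml$native[sample(nrow(ml$native)), ],
                         tolerance = 0.15)
  expect_identical(key(m), key(m2))
})

test_that("planted mature forms are recovered from noisy peak lists", {
  profiles <- default_family_profiles()
  profiles$n_members <- profiles$n_members * 5L  # 105 planted forms
  spec <- synthetic_venom_spec(seed = 77, family_profiles = profiles,
                               mass_noise_sd = 0.02, n_decoy_peaks = 30L)
  gen <- generate_precursors(spec)
  ml <- generate_mass_lists(gen, spec)
  cand <- enumerate_all_candidates(gen$precursors)
  m <- match_candidates(cand, ml$native, tolerance = 0.15)
  hit <- merge(m, gen$truth, by.x = "precursor_id", by.y = "id")
  correct <- hit$start == hit$signal_end & hit$end == nchar(hit$sequence.y)
  expect_gte(sum(correct) / nrow(gen$truth), 0.95)
})
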