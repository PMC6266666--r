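test_that("residue mass table covers the canonical alphabet with sane values", {
  tab <- residue_mass_table()
  expect_length(tab$residues, 20L)
  expect_false(anyDuplicated(names(tab$residues)) > 0)
  expect_true(all(tab$residues > 0))
  expect_identical(names(which.min(tab$residues)), "G")
})

test_that("peptide_mass sums residues, water and modification deltas", {
  tab <- residue_mass_table()
  const <- mass_constants()
  expect_equal(peptide_mass("G"), tab$residues[["G"]] + tab$water_mass)

  # additivity of the pyroGlu delta
  seq_q <- "QDCNPEGARCSSDSDCCYSECIGSLCQP"
  expect_equal(
    peptide_mass(seq_q, modifications(pyroglu = TRUE)) -
      peptide_mass(seq_q),
    const$delta_pyroglu)

  # disulfide delta per bond
  expect_equal(
    peptide_mass(seq_q, modifications(n_disulfides = 3)) -
      peptide_mass(seq_q),
    3 * const$delta_disulfide_per_bond)

  # custom deltas are added verbatim
  expect_equal(
    peptide_mass("GAS", modifications(custom_deltas = c(deamidation = 0.98402))),
    peptide_mass("GAS") + 0.98402)
})

test_that("concatenation additivity holds for unmodified sequences", {
  set.seed(7)
  tab <- residue_mass_table()
  for (i in 1:25) {
    a <- random_peptide_seq(sample(3:30, 1))
    b <- random_peptide_seq(sample(3:30, 1))
    expect_equal(peptide_mass(paste0(a, b)),
                 peptide_mass(a) + peptide_mass(b) - tab$water_mass)
  }
})

test_that("invalid sequences and modification sets are rejected informatively", {
  expect_error(peptide_mass("GAXDE"), "position 3")
  expect_error(peptide_mass(""), "non-empty")
  expect_error(peptide_mass("GASDE", modifications(pyroglu = TRUE)),
               "glutamine")
  expect_error(peptide_mass("CAC", modifications(n_disulfides = 2)),
               "disulfide")
  expect_error(peptide_mass("CAC", modifications(n_cys_alkylated = 3)),
               "alkylated")
  expect_error(ra_mass("CAC", n_cys = 4), "does not match")
})

test_that("ra_mass applies the elemental reduction/alkylation bookkeeping", {
  const <- mass_constants()
  # cysteine-free: no shift at all
  expect_equal(ra_mass("GASDELKT", 0), peptide_mass("GASDELKT"))
  # 6-Cys peptide: oracle = 2 H back per opened disulfide + C2H4O per Cys
  set.seed(11)
  for (i in 1:10) {
    base <- strsplit(random_peptide_seq(30), "")[[1]]
    base[sample(seq(2, 30, by = 2), 6)] <- "C"
    seqc <- paste(base, collapse = "")
    native <- peptide_mass(seqc, modifications(n_disulfides = 3))
    expected_shift <- 3 * 2 * 1.00783 + 6 * 44.02621
    expect_equal(ra_mass(seqc) - native, expected_shift, tolerance = 1e-9)
    expect_equal(expected_shift, 6 * const$delta_ra_per_cys, tolerance = 1e-9)
  }
})

test_that("shift_to_ncys maps shifts to allowed counts with smallest-n ties", {
  const <- mass_constants()
  expect_identical(shift_to_ncys(270.18, 0.10), 6L)
  expect_identical(shift_to_ncys(0.00, 0.10), 0L)
  expect_identical(shift_to_ncys(180.14, 0.10), 4L)
  expect_identical(shift_to_ncys(100, 0.10), NA_integer_)
  # exact planted shifts come back for any allowed n, even at tiny tolerance
  for (n in c(0L, 2L, 4L, 6L, 8L, 10L)) {
    expect_identical(
      shift_to_ncys(n * const$delta_ra_per_cys, 0.001,
                    allowed = c(0L, 2L, 4L, 6L, 8L, 10L)),
      n)
  }
  # equidistant delta between two allowed counts resolves to the smaller
  mid <- 3 * const$delta_ra_per_cys
  expect_identical(shift_to_ncys(mid, tolerance = 60, allowed = c(2L, 4L)), 2L)
})

test_that("mass constants can be overridden from the packaged JSON config", {
  path <- system.file("extdata", "mass_constants.json", package = "venomics")
  expect_true(nzchar(path))
  const <- mass_constants(path)
  expect_equal(const$delta_hydroxyethyl_per_cys, 44.02621)
  expect_equal(const$delta_ra_per_cys,
               const$delta_reduction_per_cys + const$delta_hydroxyethyl_per_cys)
  bad <- tempfile(fileext = ".json")
  writeLines('{"delta_unknown": 1.0}', bad)
  expect_error(mass_constants(bad), "unknown mass constant")
})
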