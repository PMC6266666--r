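# Seeded generators for every input the pipeline consumes: precursor
# repertoires with controlled cysteine scaffolds, two-condition intact-mass
# lists with decoys, PSM tables, quantal dose-response counts, and
# expression/intensity tables. Each generator returns a machine-readable
# truth table so downstream modules can be tested against planted answers.
#
# Random-stream order: generate_precursors seeds at `seed`, generate_mass_lists
# at `seed + 1`, generate_psm_table at `seed + 2`, generate_dose_response at
# `seed + 3`, generate_expression at `seed + 4`, so the generators are
# individually reproducible and order-independent.

.AA_NO_CYS <- setdiff(names(.RESIDUE_MASSES), "C")

#' Default family profile of a synthetic venom
#'
#' Five families mirroring a disulfide-rich asilid-like repertoire: 17
#' six-cysteine peptides across three families (ICK-like, defensin-like and
#' Kazal-like size classes), 2 four-cysteine and 2 cysteine-free linear
#' peptides, with composition shares 30/25/20/15/10%. Mature lengths keep
#' every peptide inside the 1-10 kDa window the mass-list comparison uses.
#'
#' @return Data frame with columns `family`, `n_members`, `n_cys`,
#'   `mature_min`, `mature_max`, `signal_min`, `signal_max`, `share`.
#' @export
default_family_profiles <- function() {
  data.frame(
    family = c("Asilidin-1", "Asilidin-12", "Asilidin-14", "Asilidin-3",
               "Asilidin-4"),
    n_members = c(10L, 4L, 3L, 2L, 2L),
    n_cys = c(6L, 6L, 6L, 4L, 0L),
    mature_min = c(28L, 34L, 55L, 30L, 40L),
    mature_max = c(40L, 40L, 65L, 50L, 75L),
    signal_min = 18L, signal_max = 24L,
    share = c(30, 25, 20, 15, 10),
    stringsAsFactors = FALSE
  )
}

#' Specification of a synthetic venom data set
#'
#' Bundles and validates every knob of the generator family. Defaults mirror
#' the study conditions the pipeline is meant to reproduce: a five-family
#' repertoire with 17/2/2 peptides of 6/4/0 cysteines, 0.02 Da mass noise,
#' 29 decoy peaks per condition, PSM confidences around 98%, an
#' expression-intensity correlation target of 0.51 over 56 records, and
#' paralysis PD50 truths of 1.16/3.07/15.58 ug per fly at 60 min / 1 min /
#' 5 s with slope 2.5 on log10(dose).
#'
#' @param seed Integer seed (mandatory; full determinism).
#' @param family_profiles See [default_family_profiles()]; shares must sum
#'   to 100.
#' @param mass_noise_sd Additive Gaussian noise on each peak mass, Da.
#' @param n_decoy_peaks Decoy peaks added to each condition's mass list.
#' @param psm_confidence_mean,psm_confidence_sd Confidence model (percent)
#'   for planted confident PSMs.
#' @param expression_correlation_target Pearson correlation (log scale)
#'   between expression and intensity in [generate_expression()].
#' @param n_expression_records Rows of the abundance table.
#' @param empirical_correlation If `TRUE` (default) the abundance table is
#'   constructed so its empirical log-scale correlation equals the target
#'   exactly; if `FALSE` the target is the population correlation.
#' @param pd50_truth Named list of true PD50s (ug per fly) per time point.
#' @param pd50_slope True slope on log10(dose).
#' @param doses Dose series in ug per fly.
#' @param n_per_dose Animals injected per dose.
#' @return Object of class `venom_spec` (a validated list).
#' @export
synthetic_venom_spec <- function(seed,
                                 family_profiles = default_family_profiles(),
                                 mass_noise_sd = 0.02,
                                 n_decoy_peaks = 29L,
                                 psm_confidence_mean = 98,
                                 psm_confidence_sd = 1.5,
                                 expression_correlation_target = 0.51,
                                 n_expression_records = 56L,
                                 empirical_correlation = TRUE,
                                 pd50_truth = list("60 min" = 1.16,
                                                   "1 min" = 3.07,
                                                   "5 s" = 15.58),
                                 pd50_slope = 2.5,
                                 doses = c(0.5, 1, 2, 4, 8, 16),
                                 n_per_dose = 20L) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    stop("seed is mandatory for a synthetic venom spec")
  }
  stopifnot(seed == as.integer(seed), mass_noise_sd >= 0, n_decoy_peaks >= 0,
            abs(expression_correlation_target) <= 1,
            n_expression_records >= 3L, pd50_slope > 0,
            all(doses > 0), n_per_dose >= 1L)
  fp <- family_profiles
  req <- c("family", "n_members", "n_cys", "mature_min", "mature_max",
           "signal_min", "signal_max", "share")
  stopifnot(all(req %in% names(fp)), all(fp$n_members >= 0),
            all(fp$n_cys %in% c(0L, 4L, 6L, 8L)),
            all(fp$mature_min <= fp$mature_max),
            all(fp$signal_min <= fp$signal_max), all(fp$share >= 0))
  if (abs(sum(fp$share) - 100) > 1e-9) {
    stop("family composition shares must sum to 100, got ", sum(fp$share))
  }
  if (any(fp$mature_min < 2L * fp$n_cys - 1L)) {
    stop("infeasible profile: mature_min too short to hold non-adjacent cysteines")
  }
  spec <- list(seed = as.integer(seed), family_profiles = fp,
               mass_noise_sd = mass_noise_sd,
               n_decoy_peaks = as.integer(n_decoy_peaks),
               psm_confidence_mean = psm_confidence_mean,
               psm_confidence_sd = psm_confidence_sd,
               expression_correlation_target = expression_correlation_target,
               n_expression_records = as.integer(n_expression_records),
               empirical_correlation = isTRUE(empirical_correlation),
               pd50_truth = pd50_truth, pd50_slope = pd50_slope,
               doses = doses, n_per_dose = as.integer(n_per_dose))
  class(spec) <- "venom_spec"
  spec
}

# Random mature region of length len with exactly n_cys cysteines at
# non-adjacent positions; never starts with Q (so planted native forms carry
# no incidental pyroGlu variant) or C.
.random_mature <- function(len, n_cys) {
  res <- sample(.AA_NO_CYS, len, replace = TRUE)
  if (res[1] == "Q") res[1] <- "A"
  if (n_cys > 0L) {
    stopifnot(len >= 2L * n_cys - 1L)
    repeat {
      pos <- sort(sample(2:len, n_cys))
      if (n_cys == 1L || all(diff(pos) > 1L)) break
    }
    res[pos] <- "C"
  }
  paste(res, collapse = "")
}

.random_signal <- function(len) {
  paste(c("M", sample(.AA_NO_CYS, len - 1L, replace = TRUE)), collapse = "")
}

#' Generate a synthetic precursor repertoire with truth table
#'
#' Each precursor is a random signal peptide followed by a mature region
#' holding exactly the family's cysteine count at non-adjacent positions.
#' The first family with at least two members contains a planted
#' >90%-identity subtype pair (its second member is the first with two
#' mature-region substitutions), exercising the nomenclature clustering.
#' Expression values are log-normal, scaled by family composition share.
#'
#' @param spec A [synthetic_venom_spec()].
#' @return List with `precursors` (data frame: `id`, `sequence`,
#'   `signal_end`, `family`, `expression`) and `truth` (adds `mature_seq`,
#'   `n_cys`, `native_mass`, `ra_mass`, `share`).
#' @export
generate_precursors <- function(spec) {
  stopifnot(inherits(spec, "venom_spec"))
  set.seed(spec$seed)
  fp <- spec$family_profiles
  rows <- list()
  for (f in seq_len(nrow(fp))) {
    for (m in seq_len(fp$n_members[f])) {
      sig_len <- sample(fp$signal_min[f]:fp$signal_max[f], 1L)
      mat_len <- sample(fp$mature_min[f]:fp$mature_max[f], 1L)
      signal <- .random_signal(sig_len)
      mature <- .random_mature(mat_len, fp$n_cys[f])
      rows[[length(rows) + 1L]] <- list(family = fp$family[f],
                                        n_cys = fp$n_cys[f],
                                        share = fp$share[f],
                                        n_members = fp$n_members[f],
                                        signal = signal, mature = mature)
    }
  }
  # plant a >90%-identity subtype pair in the first family with >= 2 members
  fam_first <- fp$family[fp$n_members >= 2L][1]
  idx <- which(vapply(rows, function(r) r$family == fam_first, logical(1)))
  if (length(idx) >= 2L) {
    a <- rows[[idx[1]]]
    mature <- strsplit(a$mature, "")[[1]]
    subst <- sample(which(mature != "C" & seq_along(mature) > 1L), 2L)
    for (s in subst) {
      mature[s] <- sample(setdiff(.AA_NO_CYS, mature[s]), 1L)
    }
    rows[[idx[2]]]$signal <- a$signal
    rows[[idx[2]]]$mature <- paste(mature, collapse = "")
  }
  truth <- do.call(rbind, lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    seqc <- paste0(r$signal, r$mature)
    expression <- rlnorm(1, meanlog = log(1000 * r$share / r$n_members),
                         sdlog = 0.5)
    data.frame(
      id = sprintf("pre%03d", i), family = r$family, sequence = seqc,
      signal_end = nchar(r$signal), mature_seq = r$mature,
      n_cys = r$n_cys,
      native_mass = peptide_mass(r$mature,
                                 modifications(n_disulfides = r$n_cys %/% 2L)),
      ra_mass = ra_mass(r$mature),
      expression = expression, share = r$share,
      stringsAsFactors = FALSE)
  }))
  precursors <- truth[, c("id", "sequence", "signal_end", "family",
                          "expression")]
  list(precursors = precursors, truth = truth)
}

# Draw decoy masses uniformly in `range`, rejecting any candidate within
# `exclusion` Da of an allowed reduction/alkylation shift (including 0) from
# any already-placed mass in either condition, so decoys can never form a
# valid native/RA pair.
.draw_decoys <- function(n, existing, range, allowed, constants,
                         exclusion = 1) {
  shift <- constants$delta_ra_per_cys
  offsets <- c(-rev(allowed), allowed) * shift
  out <- numeric(0)
  guard <- 0L
  while (length(out) < n) {
    guard <- guard + 1L
    if (guard > 10000L * max(n, 1L)) stop("decoy rejection sampling stalled")
    cand <- runif(1, range[1], range[2])
    pool <- c(existing, out)
    if (length(pool) == 0L ||
        min(abs(outer(cand - pool, offsets, "-"))) >= exclusion) {
      out <- c(out, cand)
    }
  }
  out
}

#' Generate native and reduced/alkylated mass lists
#'
#' Each planted mature form contributes a native peak at its oxidised mass
#' and an RA peak at its reduced/hydroxyethyl-alkylated mass, both with
#' additive Gaussian noise; intensities are log-normal, scaled by family
#' composition share. Decoy peaks are drawn uniformly over `mass_range` at
#' least 1 Da away from any allowed-shift relation with any other peak.
#'
#' @param generated Output of [generate_precursors()].
#' @param spec The [synthetic_venom_spec()].
#' @param mass_range Mass window for decoys, Da.
#' @param constants Mass constants, from [mass_constants()].
#' @return List with `native` and `ra` peak data frames (`mass`,
#'   `intensity`, `condition`) and `truth` (planted peptide masses after
#'   noise, with ids).
#' @export
generate_mass_lists <- function(generated, spec,
                                mass_range = c(1000, 10000),
                                constants = mass_constants()) {
  stopifnot(inherits(spec, "venom_spec"))
  set.seed(spec$seed + 1L)
  truth <- generated$truth
  n <- nrow(truth)
  nat_mass <- truth$native_mass + rnorm(n, 0, spec$mass_noise_sd)
  ra_mass_obs <- truth$ra_mass + rnorm(n, 0, spec$mass_noise_sd)
  intensity <- rlnorm(n, meanlog = log(1e6 * truth$share /
                                         ave(truth$share, truth$family,
                                             FUN = length)),
                      sdlog = 0.4)
  ra_intensity <- intensity * rlnorm(n, 0, 0.2)
  existing <- c(nat_mass, ra_mass_obs)
  decoy_nat <- .draw_decoys(spec$n_decoy_peaks, existing, mass_range,
                            c(0L, 4L, 6L, 8L), constants)
  decoy_ra <- .draw_decoys(spec$n_decoy_peaks, c(existing, decoy_nat),
                           mass_range, c(0L, 4L, 6L, 8L), constants)
  decoy_int <- function(k) rlnorm(k, meanlog = log(2e5), sdlog = 0.6)
  native <- data.frame(
    mass = c(nat_mass, decoy_nat),
    intensity = c(intensity, decoy_int(spec$n_decoy_peaks)),
    condition = "native", stringsAsFactors = FALSE)
  ra <- data.frame(
    mass = c(ra_mass_obs, decoy_ra),
    intensity = c(ra_intensity, decoy_int(spec$n_decoy_peaks)),
    condition = "reduced_alkylated", stringsAsFactors = FALSE)
  list(native = native, ra = ra,
       truth = data.frame(id = truth$id, family = truth$family,
                          n_cys = truth$n_cys,
                          native_mass_obs = nat_mass,
                          ra_mass_obs = ra_mass_obs,
                          intensity = intensity,
                          stringsAsFactors = FALSE))
}

# Random tryptic-looking peptide for decoy PSMs.
.random_peptide <- function(len) {
  paste(c(sample(.AA_NO_CYS, len - 1L, replace = TRUE), "K"), collapse = "")
}

#' Generate a PSM table with planted identification truth
#'
#' Every true protein receives `k` distinct confident tryptic fragments of
#' its mature region (`k` drawn uniformly from 1-5, capped by the number of
#' fragments the sequence yields; recorded in the truth table) with
#' confidences from the spec's confidence model truncated above the 95%
#' threshold, plus sub-threshold and duplicate PSMs as nuisance rows. Decoy
#' proteins carry only sub-threshold PSMs. Signal-peptide prediction flags
#' are `TRUE` with probability 0.8 for true proteins (prediction is
#' imperfect) and `FALSE` for decoys.
#'
#' @param generated Output of [generate_precursors()].
#' @param spec The [synthetic_venom_spec()].
#' @param n_decoy_proteins Decoy proteins with only sub-threshold evidence.
#' @param confidence_threshold Percent threshold the planted confident PSMs
#'   must strictly exceed.
#' @return List with `psms` (data frame `protein_id`, `peptide`,
#'   `confidence`), `signal_flags`, and `truth` (planted `k_confident` and
#'   the analytic `accepted_truth` per protein).
#' @export
generate_psm_table <- function(generated, spec, n_decoy_proteins = 10L,
                               confidence_threshold = 95) {
  stopifnot(inherits(spec, "venom_spec"))
  set.seed(spec$seed + 2L)
  truth <- generated$truth
  psms <- list(); truth_rows <- list(); flags <- list()
  conf_confident <- function(k) {
    pmin(pmax(rnorm(k, spec$psm_confidence_mean, spec$psm_confidence_sd),
              confidence_threshold + 0.1), 100)
  }
  for (i in seq_len(nrow(truth))) {
    pid <- truth$id[i]
    frags <- unique(tryptic_digest(truth$mature_seq[i], missed_cleavages = 1L))
    frags <- frags[nchar(frags) >= 5L]
    k <- min(sample(1:5, 1L), length(frags))
    signal <- runif(1) < 0.8
    if (k > 0L) {
      chosen <- sample(frags, k)
      psms[[length(psms) + 1L]] <- data.frame(
        protein_id = pid, peptide = chosen,
        confidence = conf_confident(k), stringsAsFactors = FALSE)
      # duplicate spectrum of the first confident fragment
      psms[[length(psms) + 1L]] <- data.frame(
        protein_id = pid, peptide = chosen[1],
        confidence = conf_confident(1L), stringsAsFactors = FALSE)
    }
    # a nuisance sub-threshold fragment that must not count
    leftover <- setdiff(frags, if (k > 0L) chosen else character(0))
    if (length(leftover) > 0L) {
      psms[[length(psms) + 1L]] <- data.frame(
        protein_id = pid, peptide = leftover[1],
        confidence = runif(1, 50, confidence_threshold - 0.1),
        stringsAsFactors = FALSE)
    }
    flags[[length(flags) + 1L]] <- data.frame(
      protein_id = pid, signal_peptide_predicted = signal,
      stringsAsFactors = FALSE)
    truth_rows[[length(truth_rows) + 1L]] <- data.frame(
      protein_id = pid, k_confident = k, signal_peptide_predicted = signal,
      accepted_truth = k >= 3L || (signal && k >= 2L),
      stringsAsFactors = FALSE)
  }
  for (d in seq_len(n_decoy_proteins)) {
    pid <- sprintf("decoy%03d", d)
    psms[[length(psms) + 1L]] <- data.frame(
      protein_id = pid,
      peptide = vapply(1:3, function(j) .random_peptide(sample(6:12, 1L)),
                       character(1)),
      confidence = runif(3, 40, confidence_threshold - 0.1),
      stringsAsFactors = FALSE)
    flags[[length(flags) + 1L]] <- data.frame(
      protein_id = pid, signal_peptide_predicted = FALSE,
      stringsAsFactors = FALSE)
    truth_rows[[length(truth_rows) + 1L]] <- data.frame(
      protein_id = pid, k_confident = 0L, signal_peptide_predicted = FALSE,
      accepted_truth = FALSE, stringsAsFactors = FALSE)
  }
  list(psms = do.call(rbind, psms),
       signal_flags = do.call(rbind, flags),
       truth = do.call(rbind, truth_rows))
}

#' Generate quantal dose-response counts
#'
#' Binomial draws from a logistic curve in log10(dose) with the spec's true
#' PD50 and slope, for every time point in `pd50_truth`.
#'
#' @param spec The [synthetic_venom_spec()].
#' @return Data frame: `dose`, `n_injected`, `n_paralysed`, `timepoint`.
#' @export
generate_dose_response <- function(spec) {
  stopifnot(inherits(spec, "venom_spec"))
  set.seed(spec$seed + 3L)
  out <- lapply(names(spec$pd50_truth), function(tp) {
    pd50 <- spec$pd50_truth[[tp]]
    p <- plogis(spec$pd50_slope * (log10(spec$doses) - log10(pd50)))
    data.frame(dose = spec$doses, n_injected = spec$n_per_dose,
               n_paralysed = rbinom(length(spec$doses), spec$n_per_dose, p),
               timepoint = tp, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Generate an expression/intensity abundance table
#'
#' Bivariate log-normal precursor-count intensity and expression with the
#' spec's target Pearson correlation on the log scale. With
#' `empirical_correlation = TRUE` (spec default) the sample is rotated so its
#' empirical log-scale correlation equals the target exactly; otherwise the
#' target is the population correlation and the sample value fluctuates
#' around it.
#'
#' @param spec The [synthetic_venom_spec()].
#' @param n Number of records (default `spec$n_expression_records`).
#' @return Data frame: `entity_id`, `family_label`,
#'   `precursor_count_intensity`, `expression`.
#' @export
generate_expression <- function(spec, n = spec$n_expression_records) {
  stopifnot(inherits(spec, "venom_spec"), n >= 3L)
  set.seed(spec$seed + 4L)
  r <- spec$expression_correlation_target
  sigma <- matrix(c(1, r, r, 1), 2L)
  z <- MASS::mvrnorm(n, mu = c(log(1e5), log(1e3)), Sigma = sigma,
                     empirical = spec$empirical_correlation)
  fams <- spec$family_profiles$family
  data.frame(
    entity_id = sprintf("ent%03d", seq_len(n)),
    family_label = sample(fams, n, replace = TRUE,
                          prob = spec$family_profiles$share),
    precursor_count_intensity = exp(z[, 1]),
    expression = exp(z[, 2]),
    stringsAsFactors = FALSE)
}

#' Abundance records realising the planted family composition exactly
#'
#' One record per precursor, with each family's share of both intensity and
#' expression split equally among its members, so
#' [composition_fractions()] recovers the spec's composition shares exactly.
#'
#' @param spec The [synthetic_venom_spec()].
#' @return Data frame usable by [composition_fractions()].
#' @export
planted_family_abundances <- function(spec) {
  stopifnot(inherits(spec, "venom_spec"))
  fp <- spec$family_profiles[spec$family_profiles$n_members > 0L, ,
                             drop = FALSE]
  per <- fp$share / fp$n_members
  data.frame(
    entity_id = sprintf("ent%03d", seq_len(sum(fp$n_members))),
    family_label = rep(fp$family, fp$n_members),
    precursor_count_intensity = rep(per, fp$n_members),
    expression = rep(per, fp$n_members),
    stringsAsFactors = FALSE)
}
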