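# Candidate mature peptides from annotated precursors, and their
# reconciliation with deconvoluted intact-mass peaks.
#
# Coordinates are 0-based half-open on the precursor translation throughout:
# signal_end is the index of the first mature residue, and a candidate
# (start, end) denotes sequence[start:end) in 0-based terms.

#' Validate a precursor table
#'
#' Checks the columns and invariants of a precursor data frame: `id`,
#' `sequence` (canonical residues), `signal_end` (0-based index of the first
#' mature residue, strictly inside the sequence), `family`, and `expression`
#' (non-negative, FPKM-like).
#'
#' @param precursors Data frame of precursor records.
#' @return The validated data frame, invisibly usable downstream.
#' @export
validate_precursors <- function(precursors) {
  req <- c("id", "sequence", "signal_end", "family", "expression")
  missing_cols <- setdiff(req, names(precursors))
  if (length(missing_cols) > 0L) {
    stop("precursor table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(precursors$id)) stop("duplicate precursor ids")
  for (i in seq_len(nrow(precursors))) {
    .residue_vector(precursors$sequence[i])
    se <- precursors$signal_end[i]
    if (is.na(se) || se < 0 || se >= nchar(precursors$sequence[i])) {
      stop(sprintf("record %d (%s): signal_end %s outside [0, length)",
                   i, precursors$id[i], as.character(se)))
    }
    if (is.na(precursors$expression[i]) || precursors$expression[i] < 0) {
      stop(sprintf("record %d (%s): negative or missing expression",
                   i, precursors$id[i]))
    }
  }
  precursors
}

# 0-based half-open substring helper.
.slice <- function(sequence, start, end) substr(sequence, start + 1L, end)

.candidate_row <- function(precursor_id, sequence, start, end, pyroglu,
                           provenance, constants) {
  subseq <- .slice(sequence, start, end)
  n_cys <- count_cys(subseq)
  n_ss <- n_cys %/% 2L
  data.frame(
    precursor_id = precursor_id, start = start, end = end,
    sequence = subseq, n_cys = n_cys, n_disulfides = n_ss,
    pyroglu = pyroglu,
    predicted_native = peptide_mass(
      subseq, modifications(n_disulfides = n_ss, pyroglu = pyroglu),
      constants = constants),
    predicted_ra = ra_mass(subseq, pyroglu = pyroglu, constants = constants),
    provenance = provenance,
    stringsAsFactors = FALSE
  )
}

#' Enumerate candidate mature peptides from one precursor
#'
#' Starting from the signal-cleaved mature region, generates the plausible
#' processed forms of a venom precursor: the full mature sequence, its
#' N-terminal truncations up to `max_n_trim` residues (capturing the
#' N-terminal heterogeneity seen between co-occurring subtypes), C-terminal
#' truncations up to `max_c_trim`, each annotated domain as an excised
#' peptide (multidomain precursors are processed into single-domain venom
#' peptides), and a pyroglutamate variant of every candidate that starts with
#' glutamine. Native predicted masses assume full oxidation
#' (`floor(n_cys / 2)` disulfides); reduced/alkylated masses carry one
#' hydroxyethyl adduct per cysteine.
#'
#' @param precursor One-row data frame (or list) with `id`, `sequence`,
#'   `signal_end`; see [validate_precursors()].
#' @param domains Optional data frame of 0-based half-open `(start, end)`
#'   intervals on the precursor (columns `start`, `end`), each within the
#'   mature region.
#' @param max_n_trim,max_c_trim Maximum residues trimmed from the N- and
#'   C-terminus of the full mature form.
#' @param allow_pyroglu Add a pyroGlu variant for candidates starting with Q.
#' @param use_domains Emit one candidate per annotated domain.
#' @param constants Mass constants, from [mass_constants()].
#' @return Data frame of candidates with 0-based half-open coordinates,
#'   cysteine/disulfide counts, `predicted_native` and `predicted_ra` masses
#'   (Da), and a `provenance` label (`signal_cleaved`, `n_trimmed`,
#'   `c_trimmed`, `domain_excised`, `pyroglu_variant`). Duplicate
#'   (interval, modification) combinations are removed.
#' @examples
#' p <- data.frame(id = "pre1", sequence = "MKLLVALFAKNDRECKKIAEVCYRHEECCSFQCPSYWGKCVS",
#'                 signal_end = 9, family = "fam1", expression = 100)
#' enumerate_candidates(p, max_n_trim = 2, max_c_trim = 0)
#' @export
enumerate_candidates <- function(precursor, domains = NULL,
                                 max_n_trim = 4L, max_c_trim = 2L,
                                 allow_pyroglu = TRUE, use_domains = TRUE,
                                 constants = mass_constants()) {
  stopifnot(max_n_trim >= 0, max_c_trim >= 0)
  precursor <- as.list(precursor[c("id", "sequence", "signal_end")])
  if (is.null(precursor$signal_end) || is.na(precursor$signal_end)) {
    stop("precursor ", precursor$id,
         " has no signal_end annotation; cannot define the mature region")
  }
  seqc <- toupper(precursor$sequence)
  len <- nchar(seqc)
  se <- as.integer(precursor$signal_end)
  if (se < 0 || se >= len) stop("signal_end outside precursor for ", precursor$id)

  rows <- list()
  add <- function(start, end, provenance) {
    if (end - start >= 1L) {
      rows[[length(rows) + 1L]] <<- .candidate_row(
        precursor$id, seqc, start, end, FALSE, provenance, constants)
    }
  }
  add(se, len, "signal_cleaved")
  for (k in seq_len(max_n_trim)) add(se + k, len, "n_trimmed")
  for (k in seq_len(max_c_trim)) add(se, len - k, "c_trimmed")
  if (use_domains && !is.null(domains) && nrow(domains) > 0L) {
    for (i in seq_len(nrow(domains))) {
      ds <- as.integer(domains$start[i]); de <- as.integer(domains$end[i])
      if (ds < se || de > len || ds >= de) {
        stop(sprintf("domain [%d, %d) of %s outside mature region [%d, %d)",
                     ds, de, precursor$id, se, len))
      }
      add(ds, de, "domain_excised")
    }
  }
  out <- do.call(rbind, rows)
  if (allow_pyroglu) {
    qstart <- out[substr(out$sequence, 1, 1) == "Q", , drop = FALSE]
    if (nrow(qstart) > 0L) {
      pyro <- do.call(rbind, lapply(seq_len(nrow(qstart)), function(i) {
        .candidate_row(precursor$id, seqc, qstart$start[i], qstart$end[i],
                       TRUE, "pyroglu_variant", constants)
      }))
      out <- rbind(out, pyro)
    }
  }
  out[!duplicated(out[, c("start", "end", "pyroglu")]), , drop = FALSE]
}

#' Enumerate candidates for a whole precursor table
#'
#' @param precursors Precursor data frame (see [validate_precursors()]).
#' @param domains Optional data frame with columns `id`, `start`, `end`
#'   giving domain intervals per precursor.
#' @inheritParams enumerate_candidates
#' @return Row-bound candidate data frame over all precursors.
#' @export
enumerate_all_candidates <- function(precursors, domains = NULL,
                                     max_n_trim = 4L, max_c_trim = 2L,
                                     allow_pyroglu = TRUE, use_domains = TRUE,
                                     constants = mass_constants()) {
  precursors <- validate_precursors(precursors)
  out <- lapply(seq_len(nrow(precursors)), function(i) {
    dom <- NULL
    if (!is.null(domains)) {
      dom <- domains[domains$id == precursors$id[i], , drop = FALSE]
    }
    enumerate_candidates(precursors[i, ], dom, max_n_trim, max_c_trim,
                         allow_pyroglu, use_domains, constants)
  })
  do.call(rbind, out)
}

#' Reconcile candidate mature peptides with observed mass peaks
#'
#' Assigns deconvoluted neutral monoisotopic peaks to candidate mature forms.
#' Peaks are visited in order of descending intensity (ties by ascending
#' mass, mirroring abundance-rank usage); each peak takes the still-unmatched
#' candidate whose predicted mass for the peak's condition (`predicted_native`
#' for native peaks, `predicted_ra` for reduced/alkylated ones) is within
#' `tolerance`, preferring the smallest absolute mass error, then the
#' candidate with fewer modifications, then the longer candidate. The result
#' is a partial injection: no peak or candidate is used twice.
#'
#' @param candidates Candidate data frame from [enumerate_candidates()].
#' @param peaks Data frame with columns `mass` (Da), `intensity` (> 0) and
#'   `condition` (`"native"` or `"reduced_alkylated"`).
#' @param tolerance Maximum |observed - predicted| in Da. The default 0.15 Da
#'   accommodates the spread seen between deconvoluted intact masses and
#'   sequence-derived predictions.
#' @return Data frame of matches: candidate columns plus `peak_mass`,
#'   `peak_intensity`, `condition` and `delta` (observed - predicted, Da).
#'   Empty inputs give a zero-row frame.
#' @export
match_candidates <- function(candidates, peaks, tolerance = 0.15) {
  stopifnot(tolerance > 0)
  if (is.null(candidates)) candidates <- data.frame()
  if (is.null(peaks)) peaks <- data.frame()
  empty <- cbind(
    candidates[0, , drop = FALSE],
    data.frame(peak_mass = numeric(0), peak_intensity = numeric(0),
               condition = character(0), delta = numeric(0),
               stringsAsFactors = FALSE))
  if (nrow(candidates) == 0L || nrow(peaks) == 0L) return(empty)
  if (!all(peaks$condition %in% c("native", "reduced_alkylated"))) {
    stop("peak condition must be 'native' or 'reduced_alkylated'")
  }
  # deterministic candidate order so ties do not depend on input order
  cand <- candidates[order(candidates$precursor_id, candidates$start,
                           candidates$end, candidates$pyroglu), , drop = FALSE]
  peaks <- peaks[order(-peaks$intensity, peaks$mass), , drop = FALSE]
  n_mods <- cand$n_disulfides + as.integer(cand$pyroglu)
  cand_len <- nchar(cand$sequence)
  taken <- rep(FALSE, nrow(cand))
  matches <- vector("list", nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    predicted <- if (peaks$condition[i] == "native") cand$predicted_native else cand$predicted_ra
    nm <- if (peaks$condition[i] == "native") n_mods else cand$n_cys + as.integer(cand$pyroglu)
    delta <- peaks$mass[i] - predicted
    ok <- which(!taken & abs(delta) <= tolerance)
    if (length(ok) == 0L) next
    ord <- ok[order(abs(delta[ok]), nm[ok], -cand_len[ok])]
    j <- ord[1]
    taken[j] <- TRUE
    matches[[i]] <- cbind(
      cand[j, , drop = FALSE],
      data.frame(peak_mass = peaks$mass[i], peak_intensity = peaks$intensity[i],
                 condition = peaks$condition[i], delta = delta[j],
                 stringsAsFactors = FALSE))
  }
  matches <- matches[!vapply(matches, is.null, logical(1))]
  if (length(matches) == 0L) return(empty)
  out <- do.call(rbind, matches)
  rownames(out) <- NULL
  out
}
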