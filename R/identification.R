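# Protein identification filtering on PSM tables. The acceptance rule is
# signal-peptide-conditional: three distinct confident tryptic fragments for
# a protein without a predicted secretion signal, two when a signal peptide
# was predicted (secreted proteins are expected in venom, so weaker proteomic
# evidence suffices).

#' In-silico tryptic digestion
#'
#' Cleaves C-terminal to lysine or arginine except when the next residue is
#' proline, and returns all fragments containing up to `missed_cleavages`
#' internal uncleaved sites (i.e. every run of 1 to `missed_cleavages + 1`
#' consecutive fully-cleaved fragments). At 0 missed cleavages the fragments
#' partition the input.
#'
#' @param sequence Amino-acid string.
#' @param missed_cleavages Maximum internal missed cleavage sites (>= 0).
#' @return Character vector of fragments, N- to C-terminal order, shorter
#'   windows first.
#' @examples
#' tryptic_digest("AKRPGK")       # no cleavage before proline
#' tryptic_digest("AKRPGK", 1)
#' @export
tryptic_digest <- function(sequence, missed_cleavages = 0L) {
  stopifnot(missed_cleavages >= 0,
            missed_cleavages == as.integer(missed_cleavages))
  res <- .residue_vector(sequence)
  n <- length(res)
  cut_after <- which(res %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & res[pmin(cut_after + 1L, n)] != "P"]
  bounds <- c(0L, cut_after, n)
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1]
  base <- vapply(seq_along(starts), function(i) {
    paste(res[starts[i]:ends[i]], collapse = "")
  }, character(1))
  out <- character(0)
  for (mc in 0:min(missed_cleavages, length(base) - 1L)) {
    for (i in seq_len(length(base) - mc)) {
      out <- c(out, paste(base[i:(i + mc)], collapse = ""))
    }
  }
  out
}

#' Identification decision for one protein
#'
#' Counts the distinct peptide sequences among a protein's PSMs with
#' confidence strictly above `confidence_threshold`, and accepts the protein
#' when that count reaches 3, or 2 if a secretion signal peptide was
#' predicted for it.
#'
#' @param psms Data frame of PSMs for a single protein, columns `protein_id`,
#'   `peptide`, `confidence` (percent, 0-100).
#' @param signal_peptide_predicted Logical flag for the protein.
#' @param confidence_threshold Percent; PSMs must exceed it strictly.
#' @return One-row data frame: `protein_id`,
#'   `n_confident_distinct_fragments`, `signal_peptide_predicted`,
#'   `accepted`.
#' @examples
#' psms <- data.frame(protein_id = "p1",
#'                    peptide = c("AAK", "CCR", "DDK"),
#'                    confidence = c(96, 97, 99))
#' accept_identification(psms, signal_peptide_predicted = FALSE)
#' @export
accept_identification <- function(psms, signal_peptide_predicted,
                                  confidence_threshold = 95) {
  stopifnot(is.logical(signal_peptide_predicted),
            length(signal_peptide_predicted) == 1L,
            !is.na(signal_peptide_predicted),
            confidence_threshold > 0, confidence_threshold < 100)
  ids <- unique(psms$protein_id)
  if (length(ids) > 1L) {
    stop("PSM table mixes protein ids: ", paste(ids, collapse = ", "))
  }
  if (nrow(psms) > 0L) {
    stopifnot(all(nchar(psms$peptide) > 0L),
              all(psms$confidence >= 0 & psms$confidence <= 100))
  }
  n_conf <- length(unique(psms$peptide[psms$confidence > confidence_threshold]))
  required <- if (signal_peptide_predicted) 2L else 3L
  data.frame(
    protein_id = if (length(ids) == 1L) ids else NA_character_,
    n_confident_distinct_fragments = n_conf,
    signal_peptide_predicted = signal_peptide_predicted,
    accepted = n_conf >= required,
    stringsAsFactors = FALSE
  )
}

#' Filter a full PSM table into identification decisions
#'
#' Applies [accept_identification()] to every protein in a PSM table.
#' Proteins listed in `signal_flags` but absent from the PSM table are
#' reported with zero fragments (rejected).
#'
#' @param psm_table Data frame with columns `protein_id`, `peptide`,
#'   `confidence`.
#' @param signal_flags Data frame with columns `protein_id` and
#'   `signal_peptide_predicted`.
#' @param confidence_threshold Percent; strict threshold.
#' @return Data frame of decisions, one row per protein in `signal_flags`,
#'   ordered as given there.
#' @export
filter_identifications <- function(psm_table, signal_flags,
                                   confidence_threshold = 95) {
  stopifnot(all(c("protein_id", "signal_peptide_predicted") %in%
                  names(signal_flags)))
  if (anyDuplicated(signal_flags$protein_id)) {
    stop("duplicate protein ids in signal_flags")
  }
  orphan <- setdiff(unique(psm_table$protein_id), signal_flags$protein_id)
  if (length(orphan) > 0L) {
    stop("PSM table has protein id(s) without a signal-peptide flag: ",
         paste(head(orphan, 5), collapse = ", "))
  }
  out <- lapply(seq_len(nrow(signal_flags)), function(i) {
    pid <- signal_flags$protein_id[i]
    sub <- psm_table[psm_table$protein_id == pid, , drop = FALSE]
    dec <- accept_identification(sub, signal_flags$signal_peptide_predicted[i],
                                 confidence_threshold)
    dec$protein_id <- pid
    dec
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
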