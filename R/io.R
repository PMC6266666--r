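# Readers and writers for the pipeline's plain-text formats. Precursor FASTA
# headers follow the dialect "id|family|signal_end|expression"; every table
# is tab-separated with a header row, UTF-8, "." decimal, masses printed to
# 4 decimals.

#' Read precursors from FASTA
#'
#' Parses a FASTA file whose headers follow `id|family|signal_end|expression`
#' (signal_end 0-based, expression FPKM-like). Sequences are upper-cased and
#' validated against the canonical amino-acid alphabet.
#'
#' @param path Path to the FASTA file.
#' @return Validated precursor data frame (see [validate_precursors()]).
#' @export
read_precursor_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  # BStringSet keeps invalid characters so they can be rejected explicitly
  aa <- Biostrings::readBStringSet(path)
  if (length(aa) == 0L) stop("no records in ", path)
  parts <- strsplit(names(aa), "|", fixed = TRUE)
  for (i in seq_along(parts)) {
    if (length(parts[[i]]) != 4L) {
      stop(sprintf(
        "record %d: header '%s' does not follow id|family|signal_end|expression",
        i, names(aa)[i]))
    }
    if (is.na(suppressWarnings(as.numeric(parts[[i]][3])))) {
      stop(sprintf("record %d: signal_end '%s' is not a number", i,
                   parts[[i]][3]))
    }
    if (is.na(suppressWarnings(as.numeric(parts[[i]][4])))) {
      stop(sprintf("record %d: expression '%s' is not a number", i,
                   parts[[i]][4]))
    }
  }
  out <- data.frame(
    id = vapply(parts, `[`, character(1), 1L),
    sequence = toupper(as.character(aa)),
    signal_end = as.integer(vapply(parts, `[`, character(1), 3L)),
    family = vapply(parts, `[`, character(1), 2L),
    expression = as.numeric(vapply(parts, `[`, character(1), 4L)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  validate_precursors(out)
}

#' Write precursors to FASTA
#'
#' Inverse of [read_precursor_fasta()]; sequences are written unwrapped so
#' that write-read-write round-trips are byte-identical.
#'
#' @param precursors Precursor data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_precursor_fasta <- function(precursors, path) {
  precursors <- validate_precursors(precursors)
  header <- sprintf(">%s|%s|%d|%s", precursors$id, precursors$family,
                    as.integer(precursors$signal_end),
                    format(precursors$expression, trim = TRUE,
                           scientific = FALSE))
  lines <- as.vector(rbind(header, toupper(precursors$sequence)))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

.read_tsv <- function(path, required) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   check.names = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop(path, " lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  df
}

#' Write a table as TSV
#'
#' Tab-separated, header row, no quoting or row names; numeric mass-like
#' columns are pre-rounded to 4 decimals by the specialised writers.
#'
#' @param df Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_file <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a deconvoluted peak list
#'
#' @param path TSV with columns `mass`, `intensity`, `condition`.
#' @return Peak data frame; masses and intensities numeric, intensities > 0.
#' @export
read_peaks_tsv <- function(path) {
  df <- .read_tsv(path, c("mass", "intensity", "condition"))
  df$mass <- as.numeric(df$mass)
  df$intensity <- as.numeric(df$intensity)
  if (any(is.na(df$mass)) || any(df$mass <= 0)) {
    stop(path, ": masses must be positive numbers")
  }
  if (any(is.na(df$intensity)) || any(df$intensity <= 0)) {
    stop(path, ": intensities must be positive numbers")
  }
  bad <- !(df$condition %in% c("native", "reduced_alkylated"))
  if (any(bad)) {
    stop(sprintf("%s line %d: condition '%s' not 'native'/'reduced_alkylated'",
                 path, which(bad)[1] + 1L, df$condition[which(bad)[1]]))
  }
  df
}

#' Write a peak list
#' @param peaks Peak data frame (`mass`, `intensity`, `condition`).
#' @param path Output path.
#' @export
write_peaks_tsv <- function(peaks, path) {
  peaks$mass <- round(peaks$mass, 4)
  write_tsv_file(peaks[, c("mass", "intensity", "condition")], path)
}

#' Read a PSM table
#' @param path TSV with columns `protein_id`, `peptide`, `confidence`.
#' @return PSM data frame; confidences numeric in \[0, 100\].
#' @export
read_psm_tsv <- function(path) {
  df <- .read_tsv(path, c("protein_id", "peptide", "confidence"))
  df$confidence <- as.numeric(df$confidence)
  if (any(is.na(df$confidence)) || any(df$confidence < 0) ||
      any(df$confidence > 100)) {
    stop(path, ": confidences must be numbers in [0, 100]")
  }
  df
}

#' Read domain intervals
#' @param path TSV with columns `id`, `start`, `end` (0-based half-open on
#'   the precursor).
#' @return Data frame of domain intervals.
#' @export
read_domains_tsv <- function(path) {
  df <- .read_tsv(path, c("id", "start", "end"))
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  if (any(is.na(df$start)) || any(is.na(df$end)) || any(df$start >= df$end)) {
    stop(path, ": domain intervals must satisfy start < end")
  }
  df
}

#' Read dose-response observations
#' @param path TSV with columns `dose`, `n_injected`, `n_paralysed`,
#'   `timepoint`.
#' @return Data frame of observations.
#' @export
read_dose_response_tsv <- function(path) {
  df <- .read_tsv(path, c("dose", "n_injected", "n_paralysed", "timepoint"))
  df$dose <- as.numeric(df$dose)
  df$n_injected <- as.integer(df$n_injected)
  df$n_paralysed <- as.integer(df$n_paralysed)
  if (any(df$n_paralysed > df$n_injected) || any(df$n_paralysed < 0)) {
    stop(path, ": need 0 <= n_paralysed <= n_injected")
  }
  df
}

#' Read per-protein signal-peptide prediction flags
#' @param path TSV with columns `protein_id`, `signal_peptide_predicted`.
#' @return Data frame of flags (logical `signal_peptide_predicted`).
#' @export
read_signal_flags_tsv <- function(path) {
  df <- .read_tsv(path, c("protein_id", "signal_peptide_predicted"))
  df$signal_peptide_predicted <- as.logical(df$signal_peptide_predicted)
  if (any(is.na(df$signal_peptide_predicted))) {
    stop(path, ": signal_peptide_predicted must be TRUE/FALSE")
  }
  df
}

#' Read an abundance table
#' @param path TSV with columns `entity_id`, `family_label`,
#'   `precursor_count_intensity`, `expression`.
#' @return Data frame of abundance records.
#' @export
read_abundance_tsv <- function(path) {
  df <- .read_tsv(path, c("entity_id", "family_label",
                          "precursor_count_intensity", "expression"))
  df$precursor_count_intensity <- as.numeric(df$precursor_count_intensity)
  df$expression <- as.numeric(df$expression)
  if (any(df$precursor_count_intensity < 0) || any(df$expression < 0)) {
    stop(path, ": abundances must be non-negative")
  }
  df
}

#' Write all synthetic fixtures for a spec
#'
#' Runs every generator of a [synthetic_venom_spec()] and writes the full
#' fixture set (precursor FASTA, native/RA peak lists, PSM table and signal
#' flags, dose-response counts, abundance table, truth tables, and a JSON
#' echo of the spec) into a directory.
#'
#' @param spec The [synthetic_venom_spec()].
#' @param outdir Output directory (created if missing).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_synthetic_fixtures <- function(spec, outdir) {
  stopifnot(inherits(spec, "venom_spec"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  gen <- generate_precursors(spec)
  masses <- generate_mass_lists(gen, spec)
  psm <- generate_psm_table(gen, spec)
  dr <- generate_dose_response(spec)
  abund <- generate_expression(spec)
  p <- function(f) file.path(outdir, f)
  write_precursor_fasta(gen$precursors, p("precursors.fasta"))
  write_tsv_file(gen$truth, p("precursor_truth.tsv"))
  write_peaks_tsv(masses$native, p("peaks_native.tsv"))
  write_peaks_tsv(masses$ra, p("peaks_ra.tsv"))
  write_tsv_file(masses$truth, p("mass_truth.tsv"))
  write_tsv_file(psm$psms, p("psms.tsv"))
  write_tsv_file(psm$signal_flags, p("signal_flags.tsv"))
  write_tsv_file(psm$truth, p("psm_truth.tsv"))
  write_tsv_file(dr, p("dose_response.tsv"))
  write_tsv_file(abund, p("abundance.tsv"))
  spec_echo <- spec
  class(spec_echo) <- NULL
  jsonlite::write_json(spec_echo, p("spec.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files <- c(precursors = p("precursors.fasta"),
             precursor_truth = p("precursor_truth.tsv"),
             peaks_native = p("peaks_native.tsv"),
             peaks_ra = p("peaks_ra.tsv"),
             mass_truth = p("mass_truth.tsv"),
             psms = p("psms.tsv"), signal_flags = p("signal_flags.tsv"),
             psm_truth = p("psm_truth.tsv"),
             dose_response = p("dose_response.tsv"),
             abundance = p("abundance.tsv"), spec = p("spec.json"))
  invisible(files)
}

#' Table of mature venom peptides with printed reference masses
#'
#' The packaged reference table of mature disulfide-rich peptides detected in
#' assassin-fly venom: sequence, cysteine count, pyroglutamate flag, and the
#' published predicted and measured monoisotopic masses for the native and
#' reduced/alkylated conditions. Used by the worked examples and the
#' reproduction script.
#'
#' @param path Optional alternative TSV path.
#' @return Data frame, one row per mature peptide.
#' @export
reference_peptide_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "dg_mature_peptides.tsv",
                        package = "venomics")
  }
  df <- .read_tsv(path, c("peptide", "sequence", "n_cys", "pyroglu",
                          "predicted_native", "measured_native",
                          "predicted_ra", "measured_ra",
                          "exclude_from_reproduction"))
  df$pyroglu <- as.logical(df$pyroglu)
  df$exclude_from_reproduction <- as.logical(df$exclude_from_reproduction)
  df
}
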