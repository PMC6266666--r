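# Rational toxin nomenclature: activity prefix + family label + species
# acronym + ordinal + subtype letter, e.g. "U-Asilidin_12_-Dg3a". Precursors
# whose full sequences exceed 90% identity are subtypes: they share one
# ordinal and are distinguished by a trailing lowercase letter in discovery
# order.

#' Global percent identity between two sequences
#'
#' Needleman-Wunsch global alignment maximising the number of identical
#' aligned positions (match 1, mismatch 0, with a vanishing gap-extension
#' penalty so that among maximum-match alignments the one with fewest gap
#' columns is chosen). Identity is matches divided by alignment length
#' (including gap columns), times 100. Symmetric, and 100 for identical
#' sequences.
#'
#' @param a,b Non-empty amino-acid strings.
#' @return Percent identity in \[0, 100\].
#' @examples
#' percent_identity("AAAA", "AAAT")  # 75
#' @export
percent_identity <- function(a, b) {
  stopifnot(nchar(a) > 0L, nchar(b) > 0L)
  a <- toupper(a); b <- toupper(b)
  alphabet <- unique(c(strsplit(a, "")[[1]], strsplit(b, "")[[1]]))
  submat <- matrix(0, length(alphabet), length(alphabet),
                   dimnames = list(alphabet, alphabet))
  diag(submat) <- 1
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = "global", substitutionMatrix = submat,
    gapOpening = 0, gapExtension = 1e-3)
  matches <- Biostrings::nmatch(aln)
  pairs <- matches + Biostrings::nmismatch(aln)
  # alignment length = aligned pairs + gap columns = n + m - pairs
  aln_len <- nchar(a) + nchar(b) - pairs
  100 * matches / aln_len
}

#' Pairwise identity matrix
#'
#' @param sequences Character vector of sequences.
#' @return Symmetric matrix of [percent_identity()] values (diagonal 100).
#' @export
identity_matrix <- function(sequences) {
  n <- length(sequences)
  m <- diag(100, n)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        m[i, j] <- m[j, i] <- percent_identity(sequences[i], sequences[j])
      }
    }
  }
  m
}

# Single-linkage clusters from a similarity matrix at a strict threshold:
# connected components of the graph with edges sim > threshold.
.single_linkage <- function(sim, threshold) {
  n <- nrow(sim)
  comp <- seq_len(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && sim[i, j] > threshold) {
        old <- comp[j]; new <- comp[i]
        if (old != new) comp[comp == old] <- new
      }
    }
  }
  match(comp, unique(comp))
}

#' Render one toxin name
#'
#' @param activity_prefix Activity prefix, e.g. `"U-"` for unknown function.
#' @param family_label Family label of the form `"Asilidin-12"`; rendered
#'   with the number set off by underscores (`"Asilidin_12_"`).
#' @param species_acronym Species acronym, e.g. `"Dg"`.
#' @param ordinal Positive integer, unique per species.
#' @param subtype_letter Lowercase letter, or `""` for singleton clusters.
#' @return The rendered name, e.g. `"U-Asilidin_12_-Dg3a"`.
#' @export
render_toxin_name <- function(activity_prefix, family_label, species_acronym,
                              ordinal, subtype_letter = "") {
  stopifnot(ordinal >= 1, ordinal == as.integer(ordinal))
  fam <- sub("^(.*)-([0-9]+)$", "\\1_\\2_", family_label)
  paste0(activity_prefix, fam, "-", species_acronym, ordinal, subtype_letter)
}

#' Assign rational toxin names to a precursor repertoire
#'
#' Clusters full precursor sequences by single linkage at a strict identity
#' threshold (default > 90%), then names each precursor as
#' prefix + family + species acronym + ordinal + subtype letter. Clusters are
#' ordered by the discovery order of their first member and numbered 1, 2,
#' ...; members of a multi-sequence cluster receive letters a, b, c ... in
#' discovery order, while singleton clusters are letterless unless
#' `letter_singletons` is set.
#'
#' @param precursors Data frame with columns `id`, `sequence`,
#'   `family` (e.g. `"Asilidin-12"`), `discovery_order` (distinct), and
#'   optionally `activity_prefix` (default `"U-"`).
#' @param species_acronym Species acronym used in every name.
#' @param identity_threshold Subtype threshold in percent (strict `>`).
#' @param letter_singletons Give singleton clusters the letter `"a"`.
#' @return Data frame: `id`, `name`, `activity_prefix`, `family`,
#'   `species_acronym`, `ordinal`, `subtype_letter`, `cluster`.
#' @examples
#' pre <- data.frame(
#'   id = c("c1", "c2", "c3"),
#'   sequence = c("MKLAILTCDLIGNERLCVLHCLAKGFRGGWCDGRKVCNCRR",
#'                "MKWFVLSQEQRQCKKIGEHCY",
#'                "MKLAILTCDLIGNERLCVVHCLAKGFRGGWCDSRKVCNCRR"),
#'   family = c("Asilidin-12", "Asilidin-1", "Asilidin-12"),
#'   discovery_order = 1:3)
#' assign_names(pre)
#' @export
assign_names <- function(precursors, species_acronym = "Dg",
                         identity_threshold = 90, letter_singletons = FALSE) {
  req <- c("id", "sequence", "family", "discovery_order")
  stopifnot(all(req %in% names(precursors)))
  if (anyDuplicated(precursors$discovery_order)) {
    stop("discovery_order must be a total order (no ties)")
  }
  prefix <- if ("activity_prefix" %in% names(precursors)) {
    precursors$activity_prefix
  } else rep("U-", nrow(precursors))
  ord <- order(precursors$discovery_order)
  p <- precursors[ord, , drop = FALSE]
  prefix <- prefix[ord]
  cl <- .single_linkage(identity_matrix(p$sequence), identity_threshold)
  # clusters already appear in discovery order of their first member because
  # rows are sorted by discovery order and .single_linkage labels by first
  # occurrence
  sizes <- table(cl)
  letter_pos <- stats::ave(seq_along(cl), cl, FUN = seq_along)
  letter <- ifelse(sizes[as.character(cl)] > 1L | letter_singletons,
                   letters[letter_pos], "")
  name <- vapply(seq_len(nrow(p)), function(i) {
    render_toxin_name(prefix[i], p$family[i], species_acronym, cl[i],
                      letter[i])
  }, character(1))
  out <- data.frame(
    id = p$id, name = name, activity_prefix = prefix, family = p$family,
    species_acronym = species_acronym, ordinal = cl,
    subtype_letter = letter, cluster = cl, stringsAsFactors = FALSE)
  out[order(p$discovery_order), , drop = FALSE]
}
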