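# Cysteine counting by pairing native against reduced/alkylated intact-mass
# lists: the most abundant masses in a window are compared between the two
# conditions and each native peak is assigned the cysteine count whose
# expected reduction/alkylation shift best explains an RA partner.

#' Select the most abundant peaks in a mass window
#'
#' Restricts a deconvoluted peak list to a mass range and keeps the `top_n`
#' most intense peaks, sorted by descending intensity with ties broken by
#' ascending mass. The defaults (top 50 peaks between 1 and 10 kDa) target
#' the peptide-rich region of a venom mass profile.
#'
#' @param peaks Data frame with columns `mass` and `intensity`.
#' @param top_n Number of peaks to keep (>= 1).
#' @param mass_range Length-2 numeric, inclusive window in Da.
#' @return The filtered, sorted peak data frame (fewer than `top_n` rows when
#'   the window holds fewer peaks).
#' @export
select_top_peaks <- function(peaks, top_n = 50L, mass_range = c(1000, 10000)) {
  stopifnot(top_n >= 1L, length(mass_range) == 2L,
            mass_range[1] < mass_range[2])
  inr <- peaks[peaks$mass >= mass_range[1] & peaks$mass <= mass_range[2], ,
               drop = FALSE]
  inr <- inr[order(-inr$intensity, inr$mass), , drop = FALSE]
  out <- head(inr, top_n)
  rownames(out) <- NULL
  out
}

#' Pair native and reduced/alkylated peaks into cysteine assignments
#'
#' Walks the native peaks in order of intensity rank and, for each, finds the
#' reduced/alkylated peak whose mass shift `ra - native` matches
#' `n * delta_ra_per_cys` for some allowed cysteine count `n` within
#' `tolerance` ([shift_to_ncys()]); among fitting RA peaks the one with the
#' smallest residual wins, ties broken by ascending RA mass. Each RA peak
#' satisfies at most one native peak (a single molecular species yields one
#' shifted product). A count of 0 denotes a cysteine-free peptide whose mass
#' is unchanged between the two lists.
#'
#' @param native,ra Peak data frames (columns `mass`, `intensity`), typically
#'   pre-filtered with [select_top_peaks()].
#' @param allowed Candidate cysteine counts.
#' @param tolerance Maximum residual in Da between the observed shift and the
#'   nearest allowed shift.
#' @param constants Mass constants, from [mass_constants()].
#' @return A list with `assignments` (data frame: `native_mass`, `ra_mass`,
#'   `delta`, `n_cys`, `residual`, `native_rank`, `ra_rank`; rank 1 = most
#'   intense), `unmatched_native` and `unmatched_ra` (peak data frames).
#' @export
pair_conditions <- function(native, ra, allowed = c(0L, 4L, 6L, 8L),
                            tolerance = 0.1, constants = mass_constants()) {
  stopifnot(tolerance > 0)
  nat <- native[order(-native$intensity, native$mass), , drop = FALSE]
  ral <- ra[order(-ra$intensity, ra$mass), , drop = FALSE]
  n_nat <- nrow(nat); n_ra <- nrow(ral)
  taken <- rep(FALSE, n_ra)
  rows <- list()
  for (i in seq_len(n_nat)) {
    if (n_ra == 0L) break
    delta <- ral$mass - nat$mass[i]
    fit <- vapply(delta, shift_to_ncys, integer(1), tolerance = tolerance,
                  allowed = allowed, constants = constants)
    residual <- abs(delta - fit * constants$delta_ra_per_cys)
    ok <- which(!taken & !is.na(fit))
    if (length(ok) == 0L) next
    j <- ok[order(residual[ok], ral$mass[ok])][1]
    taken[j] <- TRUE
    rows[[length(rows) + 1L]] <- data.frame(
      native_mass = nat$mass[i], ra_mass = ral$mass[j],
      delta = delta[j], n_cys = fit[j], residual = residual[j],
      native_rank = i, ra_rank = j)
  }
  assignments <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(native_mass = numeric(0), ra_mass = numeric(0),
               delta = numeric(0), n_cys = integer(0), residual = numeric(0),
               native_rank = integer(0), ra_rank = integer(0))
  matched_nat <- assignments$native_rank
  list(
    assignments = assignments,
    unmatched_native = nat[setdiff(seq_len(n_nat), matched_nat), , drop = FALSE],
    unmatched_ra = ral[!taken, , drop = FALSE]
  )
}

#' Count cysteines per venom peptide from two-condition mass lists
#'
#' Convenience wrapper over [select_top_peaks()] and [pair_conditions()]:
#' takes the `top_n` most abundant peaks of each condition within
#' `mass_range` and pairs them. With `ra_from_top = FALSE` the full RA list
#' is searched for shifted partners of the native top peaks instead of only
#' its own most abundant subset.
#'
#' @inheritParams pair_conditions
#' @inheritParams select_top_peaks
#' @param ra_from_top Restrict the RA side to its own top-`top_n` window
#'   (default) or search the complete RA list.
#' @return See [pair_conditions()].
#' @export
count_cysteines <- function(native, ra, top_n = 50L,
                            mass_range = c(1000, 10000),
                            allowed = c(0L, 4L, 6L, 8L), tolerance = 0.1,
                            ra_from_top = TRUE,
                            constants = mass_constants()) {
  nat <- select_top_peaks(native, top_n, mass_range)
  ral <- if (ra_from_top) select_top_peaks(ra, top_n, mass_range) else ra
  pair_conditions(nat, ral, allowed = allowed, tolerance = tolerance,
                  constants = constants)
}
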