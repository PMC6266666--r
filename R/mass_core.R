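# Monoisotopic residue masses (Da) for the 20 canonical amino acids.
# These are residue (dehydrated) masses; a free peptide adds one water.
.RESIDUE_MASSES <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

#' Monoisotopic residue mass table
#'
#' Returns the monoisotopic masses of the 20 canonical amino-acid residues
#' (dehydrated, i.e. what each residue contributes inside a peptide chain),
#' together with the mass of water and of a proton.
#'
#' @return A list with elements `residues` (named numeric vector of 20 residue
#'   masses in Da), `water_mass` and `proton_mass` (Da).
#' @examples
#' tab <- residue_mass_table()
#' tab$residues[["G"]] + tab$water_mass  # mass of free glycine
#' @export
residue_mass_table <- function() {
  list(
    residues = .RESIDUE_MASSES,
    water_mass = 18.01056,
    proton_mass = 1.00783
  )
}

#' Modification mass constants
#'
#' Mass deltas (Da, monoisotopic) for the chemical states handled by
#' [peptide_mass()] and [ra_mass()]: disulfide bond formation (loss of two
#' hydrogens per bond), N-terminal pyroglutamate formation from glutamine
#' (loss of NH3), hydroxyethylation of a cysteine thiol by iodoethanol
#' (gain of C2H4O), and reduction of a half-cystine to a free thiol
#' (gain of one hydrogen).
#'
#' The per-cysteine shift observed when a natively disulfide-bonded peptide is
#' reduced and alkylated is `delta_reduction_per_cys +
#' delta_hydroxyethyl_per_cys` (~45.034 Da).
#'
#' @param path Optional path to a JSON file overriding any of the constants
#'   (keys as in the returned list). The packaged defaults live at
#'   `system.file("extdata", "mass_constants.json", package = "venomics")`.
#' @return A list with elements `delta_disulfide_per_bond`, `delta_pyroglu`,
#'   `delta_hydroxyethyl_per_cys`, `delta_reduction_per_cys`, and the derived
#'   `delta_ra_per_cys`.
#' @examples
#' mass_constants()$delta_ra_per_cys
#' @export
mass_constants <- function(path = NULL) {
  const <- list(
    delta_disulfide_per_bond = -2 * 1.00783,
    delta_pyroglu = -17.02655,
    delta_hydroxyethyl_per_cys = 44.02621,
    delta_reduction_per_cys = 1.00783
  )
  if (!is.null(path)) {
    override <- jsonlite::read_json(path, simplifyVector = TRUE)
    unknown <- setdiff(names(override), names(const))
    if (length(unknown) > 0L) {
      stop("unknown mass constant(s) in ", path, ": ",
           paste(unknown, collapse = ", "))
    }
    const[names(override)] <- lapply(override, as.numeric)
  }
  stopifnot(const$delta_disulfide_per_bond < 0, const$delta_pyroglu < 0,
            const$delta_hydroxyethyl_per_cys > 0)
  const$delta_ra_per_cys <-
    const$delta_reduction_per_cys + const$delta_hydroxyethyl_per_cys
  const
}

#' Describe a set of covalent modifications
#'
#' Bundles the modification state applied by [peptide_mass()]: number of
#' intramolecular disulfide bonds, N-terminal pyroglutamate (from Gln), number
#' of hydroxyethyl-alkylated cysteines, and arbitrary labelled custom deltas.
#'
#' @param n_disulfides Number of disulfide bonds (each removes 2 H).
#' @param pyroglu Logical; cyclise an N-terminal glutamine to pyroglutamate.
#' @param n_cys_alkylated Number of cysteines carrying a hydroxyethyl adduct.
#' @param custom_deltas Optional named numeric vector of additional mass
#'   deltas in Da (e.g. `c(deamidation = 0.98402)`).
#' @return An object of class `venom_mods`.
#' @examples
#' modifications(n_disulfides = 3)
#' modifications(pyroglu = TRUE)
#' @export
modifications <- function(n_disulfides = 0L, pyroglu = FALSE,
                          n_cys_alkylated = 0L, custom_deltas = NULL) {
  stopifnot(length(n_disulfides) == 1L, n_disulfides >= 0,
            n_disulfides == as.integer(n_disulfides),
            is.logical(pyroglu), length(pyroglu) == 1L, !is.na(pyroglu),
            length(n_cys_alkylated) == 1L, n_cys_alkylated >= 0,
            n_cys_alkylated == as.integer(n_cys_alkylated))
  if (!is.null(custom_deltas)) {
    stopifnot(is.numeric(custom_deltas), !is.null(names(custom_deltas)),
              all(nzchar(names(custom_deltas))))
  }
  structure(
    list(n_disulfides = as.integer(n_disulfides), pyroglu = pyroglu,
         n_cys_alkylated = as.integer(n_cys_alkylated),
         custom_deltas = custom_deltas),
    class = "venom_mods"
  )
}

#' @export
print.venom_mods <- function(x, ...) {
  cat("Modifications:", x$n_disulfides, "disulfide(s),",
      if (x$pyroglu) "N-terminal pyroGlu," else "no pyroGlu,",
      x$n_cys_alkylated, "hydroxyethyl-Cys\n")
  if (!is.null(x$custom_deltas)) {
    cat("  custom:", paste(names(x$custom_deltas), round(x$custom_deltas, 5),
                           sep = " = ", collapse = ", "), "\n")
  }
  invisible(x)
}

# Split a peptide string into residue letters, rejecting non-canonical ones
# with the 1-based position of the first offender.
.residue_vector <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L, !is.na(sequence))
  if (nchar(sequence) == 0L) stop("sequence must be non-empty")
  letters1 <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  bad <- which(!(letters1 %in% names(.RESIDUE_MASSES)))
  if (length(bad) > 0L) {
    stop(sprintf("unknown residue '%s' at position %d", letters1[bad[1]],
                 bad[1]))
  }
  letters1
}

#' Count cysteine residues
#'
#' @param sequence Amino-acid string (canonical one-letter codes).
#' @return Integer count of `C` residues.
#' @examples
#' count_cys("ITCDLIGNERLCVLHCLAKGFRGGWCDGRKVCNCRR")
#' @export
count_cys <- function(sequence) {
  sum(.residue_vector(sequence) == "C")
}

#' Monoisotopic mass of a modified peptide
#'
#' Sums monoisotopic residue masses, adds one water, and applies the
#' modification deltas: `n_disulfides` times the disulfide delta (-2 H per
#' bond), the pyroglutamate delta (-NH3) if requested, `n_cys_alkylated`
#' hydroxyethyl adducts (+C2H4O each), and any custom deltas.
#'
#' @param sequence Amino-acid string; canonical one-letter codes only.
#' @param mods A [modifications()] object.
#' @param constants Mass constants, from [mass_constants()].
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' # native fold of a 6-cysteine defensin-like peptide, 3 disulfides:
#' peptide_mass("ITCDLIGNERLCVLHCLAKGFRGGWCDGRKVCNCRR",
#'              modifications(n_disulfides = 3))
#' @seealso [ra_mass()] for the reduced/alkylated state.
#' @export
peptide_mass <- function(sequence, mods = modifications(),
                         constants = mass_constants()) {
  stopifnot(inherits(mods, "venom_mods"))
  res <- .residue_vector(sequence)
  n_cys <- sum(res == "C")
  if (mods$n_disulfides > n_cys %/% 2L) {
    stop(sprintf("%d disulfide(s) requested but sequence has only %d cysteine(s) (max %d bonds)",
                 mods$n_disulfides, n_cys, n_cys %/% 2L))
  }
  if (mods$n_cys_alkylated > n_cys) {
    stop(sprintf("%d alkylated cysteine(s) requested but sequence has only %d",
                 mods$n_cys_alkylated, n_cys))
  }
  if (mods$pyroglu && res[1] != "Q") {
    stop("pyroglutamate requires an N-terminal glutamine (Q); sequence starts with ",
         res[1])
  }
  tab <- residue_mass_table()
  mass <- sum(tab$residues[res]) + tab$water_mass +
    mods$n_disulfides * constants$delta_disulfide_per_bond +
    (if (mods$pyroglu) constants$delta_pyroglu else 0) +
    mods$n_cys_alkylated * constants$delta_hydroxyethyl_per_cys
  if (!is.null(mods$custom_deltas)) mass <- mass + sum(mods$custom_deltas)
  unname(mass)
}

#' Monoisotopic mass after reduction and hydroxyethyl alkylation
#'
#' Mass of the fully reduced peptide (no disulfide bonds, all cysteines free
#' thiols) with one hydroxyethyl adduct per cysteine -- the species observed
#' after treatment with iodoethanol/triethylphosphine. For a natively oxidised
#' peptide with an even cysteine count this exceeds the native mass by
#' `n_cys * delta_ra_per_cys`.
#'
#' @param sequence Amino-acid string.
#' @param n_cys Cysteine count; must equal `count_cys(sequence)` (passed
#'   explicitly as a guard against sequence/annotation mismatches).
#' @param pyroglu Retain an N-terminal pyroglutamate through the treatment.
#' @param constants Mass constants, from [mass_constants()].
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' ra_mass("ITCDLIGNERLCVLHCLAKGFRGGWCDGRKVCNCRR", 6)
#' @export
ra_mass <- function(sequence, n_cys = count_cys(sequence), pyroglu = FALSE,
                    constants = mass_constants()) {
  actual <- count_cys(sequence)
  if (n_cys != actual) {
    stop(sprintf("n_cys = %d does not match the %d cysteine(s) in the sequence",
                 n_cys, actual))
  }
  peptide_mass(sequence,
               modifications(n_disulfides = 0L, pyroglu = pyroglu,
                             n_cys_alkylated = actual),
               constants = constants)
}

#' Map a native-to-RA mass shift to a cysteine count
#'
#' Given the mass difference between a reduced/alkylated peak and its native
#' counterpart, returns the cysteine count `n` from `allowed` whose expected
#' shift `n * delta_ra_per_cys` lies closest to `delta`, provided the residual
#' is within `tolerance`; ties go to the smaller count. A total function:
#' returns `NA` when no allowed count fits.
#'
#' @param delta Observed mass shift in Da (RA minus native).
#' @param tolerance Maximum residual in Da (> 0).
#' @param allowed Candidate cysteine counts (even, non-negative).
#' @param constants Mass constants, from [mass_constants()].
#' @return Integer cysteine count, or `NA_integer_`.
#' @examples
#' shift_to_ncys(270.18, tolerance = 0.10)        # -> 6
#' shift_to_ncys(0.00, tolerance = 0.10)          # -> 0 (unchanged)
#' shift_to_ncys(100.00, tolerance = 0.10)        # -> NA
#' @export
shift_to_ncys <- function(delta, tolerance = 0.1, allowed = c(0L, 4L, 6L, 8L),
                          constants = mass_constants()) {
  stopifnot(is.numeric(delta), length(delta) == 1L, tolerance > 0,
            length(allowed) >= 1L, all(allowed >= 0),
            all(allowed == as.integer(allowed)))
  allowed <- sort(unique(as.integer(allowed)))
  residual <- abs(delta - allowed * constants$delta_ra_per_cys)
  best <- which.min(residual)  # which.min takes the first, i.e. smallest n, on ties
  if (residual[best] <= tolerance) allowed[best] else NA_integer_
}
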