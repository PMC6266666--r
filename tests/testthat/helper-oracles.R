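# Independent reference implementations used as test oracles. These are
# deliberately naive (quadratic DP, exhaustive search) and share no code with
# the package internals they check.

# Textbook Needleman-Wunsch DP maximising identical aligned positions
# (match 1, mismatch 0, gap 0), tie-broken toward alignments with more
# aligned residue pairs (hence fewest gap columns). Returns identity % =
# matches / alignment length, with alignment length = n + m - pairs.
nw_identity_oracle <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  M <- matrix(0L, n + 1L, m + 1L)  # max matches
  P <- matrix(0L, n + 1L, m + 1L)  # max aligned pairs given max matches
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      diag_m <- M[i, j] + (x[i] == y[j])
      diag_p <- P[i, j] + 1L
      best_m <- max(diag_m, M[i, j + 1L], M[i + 1L, j])
      cand_p <- c(
        if (diag_m == best_m) diag_p,
        if (M[i, j + 1L] == best_m) P[i, j + 1L],
        if (M[i + 1L, j] == best_m) P[i + 1L, j])
      M[i + 1L, j + 1L] <- best_m
      P[i + 1L, j + 1L] <- max(cand_p)
    }
  }
  100 * M[n + 1L, m + 1L] / (n + m - P[n + 1L, m + 1L])
}

# Exhaustive maximum-cardinality candidate/peak matching under a mass
# tolerance (recursion over peaks). Returns the maximum number of pairs.
max_matching_oracle <- function(predicted, observed, tolerance) {
  recurse <- function(p_idx, used) {
    if (p_idx > length(observed)) return(0L)
    best <- recurse(p_idx + 1L, used)  # leave this peak unmatched
    for (c_idx in seq_along(predicted)) {
      if (!used[c_idx] &&
          abs(observed[p_idx] - predicted[c_idx]) <= tolerance) {
        used2 <- used; used2[c_idx] <- TRUE
        best <- max(best, 1L + recurse(p_idx + 1L, used2))
      }
    }
    best
  }
  recurse(1L, rep(FALSE, length(predicted)))
}

# Naive all-pairs scan replicating the native/RA pairing contract: walk
# native peaks by intensity rank, test every RA peak against every allowed
# shift, take the smallest residual (ties: ascending RA mass), never reuse
# an RA peak.
ra_pairing_oracle <- function(native, ra, allowed, tolerance, shift) {
  nat <- native[order(-native$intensity, native$mass), , drop = FALSE]
  ral <- ra[order(-ra$intensity, ra$mass), , drop = FALSE]
  used <- rep(FALSE, nrow(ral))
  out <- list()
  for (i in seq_len(nrow(nat))) {
    best <- NULL
    for (j in seq_len(nrow(ral))) {
      if (used[j]) next
      delta <- ral$mass[j] - nat$mass[i]
      for (ncys in sort(allowed)) {
        resid <- abs(delta - ncys * shift)
        if (resid <= tolerance) {
          if (is.null(best) || resid < best$residual ||
              (resid == best$residual && ral$mass[j] < best$ra_mass)) {
            best <- list(j = j, ra_mass = ral$mass[j], delta = delta,
                         n_cys = ncys, residual = resid)
          }
          break  # smaller ncys checked first; first fit is the assigned count
        }
      }
    }
    if (!is.null(best)) {
      used[best$j] <- TRUE
      out[[length(out) + 1L]] <- data.frame(
        native_mass = nat$mass[i], ra_mass = best$ra_mass,
        delta = best$delta, n_cys = best$n_cys)
    }
  }
  if (length(out) == 0L) {
    data.frame(native_mass = numeric(0), ra_mass = numeric(0),
               delta = numeric(0), n_cys = integer(0))
  } else {
    do.call(rbind, out)
  }
}

# Positional-scan tryptic cleavage oracle (K/R not before P), 0 missed
# cleavages only.
tryptic_oracle <- function(sequence) {
  res <- strsplit(sequence, "")[[1]]
  frags <- character(0)
  cur <- character(0)
  for (i in seq_along(res)) {
    cur <- c(cur, res[i])
    nxt <- if (i < length(res)) res[i + 1L] else ""
    if (res[i] %in% c("K", "R") && nxt != "P" && i < length(res)) {
      frags <- c(frags, paste(cur, collapse = ""))
      cur <- character(0)
    }
  }
  c(frags, paste(cur, collapse = ""))
}

random_peptide_seq <- function(len, alphabet = c("A", "G", "K", "R", "P",
                                                 "S", "T", "L", "E", "D")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}
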