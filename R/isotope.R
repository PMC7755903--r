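# Isotope-envelope substrate for the HDX analysis.
#
# Envelopes are plain numeric vectors of relative intensities over integer
# mass-offset bins, bin 1 being the monoisotopic peak, normalised to sum 1.

# Elemental composition of amino-acid residues (chain residues, i.e. the
# free amino acid minus H2O).  Columns C, H, N, O, S.
RESIDUE_FORMULA <- matrix(c(
  3,  5, 1, 1, 0,   # A
  3,  5, 1, 1, 1,   # C
  4,  5, 1, 3, 0,   # D
  5,  7, 1, 3, 0,   # E
  9,  9, 1, 1, 0,   # F
  2,  3, 1, 1, 0,   # G
  6,  7, 3, 1, 0,   # H
  6, 11, 1, 1, 0,   # I
  6, 12, 2, 1, 0,   # K
  6, 11, 1, 1, 0,   # L
  5,  9, 1, 1, 1,   # M
  4,  6, 2, 2, 0,   # N
  5,  7, 1, 1, 0,   # P
  5,  8, 2, 2, 0,   # Q
  6, 12, 4, 1, 0,   # R
  3,  5, 1, 2, 0,   # S
  4,  7, 1, 2, 0,   # T
  5,  9, 1, 1, 0,   # V
  11, 10, 2, 1, 0,  # W
  9,  9, 1, 2, 0    # Y
), ncol = 5, byrow = TRUE,
  dimnames = list(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
                  c("C", "H", "N", "O", "S")))

# Natural isotope abundance patterns over integer mass offsets (IUPAC).
ISOTOPE_PATTERNS <- list(
  C = c(0.9893, 0.0107),
  H = c(0.999885, 0.000115),
  N = c(0.99636, 0.00364),
  O = c(0.99757, 0.00038, 0.00205),
  S = c(0.9499, 0.0075, 0.0425, 0, 0.0001)
)

#' Elemental composition of a peptide
#'
#' Sums residue formulas and adds one H2O for the intact peptide.
#'
#' @param sequence One-letter amino-acid string.
#' @return Named integer vector with elements C, H, N, O, S.
#' @export
peptide_composition <- function(sequence) {
  ch <- aa_chars(sequence)
  if (!length(ch)) stop("empty sequence")
  counts <- colSums(RESIDUE_FORMULA[ch, , drop = FALSE])
  counts["H"] <- counts["H"] + 2
  counts["O"] <- counts["O"] + 1
  counts
}

#' Natural (undeuterated) isotope envelope of a peptide
#'
#' Aggregated isotopic distribution over integer mass offsets, obtained by
#' convolving the per-element isotope patterns raised to the elemental
#' counts.  The tail is truncated once the cumulative probability reaches
#' `1 - tol` and the result renormalised.
#'
#' @param sequence One-letter amino-acid string.
#' @param tol Tail mass allowed to be dropped at truncation.
#' @return Numeric vector of intensities summing to 1 (class
#'   `isotope_envelope`); element 1 is the monoisotopic peak.
#' @export
natural_envelope <- function(sequence, tol = 1e-6) {
  comp <- peptide_composition(sequence)
  env <- 1
  for (el in names(ISOTOPE_PATTERNS)) {
    if (comp[el] > 0) env <- conv_full(env, conv_pow(ISOTOPE_PATTERNS[[el]], comp[el]))
  }
  keep <- which(cumsum(env) >= 1 - tol)[1]
  env <- env[seq_len(keep)]
  structure(env / sum(env), class = "isotope_envelope")
}

#' Number of exchange-competent backbone amides
#'
#' Standard fast-back-exchange convention: the first `n_fast` residues and
#' every proline from position 3 onward are excluded.
#'
#' @param sequence One-letter amino-acid string.
#' @param n_fast Number of N-terminal residues whose amides back-exchange
#'   too fast to retain label (default 2).
#' @return Integer count, floored at 0.
#' @export
exchangeable_sites <- function(sequence, n_fast = 2L) {
  ch <- aa_chars(sequence)
  if (!length(ch)) stop("empty sequence")
  n_pro <- sum(ch == "P" & seq_along(ch) >= 3L)
  max(0L, length(ch) - as.integer(n_fast) - n_pro)
}

#' Forward model: deuterated isotope envelope
#'
#' Convolves a natural envelope with the mass-shift distribution of a
#' mixture of binomial deuteration populations,
#' `sum_j w_j * Binomial(N_ex, p_j)`.
#'
#' @param natural Natural envelope (numeric, sums to 1).
#' @param w Population weights (sum to 1).
#' @param p Per-population incorporation probabilities in `[0, 1]`.
#' @param N_ex Number of exchangeable amides.
#' @return Normalised envelope of length `length(natural) + N_ex`.
#' @export
deuterated_envelope <- function(natural, w, p, N_ex) {
  stopifnot(length(w) == length(p), length(w) >= 1L,
            abs(sum(w) - 1) < 1e-8, all(w >= 0),
            all(p >= 0), all(p <= 1), N_ex >= 0)
  shift <- mixture_shift(w, p, N_ex)
  env <- conv_full(as.numeric(natural), shift)
  structure(env / sum(env), class = "isotope_envelope")
}

# Mass-shift distribution of a binomial mixture.
mixture_shift <- function(w, p, N_ex) {
  shift <- numeric(N_ex + 1L)
  for (j in seq_along(w)) {
    shift <- shift + w[j] * stats::dbinom(0:N_ex, N_ex, p[j])
  }
  shift
}
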