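# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# One-letter codes of the 20 standard amino acids.
AA_CODES <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
              "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Split a sequence string into one-letter codes, validating the alphabet.
aa_chars <- function(sequence, context = "sequence") {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence)) {
    stop(context, " must be a single character string", call. = FALSE)
  }
  ch <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(ch), AA_CODES)
  if (length(bad)) {
    stop("unknown residue letter(s) in ", context, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  ch
}

# Full linear convolution of two non-negative vectors (polynomial product).
conv_full <- function(a, b) {
  n <- length(a) + length(b) - 1L
  out <- numeric(n)
  for (i in seq_along(a)) {
    idx <- i:(i + length(b) - 1L)
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

# k-fold self-convolution by exponentiation-by-squaring.
conv_pow <- function(pat, k) {
  stopifnot(k >= 0)
  out <- 1
  base <- pat
  while (k > 0) {
    if (k %% 2 == 1) out <- conv_full(out, base)
    base <- conv_full(base, base)
    k <- k %/% 2
  }
  out
}

# Pad a numeric vector with trailing zeros to length n.
pad_to <- function(x, n) {
  if (length(x) >= n) return(x[seq_len(n)])
  c(x, numeric(n - length(x)))
}

stop_if_not_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop(name, " must be TRUE or FALSE", call. = FALSE)
  }
  invisible(x)
}
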