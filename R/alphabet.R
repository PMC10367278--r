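#' Ordered alphabets
#'
#' An alphabet is an ordered set of distinct single characters
#' \eqn{\sigma_1 < \sigma_2 < \dots < \sigma_m}. The order fixes the
#' lexicographic order on sequences and all index arithmetic used by the
#' bucketing constructions: `rank` maps a character to its 1-based position
#' and is the inverse of `chars`.
#'
#' @param chars Character vector of distinct single characters, or a single
#'   string whose characters are taken in order (e.g. `"ACGT"`).
#' @return An object of class `lsb_alphabet` with elements `chars` (ordered
#'   character vector) and `m` (alphabet size).
#' @examples
#' lsb_alphabet("ACGT")
#' lsb_alphabet(c("0", "1"))
#' @export
lsb_alphabet <- function(chars) {
  if (!is.character(chars) || length(chars) == 0) {
    stop("`chars` must be a non-empty character vector or a single string")
  }
  if (length(chars) == 1L && nchar(chars) > 1L) {
    chars <- strsplit(chars, "", fixed = TRUE)[[1L]]
  }
  if (any(nchar(chars) != 1L)) {
    stop("alphabet symbols must be single characters")
  }
  if (anyDuplicated(chars)) {
    stop("alphabet symbols must be distinct")
  }
  if (length(chars) < 2L) {
    stop("an alphabet must have at least 2 symbols")
  }
  structure(list(chars = chars, m = length(chars)), class = "lsb_alphabet")
}

#' @rdname lsb_alphabet
#' @export
dna_alphabet <- function() lsb_alphabet(c("A", "C", "G", "T"))

#' @rdname lsb_alphabet
#' @export
binary_alphabet <- function() lsb_alphabet(c("0", "1"))

#' @export
print.lsb_alphabet <- function(x, ...) {
  cat("<lsb_alphabet> m =", x$m, ":", paste(x$chars, collapse = " < "), "\n")
  invisible(x)
}

as_alphabet <- function(alphabet) {
  if (inherits(alphabet, "lsb_alphabet")) return(alphabet)
  lsb_alphabet(alphabet)
}

# Split one string into its character vector.
seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]

# Ranks sigma^{-1}(s_i) of one sequence; errors on foreign symbols.
seq_ranks <- function(s, alphabet) {
  ch <- seq_chars(s)
  k <- match(ch, alphabet$chars)
  if (anyNA(k)) {
    bad <- unique(ch[is.na(k)])
    stop(sprintf("sequence '%s' contains symbols outside the alphabet: %s",
                 s, paste(bad, collapse = ", ")))
  }
  k
}

# Rank matrix for a vector of equal-length sequences (one row per sequence).
seq_ranks_matrix <- function(seqs, alphabet) {
  n <- nchar(seqs[1L])
  if (any(nchar(seqs) != n)) stop("sequences must all have the same length")
  ch <- unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE)
  k <- match(ch, alphabet$chars)
  if (anyNA(k)) {
    bad <- unique(ch[is.na(k)])
    stop(sprintf("sequences contain symbols outside the alphabet: %s",
                 paste(bad, collapse = ", ")))
  }
  matrix(k, ncol = n, byrow = TRUE)
}

# Collapse a character matrix (one row per sequence) into strings.
collapse_rows <- function(mat) {
  if (nrow(mat) == 0L) return(character(0))
  do.call(paste0, as.data.frame(mat, stringsAsFactors = FALSE))
}

ranks_to_seqs <- function(kmat, alphabet) {
  collapse_rows(matrix(alphabet$chars[kmat], nrow = nrow(kmat)))
}

validate_seq <- function(s, alphabet, n = NULL) {
  if (!is.character(s) || length(s) != 1L) stop("expected a single string")
  invisible(seq_ranks(s, alphabet))
  if (!is.null(n) && nchar(s) != n) {
    stop(sprintf("expected a sequence of length %d, got '%s' (length %d)",
                 n, s, nchar(s)))
  }
  invisible(s)
}

#' Enumerate the sequence space
#'
#' All \eqn{m^n} length-`n` sequences over the alphabet, in the
#' lexicographic order induced by the alphabet order. This is the canonical
#' processing order of [build_global()].
#'
#' @param n Sequence length (>= 1).
#' @param alphabet An [lsb_alphabet()] (or something coercible to one).
#' @param max_space Safety cap on \eqn{m^n}; enumeration refuses beyond it.
#' @return Character vector of length \eqn{m^n}, lexicographically sorted.
#' @examples
#' all_sequences(2, lsb_alphabet("ACGT"))
#' @export
all_sequences <- function(n, alphabet, max_space = 1e6) {
  alphabet <- as_alphabet(alphabet)
  check_space(n, alphabet, max_space)
  m <- alphabet$m
  # position 1 is the most significant digit: build columns right-to-left
  cols <- vector("list", n)
  for (i in seq_len(n)) {
    each <- m^(n - i)
    times <- m^(i - 1)
    cols[[i]] <- rep(rep(alphabet$chars, each = each), times = times)
  }
  collapse_rows(do.call(cbind, cols))
}

check_space <- function(n, alphabet, max_space) {
  if (n < 1) stop("`n` must be >= 1")
  size <- alphabet$m^n
  if (size > max_space) {
    stop(sprintf(
      "sequence space has %g sequences (> cap %g); explicit enumeration is intended for small n -- raise `max_space` only if you really mean it",
      size, max_space))
  }
  invisible(size)
}

# Largest values handled by the O(n) bucket arithmetic are n * m^(n-1)
# (bucket ids) and m^n (suffix encodings); both must stay exactly
# representable in a double.
check_exact_arithmetic <- function(n, m) {
  lim <- 2^53
  if (m^n > lim || n * m^(n - 1) > lim) {
    stop(sprintf(
      "n = %d with |alphabet| = %d needs bucket ids beyond 2^53, which exceed exact double-precision integer range",
      n, m))
  }
  invisible(TRUE)
}
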