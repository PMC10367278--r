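#' Optimal (1,2)-sensitive bucketing over the full sequence space
#'
#' Builds the bucket table of the global-counter construction: sequences
#' are processed in the lexicographic order induced by the alphabet, and
#' every occurrence of the smallest character \eqn{\sigma_1} at position i
#' of a processed sequence opens a fresh bucket (consecutive ids from 1)
#' holding the m sequences that agree with it everywhere except position i.
#' The induced function f is (1,2)-sensitive: sequences within one edit
#' share a bucket, sequences two or more edits apart share none. The table
#' has exactly \eqn{n m^{n-1}} buckets of m sequences each, and every
#' sequence lies in exactly n buckets.
#'
#' The explicit table costs \eqn{O(n m^n)} time and space and is intended
#' for small n (verification, teaching, oracles); [buckets_of()] computes
#' the same ids for a single sequence in O(n).
#'
#' @inheritParams all_sequences
#' @return An object of class `lsb_bucket_table`: a list with `n`,
#'   `alphabet`, `seq_to_buckets` (named list: sequence -> numeric ids) and
#'   `bucket_to_seqs` (list indexed by bucket id -> character vector).
#' @examples
#' bt <- build_global(2, dna_alphabet())
#' bt$seq_to_buckets[["AT"]]   # 2 5
#' bt$bucket_to_seqs[[6]]      # CA CC CG CT
#' @export
build_global <- function(n, alphabet, max_space = 1e6) {
  alphabet <- as_alphabet(alphabet)
  m <- alphabet$m
  seqs <- all_sequences(n, alphabet, max_space)
  kmat <- seq_ranks_matrix(seqs, alphabet)
  n_buckets <- n * m^(n - 1)
  bucket_to_seqs <- vector("list", n_buckets)
  seq_to_buckets <- rep(list(numeric(0)), length(seqs))
  names(seq_to_buckets) <- seqs
  counter <- 0
  for (idx in seq_along(seqs)) {
    ch <- seq_chars(seqs[idx])
    for (i in seq_len(n)) {
      if (kmat[idx, i] == 1L) {
        counter <- counter + 1
        mat <- matrix(ch, nrow = m, ncol = n, byrow = TRUE)
        mat[, i] <- alphabet$chars
        members <- collapse_rows(mat)
        bucket_to_seqs[[counter]] <- members
        for (mem in members) {
          seq_to_buckets[[mem]] <- c(seq_to_buckets[[mem]], counter)
        }
      }
    }
  }
  stopifnot(counter == n_buckets)
  structure(list(n = n, alphabet = alphabet,
                 seq_to_buckets = seq_to_buckets,
                 bucket_to_seqs = bucket_to_seqs),
            class = "lsb_bucket_table")
}

#' @export
print.lsb_bucket_table <- function(x, ...) {
  cat(sprintf("<lsb_bucket_table> n = %d, m = %d: %d buckets, %d sequences\n",
              x$n, x$alphabet$m, length(x$bucket_to_seqs),
              length(x$seq_to_buckets)))
  invisible(x)
}

#' Number of same-length sequences lexicographically before a sequence
#'
#' The size of \eqn{S_\sigma(t)}, the set of sequences of the same length
#' that precede `t` in the lexicographic order induced by the alphabet.
#' This is the base-m numeral encoding of `t` with digit values
#' \eqn{\sigma^{-1}(t_j) - 1}: \eqn{\sum_j (\sigma^{-1}(t_j) - 1) m^{len-j}}.
#' The empty string encodes to 0.
#'
#' @param t A string over the alphabet (any length, possibly `""`).
#' @inheritParams all_sequences
#' @return A non-negative number (exact integer stored as double).
#' @examples
#' lex_rank("T", dna_alphabet())   # 3: A, C, G come before T
#' @export
lex_rank <- function(t, alphabet) {
  alphabet <- as_alphabet(alphabet)
  if (!is.character(t) || length(t) != 1L) stop("expected a single string")
  if (nchar(t) == 0L) return(0)
  k <- seq_ranks(t, alphabet)
  len <- length(k)
  check_exact_arithmetic(len, alphabet$m)
  sum((k - 1) * alphabet$m^(len - seq_len(len)))
}

#' Occurrences of the smallest character before a sequence
#'
#' `count_sigma1_before(t)` is the total number of \eqn{\sigma_1}'s among
#' all sequences that precede `t` in lexicographic order -- the value of
#' the global bucket counter when the construction reaches `t`. It is
#' computed in O(n) as \eqn{\sum_i \mu_i(t)} where
#' \deqn{\mu_i(t) = |S_\sigma(t_{i+1} \dots t_n)| \quad \mathrm{if~} t_i = \sigma_1,}
#' \deqn{\mu_i(t) = (\sigma^{-1}(t_i) - 1)(n-i) m^{n-i-1} + m^{n-i} \quad \mathrm{otherwise.}}
#' The coefficient in the second branch is \eqn{\sigma^{-1}(t_i) - 1}
#' (the number of complete character blocks preceding \eqn{t_i}); see the
#' package vignette for the derivation and its validation against direct
#' enumeration.
#'
#' @param t A length-n string over the alphabet.
#' @inheritParams all_sequences
#' @return A non-negative number.
#' @examples
#' count_sigma1_before("CA", dna_alphabet())  # 5: A's in AA, AC, AG, AT
#' @export
count_sigma1_before <- function(t, alphabet) {
  alphabet <- as_alphabet(alphabet)
  sum(prefix_profile(t, alphabet)$mu)
}

# Linear-time profile of one sequence: ranks k_i, prefix sigma_1 counts
# ones_prefix[i] = #^1_i(s) (with a leading 0 for i = 0), suffix encodings
# nu[i] = |S_sigma(s_i..s_n)| (with nu[n+1] = 0), and the mu_i terms whose
# sum is count_sigma1_before.
prefix_profile <- function(s, alphabet) {
  k <- seq_ranks(s, alphabet)
  n <- length(k)
  m <- alphabet$m
  check_exact_arithmetic(n, m)
  nu <- numeric(n + 1L)
  for (i in n:1) nu[i] <- (k[i] - 1) * m^(n - i) + nu[i + 1L]
  i <- seq_len(n)
  mu <- ifelse(k == 1L,
               nu[i + 1L],
               (k - 1) * (n - i) * m^(n - i - 1L) + m^(n - i))
  ones_prefix <- c(0, cumsum(k == 1L))
  list(k = k, n = n, m = m, nu = nu, mu = mu, ones_prefix = ones_prefix)
}

#' O(n) bucket ids of the (1,2)-sensitive construction
#'
#' Computes, without building the global table, the n bucket ids that
#' [build_global()] assigns to `s`. The i-th id is the bucket opened at
#' position i of \eqn{s^i} (s with position i replaced by \eqn{\sigma_1}):
#' \deqn{count(s^i) + \#^1_{i-1}(s) + 1,}
#' where the counts for all i are derived from a single O(n) profile of `s`
#' via
#' \deqn{count(s^i) = count(s) - \mu_i(s) - \#^1_{i-1}(s)(\sigma^{-1}(s_i)-1) m^{n-i} + |S_\sigma(s_{i+1} \dots s_n)|.}
#'
#' @param s A length-n string over the alphabet.
#' @inheritParams all_sequences
#' @return Numeric vector of n bucket ids, ordered by position i
#'   (ids at distinct positions are always distinct).
#' @examples
#' buckets_of("AT", dna_alphabet())  # 5 2: buckets opened at positions 1, 2
#' sort(buckets_of("AT", dna_alphabet()))
#' @export
buckets_of <- function(s, alphabet) {
  alphabet <- as_alphabet(alphabet)
  p <- prefix_profile(s, alphabet)
  n <- p$n
  i <- seq_len(n)
  count_s <- sum(p$mu)
  ones_before <- p$ones_prefix[i]     # #^1_{i-1}(s)
  count_si <- count_s - p$mu -
    ones_before * (p$k - 1) * p$m^(n - i) +
    p$nu[i + 1L]
  count_si + ones_before + 1
}
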