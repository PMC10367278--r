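#' Recursive partition into minimum (1,1)-guaranteed subsets
#'
#' Partitions the sequence space \eqn{\Sigma^n} into m blocks
#' \eqn{B_n^1 \sqcup \dots \sqcup B_n^m}, each a minimum (1,1)-guaranteed
#' subset of size \eqn{m^{n-1}}: any two sequences within one edit always
#' have a common 1-neighbor inside every block. The recursion prepends
#' characters to the blocks of the length-(n-1) partition with a rotation:
#' \deqn{B_n^i = (c_1 \circ B_{n-1}^i) \sqcup (c_2 \circ B_{n-1}^{i+1})
#'   \sqcup \dots \sqcup (c_m \circ B_{n-1}^{i-1}),}
#' with base case \eqn{B_1^p = \{c_p\}}. The explicit construction is an
#' oracle for small n; production paths use [partition_index()], which
#' never materializes a block.
#'
#' @inheritParams all_sequences
#' @return A list of m character vectors (sorted), block i at position i.
#' @examples
#' build_partition(2, dna_alphabet())[[1]]  # AA CC GG TT
#' @export
build_partition <- function(n, alphabet, max_space = 1e6) {
  alphabet <- as_alphabet(alphabet)
  check_space(n, alphabet, max_space)
  m <- alphabet$m
  blocks <- as.list(alphabet$chars)
  if (n > 1) {
    for (len in 2:n) {
      nxt <- vector("list", m)
      for (i in seq_len(m)) {
        parts <- character(0)
        for (k in seq_len(m)) {
          # c_k is paired with block (i + k - 1), wrapping around
          j <- ((i + k - 2L) %% m) + 1L
          parts <- c(parts, paste0(alphabet$chars[k], blocks[[j]]))
        }
        nxt[[i]] <- parts
      }
      blocks <- nxt
    }
  }
  lapply(blocks, sort)
}

#' Block index of a sequence in the (1,1)-guaranteed partition
#'
#' Returns, for each sequence, the unique index \eqn{\ell \in 1..m} with
#' \eqn{s \in B_n^\ell}, in O(n) per sequence and without constructing any
#' block. The sequence is scanned backwards: the last character \eqn{c_p}
#' gives the base-case index p, and each preceding character \eqn{c_k}
#' updates the suffix index j via \eqn{\ell = (j + m + 1 - k) \bmod m},
#' where a result of 0 denotes block m (block indices are 1-based).
#'
#' @param s Character vector of equal-length sequences over the alphabet.
#' @inheritParams all_sequences
#' @return Integer vector of block indices in 1..m, one per sequence.
#' @examples
#' partition_index(c("TAA", "GGG"), dna_alphabet())  # 2 3
#' @export
partition_index <- function(s, alphabet) {
  alphabet <- as_alphabet(alphabet)
  if (!is.character(s)) stop("`s` must be character")
  if (length(s) == 0L) return(integer(0))
  kmat <- seq_ranks_matrix(s, alphabet)
  partition_index_ranks(kmat, alphabet$m)
}

# Backward scan on a rank matrix (rows = sequences), vectorized over rows.
partition_index_ranks <- function(kmat, m) {
  n <- ncol(kmat)
  j <- kmat[, n]
  if (n > 1L) {
    for (p in (n - 1L):1L) {
      j <- ((j + m + 1L - kmat[, p] - 1L) %% m) + 1L
    }
  }
  as.integer(j)
}

#' Membership in one partition block
#'
#' O(n) membership query for \eqn{B_n^i}: true iff
#' `partition_index(s) == index`. The block itself is never materialized.
#'
#' @inheritParams partition_index
#' @param index Block index in 1..m.
#' @return Logical vector, one element per sequence in `s`.
#' @examples
#' is_member("AA", 1, dna_alphabet())  # TRUE
#' is_member("AC", 1, dna_alphabet())  # FALSE (AC is in block 2)
#' @export
is_member <- function(s, index, alphabet) {
  alphabet <- as_alphabet(alphabet)
  if (index < 1 || index > alphabet$m) {
    stop(sprintf("`index` must be in 1..%d", alphabet$m))
  }
  partition_index(s, alphabet) == as.integer(index)
}
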