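#' Edit distance between sequences
#'
#' Unit-cost Levenshtein distance (substitutions, insertions and deletions
#' each cost 1), the metric of the sequence space \eqn{S_n = (\Sigma^n,
#' edit)}. Both arguments are validated against the alphabet; `t` may be a
#' vector, in which case the distance from `s` to each element is returned.
#'
#' @param s A single sequence (string over `alphabet`).
#' @param t A sequence or character vector of sequences.
#' @param alphabet An [lsb_alphabet()].
#' @return Integer vector of distances, one per element of `t`.
#' @examples
#' dna <- dna_alphabet()
#' edit_distance("AC", "CA", dna)  # 2: no single edit maps AC to CA
#' @export
edit_distance <- function(s, t, alphabet) {
  alphabet <- as_alphabet(alphabet)
  validate_seq(s, alphabet)
  if (!is.character(t) || length(t) < 1L) stop("`t` must be character")
  for (ti in unique(t)) validate_seq(ti, alphabet)
  as.integer(utils::adist(s, t)[1L, ])
}

# Distance of s to many candidate strings, skipping validation (internal
# hot path; candidates are constructed from alphabet symbols).
edit_distance_many <- function(s, candidates) {
  if (length(candidates) == 0L) return(integer(0))
  as.integer(utils::adist(s, candidates)[1L, ])
}

#' Edit-distance neighborhood of a sequence
#'
#' The r-neighborhood \eqn{N_n^r(s)} is the set of all length-n sequences
#' within edit distance `r` of `s`. Candidates are generated by applying
#' `b` indel pairs (one deletion plus one insertion, the length-preserving
#' unit of non-substitution edits) and up to `r - 2b` substitutions for
#' every `b` up to `floor(r/2)`, de-duplicated, and then verified by the
#' edit-distance DP, so the result never under- or over-counts. For r = 1
#' the size is always \eqn{(m-1) n + 1}.
#'
#' @inheritParams edit_distance
#' @param r Radius (integer >= 0).
#' @return Character vector of distinct sequences, sorted; always contains
#'   `s` itself.
#' @examples
#' length(neighborhood("AC", 1, dna_alphabet()))  # (4-1)*2 + 1 = 7
#' @export
neighborhood <- function(s, r, alphabet) {
  alphabet <- as_alphabet(alphabet)
  validate_seq(s, alphabet)
  if (r < 0) stop("`r` must be >= 0")
  if (r == 0) return(s)
  cand <- unique(neighborhood_candidates(s, r, alphabet))
  keep <- edit_distance_many(s, cand) <= r
  sort(cand[keep])
}

# All length-n strings reachable with b indel pairs + <= (r - 2b) subs,
# b = 0..floor(r/2). Complete for equal-length sequences: any pair at edit
# distance d <= r decomposes into b indel pairs and d - 2b substitutions.
neighborhood_candidates <- function(s, r, alphabet) {
  ch <- seq_chars(s)
  out <- list(s, substitution_variants(ch, r, alphabet))
  for (b in seq_len(r %/% 2)) {
    smax <- r - 2L * b
    bases <- if (b == 1L) single_indel_pair_variants(ch, alphabet)
             else multi_indel_pair_variants(ch, b, alphabet)
    if (smax == 0L) {
      out[[length(out) + 1L]] <- collapse_rows(bases)
    } else {
      for (ri in seq_len(nrow(bases))) {
        out[[length(out) + 1L]] <-
          substitution_variants(bases[ri, ], smax, alphabet)
      }
    }
  }
  unlist(out, use.names = FALSE)
}

# One deletion at every position x one insertion at every gap x every
# character, vectorized: rows of a character matrix, one per variant.
single_indel_pair_variants <- function(ch, alphabet) {
  n <- length(ch)
  m <- alphabet$m
  nt <- n * n                             # (deletion pos, insertion gap)
  d0 <- rep(seq_len(n), each = n)         # deleted position in ch
  p <- rep(0:(n - 1L), times = n)         # insertion gap in the core
  tpl <- matrix(0L, nt, n)
  q <- col(tpl)
  core_idx <- q - (q > p + 1L)            # index into ch[-d0]
  src <- core_idx + (core_idx >= d0)      # index into ch
  src[cbind(seq_len(nt), p + 1L)] <- 1L   # placeholder, overwritten below
  vals <- matrix(ch[src], nt, n)
  big <- vals[rep(seq_len(nt), each = m), , drop = FALSE]
  big[cbind(seq_len(nt * m), rep(p + 1L, each = m))] <-
    rep(alphabet$chars, times = nt)
  big
}

# b >= 2 indel pairs: recursive insertion enumeration over all deletion
# combinations; only reachable at small n (higher radii under the cap).
multi_indel_pair_variants <- function(ch, b, alphabet) {
  n <- length(ch)
  if (b > n) return(matrix(character(0), 0L, n))
  grow <- function(core, left) {
    if (left == 0L) return(list(core))
    res <- list()
    for (pos in 0:length(core)) {
      for (c0 in alphabet$chars) {
        res <- c(res, grow(append(core, c0, after = pos), left - 1L))
      }
    }
    res
  }
  rows <- list()
  for (del in utils::combn(n, b, simplify = FALSE)) {
    rows <- c(rows, grow(ch[-del], b))
  }
  do.call(rbind, rows)
}

# All strings obtained from the char vector `ch` by at most smax
# substitutions. For each substitution count k, every k-subset of
# positions is combined with every choice of replacement characters via a
# single matrix-index assignment.
substitution_variants <- function(ch, smax, alphabet) {
  n <- length(ch)
  m <- alphabet$m
  out <- list(paste(ch, collapse = ""))
  if (smax < 1L) return(out[[1L]])
  # alt[i, ] = the m - 1 characters unequal to ch[i]
  k0 <- match(ch, alphabet$chars)
  alt <- matrix(alphabet$chars[t(vapply(k0, function(x)
    seq_len(m)[-x], integer(m - 1L)))], nrow = n)
  for (k in seq_len(min(smax, n))) {
    combos <- utils::combn(n, k)            # k x C position sets
    C <- ncol(combos)
    R <- (m - 1L)^k                         # char choices per position set
    N <- C * R
    big <- matrix(ch, N, n, byrow = TRUE)
    combo_id <- rep(seq_len(C), each = R)
    within <- rep(seq_len(R), times = C) - 1L
    for (j in seq_len(k)) {
      pos <- combos[j, combo_id]
      choice <- (within %/% (m - 1L)^(j - 1L)) %% (m - 1L) + 1L
      big[cbind(seq_len(N), pos)] <- alt[cbind(pos, choice)]
    }
    out[[length(out) + 1L]] <- collapse_rows(big)
  }
  unlist(out, use.names = FALSE)
}

#' Edit-type category of an equal-length pair
#'
#' A pair of length-n sequences at edit distance d belongs to category i if
#' it can be transformed with exactly i indel pairs (i insertions plus i
#' deletions) and d - 2i substitutions, but not with i - 1 indel pairs.
#' Category 0 means the Hamming distance equals the edit distance. The
#' category is computed by a DP over (position in s, position in t,
#' deletions used) that finds, for each candidate i, the minimum number of
#' substitutions achievable with exactly i insertions and i deletions; the
#' smallest i whose minimum is d - 2i is returned.
#'
#' @inheritParams edit_distance
#' @param t A single sequence of the same length as `s`.
#' @return Integer i with \eqn{0 \le i \le \lfloor d/2 \rfloor}.
#' @examples
#' edit_type_category("ACGT", "CGTA", dna_alphabet())  # 1: one indel pair
#' @export
edit_type_category <- function(s, t, alphabet) {
  alphabet <- as_alphabet(alphabet)
  validate_seq(s, alphabet)
  validate_seq(t, alphabet, n = nchar(s))
  d <- edit_distance(s, t, alphabet)
  if (d == 0L) return(0L)
  bmax <- d %/% 2L
  minsubs <- min_subs_by_indel_pairs(seq_chars(s), seq_chars(t), bmax)
  for (i in 0:bmax) {
    if (!is.na(minsubs[i + 1L]) && minsubs[i + 1L] <= d - 2L * i) {
      return(i)
    }
  }
  # unreachable: i = bmax always admits a script of total cost d
  stop("internal error: no edit-type category found")
}

# minsubs[b+1] = minimum substitutions over alignments of s onto t using
# exactly b deletions and b insertions (NA if infeasible). States are
# vectorized over the deletion count.
min_subs_by_indel_pairs <- function(sch, tch, bmax) {
  n <- length(sch)
  INF <- n + 1000
  nb <- bmax + 1L
  # dp[[i+1]][[j+1]] is a vector over dels = 0..bmax of min substitutions
  # aligning s[1..i] to t[1..j]; insertions used = dels - (i - j).
  prev <- vector("list", n + 1L)
  # i = 0 row: j insertions, 0 deletions (dels index 1)
  for (j in 0:n) {
    v <- rep(INF, nb)
    v[1L] <- 0
    prev[[j + 1L]] <- v
  }
  for (i in 1:n) {
    cur <- vector("list", n + 1L)
    # j = 0: i deletions
    v <- rep(INF, nb)
    if (i <= bmax) v[i + 1L] <- 0
    cur[[1L]] <- v
    for (j in 1:n) {
      sub <- prev[[j]] + (sch[i] != tch[j])          # match / substitution
      del <- c(INF, prev[[j + 1L]][-nb])             # delete s[i]: dels + 1
      ins <- cur[[j]]                                # insert t[j]
      best <- pmin(sub, del, ins)
      # insertions used must be non-negative: dels >= i - j
      if (i > j) {
        lo <- i - j
        if (lo >= 1L) best[seq_len(min(lo, nb))] <- INF
      }
      cur[[j + 1L]] <- best
    }
    prev <- cur
  }
  v <- prev[[n + 1L]]
  v[v >= INF] <- NA
  v
}
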