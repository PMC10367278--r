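#' Bucketing schemes with proved (d1,d2) sensitivity
#'
#' A scheme is a named locality-sensitive bucketing function together with
#' its proved sensitivity pair \eqn{(d_1, d_2)}: any two sequences within
#' edit distance d1 share at least one bucket, any two at distance d2 or
#' more share none. Three kinds are available:
#'
#' * `"lsb12"` -- the optimal (1,2)-sensitive construction with integer
#'   bucket ids ([buckets_of()]); no radius.
#' * `"full"` -- neighborhood bucketing \eqn{f^r_B(s) = N_n^r(s)} with
#'   \eqn{B = \Sigma^n}: buckets are labeled by length-n sequences and a
#'   sequence is mapped to its whole r-neighborhood. Sensitivity is
#'   \eqn{(2r-1, 2r+1)} for odd r and \eqn{(2r, 2r+1)} for even r.
#' * `"partition"` -- the same with \eqn{B = B_n^i}, a minimum
#'   (1,1)-guaranteed block of the recursive partition: only neighbors
#'   passing the O(n) membership query become buckets. Sensitivity is
#'   (1,3) for r = 1, (3,5) for r = 2, and \eqn{(r, 2r+1)} for r > 2.
#'
#' @param kind One of `"lsb12"`, `"full"`, `"partition"`.
#' @param r Neighborhood radius (>= 1); forbidden for `"lsb12"`.
#' @param index Partition block index in 1..m (only for `"partition"`);
#'   all blocks carry the same guarantees, the default is block 1.
#' @return An object of class `lsb_scheme` with fields `kind`, `r`,
#'   `index`, `claimed_d1`, `claimed_d2`, and `name`.
#' @examples
#' lsb_scheme("partition", r = 2)   # the (3,5)-sensitive function
#' @export
lsb_scheme <- function(kind = c("lsb12", "full", "partition"), r = NULL,
                       index = 1L) {
  kind <- match.arg(kind)
  if (kind == "lsb12") {
    if (!is.null(r)) stop("`r` does not apply to the lsb12 scheme")
    d <- c(1L, 2L)
    name <- "lsb12"
  } else {
    if (is.null(r)) stop(sprintf("scheme '%s' needs a radius `r`", kind))
    r <- as.integer(r)
    rmin <- if (kind == "full") 0L else 1L  # r = 0 is identity bucketing
    if (r < rmin) stop(sprintf("`r` must be >= %d for scheme '%s'", rmin, kind))
    d <- scheme_sensitivity(kind, r)
    name <- if (kind == "full") sprintf("full-r%d", r)
            else sprintf("partition-r%d-i%d", r, as.integer(index))
  }
  structure(list(kind = kind, r = r, index = as.integer(index),
                 claimed_d1 = d[1L], claimed_d2 = d[2L], name = name),
            class = "lsb_scheme")
}

scheme_sensitivity <- function(kind, r) {
  if (kind == "full") {
    if (r %% 2L == 1L) c(2L * r - 1L, 2L * r + 1L) else c(2L * r, 2L * r + 1L)
  } else {
    if (r == 1L) c(1L, 3L)
    else if (r == 2L) c(3L, 5L)
    else c(r, 2L * r + 1L)
  }
}

#' @export
print.lsb_scheme <- function(x, ...) {
  cat(sprintf("<lsb_scheme> %s: (%d, %d)-sensitive\n",
              x$name, x$claimed_d1, x$claimed_d2))
  invisible(x)
}

#' Default scheme registry
#'
#' The schemes used throughout the package: the (1,2)-sensitive integer
#' construction, full-neighborhood bucketing for r = 1..3, and partition
#' bucketing for r = 1..3.
#'
#' @param index Partition block index passed to the partition schemes.
#' @return Named list of [lsb_scheme()] objects.
#' @export
scheme_registry <- function(index = 1L) {
  schemes <- c(list(lsb_scheme("lsb12")),
               lapply(1:3, function(r) lsb_scheme("full", r = r)),
               lapply(1:3, function(r) lsb_scheme("partition", r = r,
                                                  index = index)))
  names(schemes) <- vapply(schemes, `[[`, "", "name")
  schemes
}

#' Bucket labels assigned to a sequence
#'
#' Evaluates the bucketing function of a scheme on one sequence. For
#' `"full"` the labels are the whole r-neighborhood; for `"partition"`
#' only the neighbors that belong to block \eqn{B_n^i} (checked with the
#' O(n) membership query -- the block is never materialized); for
#' `"lsb12"` the integer ids from [buckets_of()].
#'
#' @param s A single sequence.
#' @param scheme An [lsb_scheme()].
#' @inheritParams all_sequences
#' @return For `"lsb12"` a numeric id vector, otherwise a character vector
#'   of sequence labels (sorted).
#' @examples
#' assign_buckets("AC", lsb_scheme("partition", r = 1), dna_alphabet())
#' @export
assign_buckets <- function(s, scheme, alphabet) {
  alphabet <- as_alphabet(alphabet)
  stopifnot(inherits(scheme, "lsb_scheme"))
  switch(scheme$kind,
    lsb12 = buckets_of(s, alphabet),
    full = neighborhood(s, scheme$r, alphabet),
    partition = {
      nb <- neighborhood(s, scheme$r, alphabet)
      nb[is_member(nb, scheme$index, alphabet)]
    })
}

#' Do two sequences share a bucket?
#'
#' True iff the bucket sets of `s` and `t` under the scheme intersect.
#' For neighborhood schemes a triangle-inequality shortcut applies: labels
#' are within radius r of both sequences, so at edit distance
#' \eqn{\ge 2r + 1} the sets cannot intersect and no neighborhood is
#' materialized. On the near side the actual intersection is always
#' computed. Set `shortcut = FALSE` to force full materialization on both
#' sides (as the exhaustive verifier does).
#'
#' @param s,t Sequences of equal length.
#' @inheritParams assign_buckets
#' @param shortcut Allow the far-side triangle shortcut (default `TRUE`).
#' @return Logical scalar.
#' @export
share_bucket <- function(s, t, scheme, alphabet, shortcut = TRUE) {
  alphabet <- as_alphabet(alphabet)
  stopifnot(inherits(scheme, "lsb_scheme"))
  if (scheme$kind == "lsb12") {
    return(length(intersect(buckets_of(s, alphabet),
                            buckets_of(t, alphabet))) > 0L)
  }
  r <- scheme$r
  if (shortcut && edit_distance(s, t, alphabet) >= 2L * r + 1L) {
    return(FALSE)
  }
  # common labels are the sequences within r of both s and t
  nb <- neighborhood(s, r, alphabet)
  common <- nb[edit_distance_many(t, nb) <= r]
  if (scheme$kind == "partition") {
    common <- common[is_member(common, scheme$index, alphabet)]
  }
  length(common) > 0L
}

#' Exhaustive sensitivity verification
#'
#' Checks both halves of the claimed \eqn{(d_1, d_2)} sensitivity of a
#' scheme over every unordered pair of length-n sequences: every pair at
#' edit distance \eqn{\le d_1} must share a bucket, every pair at distance
#' \eqn{\ge d_2} must not. Bucket sets are fully materialized and
#' intersected -- no theorem-derived shortcut is used, so the verification
#' is independent of the results it tests. Pairs at distances strictly
#' inside the gap \eqn{(d_1, d_2)} carry no guarantee; their empirical
#' collision frequencies are reported, not judged.
#'
#' @inheritParams all_sequences
#' @param scheme An [lsb_scheme()].
#' @param claimed_d1,claimed_d2 Sensitivity pair to check; defaults to the
#'   scheme's proved values.
#' @return An object of class `lsb_sensitivity_report`: `pass`,
#'   `close_violations` / `far_violations` (data frames with columns
#'   `s`, `t`, `d`), `checked_pairs`, `bucket_count` (|B|, measured),
#'   `per_seq_bucket_sizes` (table of |f(s)|), and `gap` (per-distance
#'   collision frequencies inside the gap).
#' @examples
#' rep <- verify_sensitivity(2, dna_alphabet(), lsb_scheme("lsb12"))
#' rep$pass
#' @export
verify_sensitivity <- function(n, alphabet, scheme,
                               claimed_d1 = scheme$claimed_d1,
                               claimed_d2 = scheme$claimed_d2,
                               max_space = 1e6) {
  alphabet <- as_alphabet(alphabet)
  stopifnot(inherits(scheme, "lsb_scheme"))
  seqs <- all_sequences(n, alphabet, max_space)
  assigns <- lapply(seqs, assign_buckets, scheme = scheme,
                    alphabet = alphabet)
  dmat <- utils::adist(seqs)
  N <- length(seqs)
  close_s <- close_t <- far_s <- far_t <- character(0)
  close_d <- far_d <- integer(0)
  gap_pairs <- gap_coll <- integer(max(0L, claimed_d2 - claimed_d1 - 1L))
  for (a in seq_len(N - 1L)) {
    fa <- assigns[[a]]
    for (b in (a + 1L):N) {
      d <- dmat[a, b]
      inter <- length(intersect(fa, assigns[[b]])) > 0L
      if (d <= claimed_d1 && !inter) {
        close_s <- c(close_s, seqs[a]); close_t <- c(close_t, seqs[b])
        close_d <- c(close_d, d)
      } else if (d >= claimed_d2 && inter) {
        far_s <- c(far_s, seqs[a]); far_t <- c(far_t, seqs[b])
        far_d <- c(far_d, d)
      } else if (d > claimed_d1 && d < claimed_d2) {
        g <- d - claimed_d1
        gap_pairs[g] <- gap_pairs[g] + 1L
        if (inter) gap_coll[g] <- gap_coll[g] + 1L
      }
    }
  }
  bucket_count <- length(unique(unlist(assigns)))
  gap <- if (claimed_d2 - claimed_d1 > 1L) {
    data.frame(d = (claimed_d1 + 1L):(claimed_d2 - 1L),
               pairs = gap_pairs, collisions = gap_coll,
               frequency = ifelse(gap_pairs > 0, gap_coll / gap_pairs, NA))
  } else {
    data.frame(d = integer(0), pairs = integer(0), collisions = integer(0),
               frequency = numeric(0))
  }
  structure(list(
    n = n, alphabet = alphabet, scheme = scheme,
    claimed_d1 = claimed_d1, claimed_d2 = claimed_d2,
    checked_pairs = N * (N - 1L) / 2L,
    close_violations = data.frame(s = close_s, t = close_t, d = close_d),
    far_violations = data.frame(s = far_s, t = far_t, d = far_d),
    bucket_count = bucket_count,
    per_seq_bucket_sizes = table(vapply(assigns, length, 0L)),
    gap = gap,
    pass = length(close_s) == 0L && length(far_s) == 0L
  ), class = "lsb_sensitivity_report")
}

#' @export
print.lsb_sensitivity_report <- function(x, ...) {
  cat(sprintf("<lsb_sensitivity_report> scheme %s, n = %d, m = %d\n",
              x$scheme$name, x$n, x$alphabet$m))
  cat(sprintf("  claimed (d1, d2) = (%d, %d): %s\n", x$claimed_d1,
              x$claimed_d2, if (x$pass) "PASS" else "FAIL"))
  cat(sprintf("  pairs checked: %d; |B| = %g; |f(s)| sizes: %s\n",
              x$checked_pairs, x$bucket_count,
              paste(sprintf("%s x%d", names(x$per_seq_bucket_sizes),
                            as.integer(x$per_seq_bucket_sizes)),
                    collapse = ", ")))
  if (nrow(x$close_violations) > 0L) {
    cat(sprintf("  close violations (edit <= %d, disjoint buckets): %d, e.g. %s / %s\n",
                x$claimed_d1, nrow(x$close_violations),
                x$close_violations$s[1L], x$close_violations$t[1L]))
  }
  if (nrow(x$far_violations) > 0L) {
    cat(sprintf("  far violations (edit >= %d, shared bucket): %d, e.g. %s / %s\n",
                x$claimed_d2, nrow(x$far_violations),
                x$far_violations$s[1L], x$far_violations$t[1L]))
  }
  if (nrow(x$gap) > 0L) {
    for (g in seq_len(nrow(x$gap))) {
      cat(sprintf("  gap d = %d: %d / %d pairs collide (%.3f)\n",
                  x$gap$d[g], x$gap$collisions[g], x$gap$pairs[g],
                  x$gap$frequency[g]))
    }
  }
  invisible(x)
}
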