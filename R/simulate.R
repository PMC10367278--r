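#' Random equal-length pair at an exact edit distance
#'
#' Draws `s` uniformly from \eqn{\Sigma^n} and proposes `t` by applying a
#' random edit script with `b` indel pairs and `d - 2b` substitutions at
#' distinct positions (`b` uniform on \eqn{0..\lfloor d/2 \rfloor}),
#' re-drawing until the pair verifies at exactly edit distance `d` by the
#' distance DP. Uses R's global RNG stream; seed it (or wrap the call in
#' [withr::with_seed()]) for reproducibility.
#'
#' @inheritParams all_sequences
#' @param d Target edit distance, 0 <= d <= n.
#' @param with_category Also compute the edit-type category of the pair.
#' @param max_tries Rejection rounds before giving up.
#' @return A list with `s`, `t`, `d`, and (optionally) `category`.
#' @examples
#' set.seed(1)
#' sample_pair_at_distance(10, 3, dna_alphabet())
#' @export
sample_pair_at_distance <- function(n, d, alphabet, with_category = FALSE,
                                    max_tries = 10000L) {
  alphabet <- as_alphabet(alphabet)
  if (d < 0 || d > n) stop("`d` must satisfy 0 <= d <= n")
  chars <- alphabet$chars
  m <- alphabet$m
  for (try in seq_len(max_tries)) {
    sch <- sample(chars, n, replace = TRUE)
    s <- paste(sch, collapse = "")
    if (d == 0L) {
      out <- list(s = s, t = s, d = 0L)
      if (with_category) out$category <- 0L
      return(out)
    }
    b <- sample.int(d %/% 2L + 1L, 1L) - 1L
    tch <- sch
    if (b > 0L) {
      tch <- tch[-sample.int(length(tch), b)]
      for (k in seq_len(b)) {
        tch <- append(tch, sample(chars, 1L),
                      after = sample.int(length(tch) + 1L, 1L) - 1L)
      }
    }
    nsub <- d - 2L * b
    if (nsub > 0L) {
      pos <- sample.int(n, nsub)
      for (p in pos) tch[p] <- sample(setdiff(chars, tch[p]), 1L)
    }
    t <- paste(tch, collapse = "")
    if (utils::adist(s, t)[1L, 1L] == d) {
      out <- list(s = s, t = t, d = as.integer(d))
      if (with_category) out$category <- edit_type_category(s, t, alphabet)
      return(out)
    }
  }
  stop(sprintf("could not sample a pair at exact edit distance %d for n = %d after %d tries",
               d, n, max_tries))
}

# Collision decision with the pair's distance already known. Far pairs
# (d >= 2r + 1) are decided by the triangle inequality; otherwise the
# actual bucket intersection is computed.
share_bucket_at <- function(s, t, d, scheme, alphabet) {
  if (scheme$kind == "lsb12") {
    return(length(intersect(buckets_of(s, alphabet),
                            buckets_of(t, alphabet))) > 0L)
  }
  r <- scheme$r
  if (d >= 2L * r + 1L) return(FALSE)
  # candidates are within r of s by construction (each carries at most r
  # edit operations), so only the t side and membership need checking
  cand <- neighborhood_candidates(s, r, alphabet)
  if (scheme$kind == "partition") {
    cand <- cand[partition_index(cand, alphabet) == scheme$index]
  }
  any(edit_distance_many(t, cand) <= r)
}

#' Collision-frequency experiment over random pairs
#'
#' For each edit distance in `distances`, samples `pairs_per_d` random
#' length-`n` pairs at exactly that distance and records, per scheme, the
#' fraction that share at least one bucket. For distances inside a
#' scheme's gap \eqn{(d_1, d_2)} the frequencies are additionally broken
#' down by edit-type category, labeled `"a+bx2"` (a substitutions plus b
#' indel pairs). Frequencies at \eqn{d \le d_1} are provably 1 and at
#' \eqn{d \ge d_2} provably 0 for every scheme; any deviation is a defect,
#' not sampling noise.
#'
#' Only the O(n) bucket-id formula, the O(n) membership query and
#' radius-r neighborhood enumeration are used, never the exponential
#' builders, so `n` can be realistic read-window sizes (default 20).
#'
#' @inheritParams all_sequences
#' @param distances Integer vector of exact edit distances.
#' @param pairs_per_d Number of random pairs per distance.
#' @param schemes List of [lsb_scheme()] objects; the default is the three
#'   gapped schemes full r=1, partition r=1 and partition r=2.
#' @param seed Integer seed; sampling is fully reproducible given it.
#' @param category_breakdown Add per-category rows at gap distances.
#' @return A data frame with columns `scheme`, `n`, `d`, `category`
#'   (`"ALL"` or an `"a+bx2"` label), `pairs`, `collisions`, `frequency`;
#'   the seed is attached as attribute `"seed"`.
#' @examples
#' tab <- run_experiment(n = 12, distances = 1:3, pairs_per_d = 25, seed = 7)
#' subset(tab, category == "ALL")
#' @export
run_experiment <- function(n = 20, distances = 1:6, pairs_per_d = 2000,
                           schemes = NULL, seed = 1,
                           alphabet = dna_alphabet(),
                           category_breakdown = TRUE) {
  alphabet <- as_alphabet(alphabet)
  if (is.null(schemes)) {
    schemes <- list(lsb_scheme("full", r = 1),
                    lsb_scheme("partition", r = 1),
                    lsb_scheme("partition", r = 2))
  }
  stopifnot(pairs_per_d >= 1, all(distances >= 1))
  rows <- list()
  withr::with_seed(as.integer(seed), {
    for (d in distances) {
      pairs <- replicate(pairs_per_d,
                         sample_pair_at_distance(n, d, alphabet),
                         simplify = FALSE)
      need_cat <- category_breakdown &&
        any(vapply(schemes, function(sc)
          d > sc$claimed_d1 && d < sc$claimed_d2, TRUE))
      cats <- if (need_cat) {
        vapply(pairs, function(p)
          edit_type_category(p$s, p$t, alphabet), 0L)
      } else NULL
      for (sc in schemes) {
        coll <- vapply(pairs, function(p)
          share_bucket_at(p$s, p$t, d, sc, alphabet), TRUE)
        rows[[length(rows) + 1L]] <- data.frame(
          scheme = sc$name, n = as.integer(n), d = as.integer(d),
          category = "ALL", pairs = as.integer(pairs_per_d),
          collisions = sum(coll), frequency = mean(coll))
        if (need_cat && d > sc$claimed_d1 && d < sc$claimed_d2) {
          for (i in sort(unique(cats))) {
            sel <- cats == i
            rows[[length(rows) + 1L]] <- data.frame(
              scheme = sc$name, n = as.integer(n), d = as.integer(d),
              category = sprintf("%d+%dx2", d - 2L * i, i),
              pairs = sum(sel), collisions = sum(coll[sel]),
              frequency = mean(coll[sel]))
          }
        }
      }
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "seed") <- as.integer(seed)
  out
}
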