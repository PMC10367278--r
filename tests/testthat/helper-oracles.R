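# Independent oracles and printed reference tables used across the tests.
# The oracles deliberately share no code with the package implementation.

# Plain textbook Levenshtein DP, written independently of utils::adist.
oracle_edit <- function(s, t) {
  a <- strsplit(s, "")[[1]]
  b <- strsplit(t, "")[[1]]
  la <- length(a); lb <- length(b)
  D <- matrix(0L, la + 1L, lb + 1L)
  D[, 1L] <- 0:la
  D[1L, ] <- 0:lb
  for (i in seq_len(la)) {
    for (j in seq_len(lb)) {
      D[i + 1L, j + 1L] <- min(D[i, j] + (a[i] != b[j]),
                               D[i, j + 1L] + 1L,
                               D[i + 1L, j] + 1L)
    }
  }
  D[la + 1L, lb + 1L]
}

# Brute-force neighborhood: filter the whole space by the oracle DP.
oracle_neighborhood <- function(s, r, alphabet) {
  space <- all_sequences(nchar(s), alphabet)
  sort(space[vapply(space, oracle_edit, 0L, s = s) <= r])
}

# Total sigma_1 occurrences among sequences lexicographically before t,
# by direct enumeration of the space.
oracle_count_sigma1 <- function(t, alphabet) {
  space <- all_sequences(nchar(t), alphabet)
  before <- space[seq_len(match(t, space) - 1L)]
  if (length(before) == 0L) return(0)
  sum(vapply(strsplit(before, ""), function(ch)
    sum(ch == alphabet$chars[1L]), 0))
}

# Is t reachable from s with exactly i deletions, i insertions and at most
# smax substitutions? Brute force over deletion sets and insertions.
oracle_has_script <- function(s, t, i, smax, alphabet) {
  sch <- strsplit(s, "")[[1]]
  tch <- strsplit(t, "")[[1]]
  n <- length(sch)
  if (i == 0L) return(sum(sch != tch) <= smax)
  grow <- function(core, left) {
    if (left == 0L) return(list(core))
    out <- list()
    for (pos in 0:length(core)) for (c0 in alphabet$chars) {
      out <- c(out, grow(append(core, c0, after = pos), left - 1L))
    }
    out
  }
  for (del in utils::combn(n, i, simplify = FALSE)) {
    for (v in grow(sch[-del], i)) {
      if (sum(v != tch) <= smax) return(TRUE)
    }
  }
  FALSE
}

oracle_category <- function(s, t, alphabet) {
  d <- oracle_edit(s, t)
  if (d == 0L) return(0L)
  for (i in 0:(d %/% 2L)) {
    if (oracle_has_script(s, t, i, d - 2L * i, alphabet)) return(i)
  }
  stop("oracle found no category")
}

# ---- printed reference tables ------------------------------------------

# The complete n = 2, DNA worked example of the (1,2)-sensitive
# construction: bucket ids per sequence and contents per bucket.
ref_f_table <- list(
  AA = c(1, 2), AC = c(2, 3), AG = c(2, 4), AT = c(2, 5),
  CA = c(1, 6), CC = c(3, 6), CG = c(4, 6), CT = c(5, 6),
  GA = c(1, 7), GC = c(3, 7), GG = c(4, 7), GT = c(5, 7),
  TA = c(1, 8), TC = c(3, 8), TG = c(4, 8), TT = c(5, 8))

ref_bucket_contents <- list(
  c("AA", "CA", "GA", "TA"), c("AA", "AC", "AG", "AT"),
  c("AC", "CC", "GC", "TC"), c("AG", "CG", "GG", "TG"),
  c("AT", "CT", "GT", "TT"), c("CA", "CC", "CG", "CT"),
  c("GA", "GC", "GG", "GT"), c("TA", "TC", "TG", "TT"))

# The reference 4-block partitions of the length-2 and length-3 DNA spaces.
ref_B2 <- list(
  c("AA", "CC", "GG", "TT"),
  c("AC", "CG", "GT", "TA"),
  c("AG", "CT", "GA", "TC"),
  c("AT", "CA", "GC", "TG"))

ref_B3 <- list(
  c("AAA", "ACC", "AGG", "ATT", "CAC", "CCG", "CGT", "CTA",
    "GAG", "GCT", "GGA", "GTC", "TAT", "TCA", "TGC", "TTG"),
  c("AAC", "ACG", "AGT", "ATA", "CAG", "CCT", "CGA", "CTC",
    "GAT", "GCA", "GGC", "GTG", "TAA", "TCC", "TGG", "TTT"),
  c("AAG", "ACT", "AGA", "ATC", "CAT", "CCA", "CGC", "CTG",
    "GAA", "GCC", "GGG", "GTT", "TAC", "TCG", "TGT", "TTA"),
  c("AAT", "ACA", "AGC", "ATG", "CAA", "CCC", "CGG", "CTT",
    "GAC", "GCG", "GGT", "GTA", "TAG", "TCT", "TGA", "TTC"))

write_fasta <- function(records, path) {
  lines <- unlist(lapply(names(records), function(id) {
    sq <- records[[id]]
    # wrap at 10 columns to exercise multi-line records
    c(paste0(">", id),
      substring(sq, seq(1, nchar(sq), 10), pmin(seq(10, nchar(sq) + 9, 10), nchar(sq))))
  }))
  writeLines(lines, path)
  path
}
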