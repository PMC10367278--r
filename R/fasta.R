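#' Extract length-n windows from a FASTA file
#'
#' Reads a (possibly multi-record, line-wrapped) FASTA file and yields
#' every `step`-strided length-`n` window whose symbols all lie in the
#' alphabet. Input is case-folded to upper case; windows containing any
#' other symbol (e.g. ambiguity codes such as `N`) are skipped, and the
#' skip count is reported on standard error. Coordinates are 0-based,
#' half-open: window `[offset, offset + n)`. Forward strand only; no
#' reverse-complement canonicalization (the bucketing functions are not
#' reverse-complement symmetric).
#'
#' @param path Path to a FASTA file.
#' @inheritParams all_sequences
#' @param step Stride between window starts (>= 1).
#' @return Data frame with columns `record_id` (first token of the
#'   header), `offset` (0-based) and `window`, in input order then offset.
#' @export
extract_windows <- function(path, n, alphabet, step = 1L) {
  alphabet <- as_alphabet(alphabet)
  if (n < 1L) stop("`n` must be >= 1")
  if (step < 1L) stop("`step` must be >= 1")
  recs <- tryCatch(Biostrings::readBStringSet(path),
                   error = function(e)
                     stop(sprintf("cannot read FASTA '%s': %s",
                                  path, conditionMessage(e))))
  empty <- data.frame(record_id = character(0), offset = integer(0),
                      window = character(0))
  if (length(recs) == 0L) {
    warning(sprintf("FASTA '%s' contains no records", path))
    return(empty)
  }
  ids <- vapply(strsplit(names(recs), "\\s+"), `[[`, "", 1L)
  valid_re <- paste0("^[", paste(alphabet$chars, collapse = ""), "]+$")
  out <- vector("list", length(recs))
  skipped <- 0L
  for (ri in seq_along(recs)) {
    sq <- toupper(as.character(recs[[ri]]))
    len <- nchar(sq)
    if (len < n) next
    offsets <- seq.int(0L, len - n, by = step)
    windows <- substring(sq, offsets + 1L, offsets + n)
    ok <- grepl(valid_re, windows)
    skipped <- skipped + sum(!ok)
    out[[ri]] <- data.frame(record_id = ids[ri],
                            offset = as.integer(offsets[ok]),
                            window = windows[ok])
  }
  res <- do.call(rbind, c(out, list(empty)))
  rownames(res) <- NULL
  message(sprintf("extract_windows: %d window(s) kept, %d skipped (non-alphabet symbols), %d record(s)",
                  nrow(res), skipped, length(recs)))
  res
}

#' Bucket the windows of a FASTA file
#'
#' Runs [extract_windows()] and assigns every window its bucket labels
#' under a scheme. Labels are serialized as a comma-joined, sorted list:
#' numeric ids for the `"lsb12"` scheme, sequence labels otherwise.
#'
#' @inheritParams extract_windows
#' @param scheme An [lsb_scheme()].
#' @return Data frame with columns `record_id`, `offset`, `window`,
#'   `scheme`, `buckets`.
#' @export
bucket_fasta <- function(path, n, scheme, alphabet, step = 1L) {
  alphabet <- as_alphabet(alphabet)
  stopifnot(inherits(scheme, "lsb_scheme"))
  win <- extract_windows(path, n, alphabet, step)
  win$scheme <- rep(scheme$name, nrow(win))
  win$buckets <- vapply(win$window, function(w) {
    b <- assign_buckets(w, scheme, alphabet)
    paste(sort(b), collapse = ",")
  }, "", USE.NAMES = FALSE)
  win
}
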