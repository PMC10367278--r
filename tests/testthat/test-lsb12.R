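dna <- dna_alphabet()
bin <- binary_alphabet()

test_that("global-counter construction reproduces the reference n=2 table", {
  bt <- build_global(2, dna)
  for (s in names(ref_f_table)) {
    expect_identical(sort(bt$seq_to_buckets[[s]]), ref_f_table[[s]])
  }
  for (b in seq_along(ref_bucket_contents)) {
    expect_identical(sort(bt$bucket_to_seqs[[b]]), ref_bucket_contents[[b]])
  }
  expect_length(bt$bucket_to_seqs, 8L)
})

test_that("n = 1 collapses to a single bucket holding the whole alphabet", {
  bt <- build_global(1, dna)
  expect_length(bt$bucket_to_seqs, 1L)
  expect_identical(sort(bt$bucket_to_seqs[[1]]), dna$chars)
  for (s in dna$chars) expect_identical(buckets_of(s, dna), 1)
})

test_that("lexicographic rank is the base-m encoding", {
  expect_identical(lex_rank("", dna), 0)
  expect_identical(lex_rank("T", dna), 3)
  seqs <- all_sequences(2, dna)   # sorted: rank is position - 1
  for (i in seq_along(seqs)) {
    expect_identical(lex_rank(seqs[i], dna), i - 1)
  }
})

test_that("count of sigma_1 before a sequence matches direct enumeration", {
  expect_identical(count_sigma1_before("AA", dna), 0)
  expect_identical(count_sigma1_before("AT", dna), 4)
  expect_identical(count_sigma1_before("CA", dna), 5)
  for (t in all_sequences(2, dna)) {
    expect_identical(count_sigma1_before(t, dna), oracle_count_sigma1(t, dna))
  }
  for (t in all_sequences(3, dna)) {
    expect_identical(count_sigma1_before(t, dna), oracle_count_sigma1(t, dna))
  }
  for (t in all_sequences(4, bin)) {
    expect_identical(count_sigma1_before(t, bin), oracle_count_sigma1(t, bin))
  }
})

test_that("O(n) bucket formula agrees with the global-counter oracle", {
  expect_identical(sort(buckets_of("AT", dna)), c(2, 5))
  expect_identical(sort(buckets_of("AA", dna)), c(1, 2))
  for (cfg in list(list(3L, dna), list(4L, bin))) {
    bt <- build_global(cfg[[1]], cfg[[2]])
    for (s in names(bt$seq_to_buckets)) {
      expect_identical(sort(buckets_of(s, cfg[[2]])),
                       sort(bt$seq_to_buckets[[s]]))
    }
  }
})

test_that("bucket table invariants hold", {
  for (cfg in list(list(3L, dna), list(5L, bin))) {
    n <- cfg[[1]]; a <- cfg[[2]]; m <- a$m
    bt <- build_global(n, a)
    expect_length(bt$bucket_to_seqs, n * m^(n - 1))
    sizes <- lengths(bt$bucket_to_seqs)
    expect_true(all(sizes == m))                 # every bucket holds m seqs
    expect_true(all(lengths(bt$seq_to_buckets) == n))
    expect_identical(sum(sizes), as.integer(n * m^n))  # double counting
    # the two maps are mutually consistent
    for (b in seq_along(bt$bucket_to_seqs)) {
      for (s in bt$bucket_to_seqs[[b]]) {
        expect_true(b %in% bt$seq_to_buckets[[s]])
      }
    }
  }
})

test_that("exponential builder and exact arithmetic refuse out-of-range n", {
  expect_error(build_global(12, dna), "cap")
  expect_error(buckets_of(strrep("A", 30), dna), "2\\^53")
  # n = 20 (the simulation scale) is exact and fine
  expect_length(buckets_of(strrep("ACGT", 5), dna), 20L)
})
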