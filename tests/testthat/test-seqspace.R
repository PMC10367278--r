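dna <- dna_alphabet()
bin <- binary_alphabet()

test_that("edit distance is a metric on the exhaustive binary length-3 space", {
  space <- all_sequences(3, bin)
  D <- outer(space, space,
             Vectorize(function(a, b) edit_distance(a, b, bin)))
  expect_true(all(diag(D) == 0))
  expect_true(all(D[D > 0 | t(D) > 0] > 0))          # zero iff equal
  expect_identical(D, t(D))                          # symmetry
  for (i in seq_along(space)) {
    # triangle inequality, all triples through i
    expect_true(all(outer(D[, i], D[i, ], `+`) >= D))
  }
  # agreement with the independent DP oracle on every pair
  O <- outer(space, space, Vectorize(oracle_edit))
  expect_identical(D, O)
})

test_that("edit distance examples and alphabet validation", {
  expect_identical(edit_distance("AA", "AA", dna), 0L)
  expect_identical(edit_distance("AT", "CT", dna), 1L)
  # no single edit turns AC into CA (checked by the full DP oracle)
  expect_identical(oracle_edit("AC", "CA"), 2L)
  expect_identical(edit_distance("AC", "CA", dna), 2L)
  expect_error(edit_distance("AN", "AA", dna), "outside the alphabet")
  expect_error(edit_distance("AA", "A0", dna), "outside the alphabet")
})

test_that("neighborhood equals brute-force filtering of the space", {
  for (a in list(bin, dna)) {
    for (n in 2:4) {
      set.seed(100 * a$m + n)
      pick <- sample(all_sequences(n, a), min(4L, a$m^n))
      for (r in 0:2) {
        for (s in pick) {
          expect_identical(neighborhood(s, r, a), oracle_neighborhood(s, r, a))
        }
      }
    }
  }
})

test_that("radius-1 neighborhood size is (m-1)n + 1 for every sequence", {
  for (a in list(bin, dna)) {
    for (n in c(2L, 3L)) {
      sizes <- vapply(all_sequences(n, a),
                      function(s) length(neighborhood(s, 1, a)), 0L)
      expect_true(all(sizes == (a$m - 1L) * n + 1L))
    }
  }
  expect_identical(neighborhood("AA", 0, dna), "AA")
  expect_identical(length(neighborhood("AC", 1, dna)), 7L)
})

test_that("edit-type category matches its definition", {
  # two substitutions: Hamming distance equals edit distance
  expect_identical(edit_type_category("AAAA", "CCAA", dna), 0L)
  # d = 2 but Hamming 4: one indel pair (shift by one)
  expect_identical(edit_type_category("ACGT", "CGTA", dna), 1L)
  expect_identical(oracle_category("ACGT", "CGTA", dna), 1L)
  expect_identical(edit_type_category("AA", "AA", dna), 0L)

  # exhaustive small space: bounds, symmetry, the category-0 criterion,
  # and agreement with the brute-force script oracle
  space <- all_sequences(4, bin)
  for (s in space) {
    sch <- strsplit(s, "")[[1]]
    for (t in space) {
      d <- edit_distance(s, t, bin)
      i <- edit_type_category(s, t, bin)
      expect_lte(i, d %/% 2)
      expect_identical(i, edit_type_category(t, s, bin))
      h <- sum(sch != strsplit(t, "")[[1]])
      expect_identical(i == 0L, h == d)
    }
  }
  set.seed(7)
  for (k in 1:25) {
    p <- sample_pair_at_distance(5, sample(1:4, 1), dna)
    expect_identical(edit_type_category(p$s, p$t, dna),
                     oracle_category(p$s, p$t, dna))
  }
})
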