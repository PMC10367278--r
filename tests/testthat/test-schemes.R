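dna <- dna_alphabet()
bin <- binary_alphabet()

test_that("registry schemes carry their proved sensitivity pairs", {
  reg <- scheme_registry()
  claimed <- lapply(reg, function(s) c(s$claimed_d1, s$claimed_d2))
  expect_identical(claimed[["lsb12"]], c(1L, 2L))
  expect_identical(claimed[["full-r1"]], c(1L, 3L))      # odd r: 2r-1
  expect_identical(claimed[["full-r2"]], c(4L, 5L))      # even r: 2r
  expect_identical(claimed[["full-r3"]], c(5L, 7L))
  expect_identical(claimed[["partition-r1-i1"]], c(1L, 3L))
  expect_identical(claimed[["partition-r2-i1"]], c(3L, 5L))
  expect_identical(claimed[["partition-r3-i1"]], c(3L, 7L))
  expect_true(all(vapply(reg, function(s) s$claimed_d1 < s$claimed_d2, TRUE)))
  expect_error(lsb_scheme("lsb12", r = 1), "does not apply")
  expect_error(lsb_scheme("partition", r = 0), ">= 1")
})

test_that("bucket assignment follows the scheme definition", {
  # members of a block map to themselves only at r = 1
  expect_identical(assign_buckets("AA", lsb_scheme("partition", r = 1), dna),
                   "AA")
  # non-members map to their n in-block substitution neighbors
  expect_identical(assign_buckets("AC", lsb_scheme("partition", r = 1), dna),
                   c("AA", "CC"))
  expect_identical(assign_buckets("GT", lsb_scheme("full", r = 0), dna), "GT")
  expect_identical(assign_buckets("AT", lsb_scheme("lsb12"), dna),
                   buckets_of("AT", dna))
  expect_identical(assign_buckets("ACG", lsb_scheme("full", r = 1), dna),
                   neighborhood("ACG", 1, dna))
})

test_that("share_bucket matches the enumeration definition on random pairs", {
  set.seed(11)
  schemes <- list(lsb_scheme("lsb12"), lsb_scheme("full", r = 1),
                  lsb_scheme("partition", r = 1),
                  lsb_scheme("partition", r = 2, index = 3))
  for (k in 1:60) {
    p <- sample_pair_at_distance(8, sample(0:6, 1), dna)
    for (sc in schemes) {
      by_def <- length(intersect(assign_buckets(p$s, sc, dna),
                                 assign_buckets(p$t, sc, dna))) > 0
      expect_identical(share_bucket(p$s, p$t, sc, dna), by_def)
      expect_identical(share_bucket(p$s, p$t, sc, dna, shortcut = FALSE),
                       by_def)
    }
  }
  # s = t shares for every scheme (f(s) is never empty)
  for (sc in schemes) expect_true(share_bucket("ACGTACGT", "ACGTACGT", sc, dna))
})

test_that("registry schemes pass exhaustive verification", {
  for (cfg in list(list(3L, dna), list(4L, bin))) {
    n <- cfg[[1]]; a <- cfg[[2]]
    for (sc in scheme_registry()[c("lsb12", "full-r1", "full-r2",
                                   "partition-r1-i1", "partition-r2-i1")]) {
      rep <- verify_sensitivity(n, a, sc)
      expect_true(rep$pass)
    }
  }
  rep <- verify_sensitivity(3, dna, lsb_scheme("lsb12"))
  expect_identical(rep$bucket_count, 48L)          # n * m^(n-1)
  expect_identical(names(rep$per_seq_bucket_sizes), "3")
})

test_that("the distance-2 gap of full r=1 splits by edit type", {
  # claiming (2,3) must fail: pure indel-pair neighbors at distance 2
  # have disjoint radius-1 neighborhoods
  bad <- verify_sensitivity(3, dna, lsb_scheme("full", r = 1),
                            claimed_d1 = 2, claimed_d2 = 3)
  expect_false(bad$pass)
  expect_gt(nrow(bad$close_violations), 0)
  expect_true(all(bad$close_violations$d == 2))
  cats <- mapply(edit_type_category, bad$close_violations$s,
                 bad$close_violations$t, MoreArgs = list(alphabet = dna))
  expect_true(all(cats == 1L))                     # all pure indel pairs
  # while two-substitution pairs at distance 2 do share buckets
  ok <- verify_sensitivity(3, dna, lsb_scheme("full", r = 1))
  expect_true(ok$gap$frequency[ok$gap$d == 2] > 0)
  expect_true(ok$gap$frequency[ok$gap$d == 2] < 1)
})

test_that("full-scheme assignments grow monotonically with the radius", {
  set.seed(5)
  for (s in replicate(5, paste(sample(dna$chars, 4, TRUE), collapse = ""))) {
    for (r in 0:2) {
      expect_true(all(assign_buckets(s, lsb_scheme("full", r = r), dna) %in%
                      assign_buckets(s, lsb_scheme("full", r = r + 1), dna)))
    }
  }
})
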