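test_that("exact substring reads produce a single perfect hit", {
  db <- toy_db()
  ref <- db$sequences$sequence[1L]
  read <- substr(ref, 101, 150)
  hits <- align_read(read, db)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$ref_id, "refA1a")
  expect_identical(hits$strand, "+")
  expect_equal(hits$identity, 1)
  expect_identical(hits$score, 50L)        # L * match
  expect_identical(hits$gaps, 0L)
  expect_identical(hits$ref_aligned, read)
})

test_that("a substituted base surfaces as one positioned mismatch", {
  db <- toy_db()
  ref <- db$sequences$sequence[2L]
  clean <- substr(ref, 51, 110)            # L = 60
  read <- mutate_at(clean, 30L)
  hits <- align_read(read, db)
  expect_identical(nrow(hits), 1L)
  expect_equal(hits$identity, 59 / 60)
  expect_identical(hits$score, as.integer(semiglobal_score_oracle(read, ref)))
  mm <- mismatch_table(hits)
  expect_identical(nrow(mm), 1L)
  expect_identical(mm$read_pos, 29L)       # 0-based from the 5' end
  expect_identical(mm$ref_base, substr(clean, 30, 30))
  expect_identical(mm$read_base, substr(read, 30, 30))
})

test_that("reads sharing no k-mer with any reference yield no hits", {
  db <- toy_db()
  with_seed(8L, {
    for (i in 1:20) {
      read <- random_dna(1, 40)
      # a random 40-mer essentially never shares a 12-mer with 1.2 kb
      hits <- align_read(read, db)
      if (nrow(hits) > 0L) {
        # if a chance seed exists the hit must still be a genuine DP result
        expect_true(all(hits$score <= 40L))
      }
    }
  })
  expect_warning(short <- align_read("ACGTACGT", db), "seed length")
  expect_identical(nrow(short), 0L)
})

test_that("minus-strand hits report mismatches in read orientation", {
  db <- toy_db()
  ref <- db$sequences$sequence[1L]
  # pick a window whose reverse complement starts with C (ref base G)
  b <- 200L + regexpr("G", substr(ref, 201, 320), fixed = TRUE)
  frag <- rev_comp(substr(ref, b - 59L, b))  # minus-strand molecule, L = 60
  expect_identical(substr(frag, 1, 1), "C")
  read <- paste0("T", substr(frag, 2, 60))   # deaminated 5' terminus
  hits <- align_read(read, db)
  expect_identical(hits$strand[1L], "-")
  mm <- mismatch_table(hits[1L, ])
  expect_identical(mm$read_pos, 0L)
  expect_identical(mm$ref_base, "C")       # complemented into read frame
  expect_identical(mm$read_base, "T")
})

test_that("seed-and-extend equals the exhaustive full-DP oracle", {
  tree <- toy_tree()
  with_seed(9L, {
    db <- reference_db(data.frame(
      ref_id = sprintf("r%02d", 1:8),
      taxon_id = rep(c(30L, 21L, 22L, 20L), 2L),
      marker = rep(c("SSU", "LSU"), each = 4L),
      sequence = random_dna(8, 250),
      stringsAsFactors = FALSE), tree)
    for (i in 1:60) {
      src <- sample(8L, 1L)
      L <- sample(36:80, 1L)
      a <- sample(250L - L + 1L, 1L)
      read <- substr(db$sequences$sequence[src], a, a + L - 1L)
      read <- mutate_at(read, sample(L, sample(0:2, 1L)))
      if (runif(1) < 0.5) read <- rev_comp(read)
      hits <- align_read(read, db)
      expect_gt(nrow(hits), 0L)
      oracle <- max(exhaustive_best_score(read, db),
                    exhaustive_best_score(rev_comp(read), db))
      expect_identical(hits$score[1L], as.integer(oracle))
    }
  })
})

test_that("hit filtering applies the identity cut and score window", {
  h <- function(score, identity, ref_id) {
    data.frame(ref_id = ref_id, taxon_id = 30L, marker = "SSU",
               strand = "+", score = score, columns = 100L,
               matches = as.integer(identity * 100), n_mismatch = 0L,
               gaps = 0L, identity = identity, ref_aligned = "",
               read_seq = "", stringsAsFactors = FALSE)
  }
  expect_identical(nrow(filter_hits(h(100L, 0.94, "a"))), 0L)   # identity cut
  three <- rbind(h(100L, 1, "a"), h(91L, 1, "b"), h(89L, 1, "c"))
  kept <- filter_hits(three)
  expect_identical(kept$ref_id, c("a", "b"))                    # 90 threshold
  expect_identical(nrow(filter_hits(three[0L, ])), 0L)
})

test_that("alignment invariants hold on simulated batches", {
  cfg <- simulation_config(seed = 31L, library_size = 150L)
  sim <- simulate_core(cfg)
  hits <- align_reads(sim$reads[1:300, ], sim$reference)
  expect_identical(hits$matches + hits$n_mismatch + hits$gaps, hits$columns)
  expect_true(all(hits$identity >= 0 & hits$identity <= 1))
  expect_identical(nchar(hits$ref_aligned), nchar(hits$read_seq))
})
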