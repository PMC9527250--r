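# build a best-hit table directly from (read, aligned-reference) string
# pairs: gap-free alignments unless the ref string carries '-'
mk_hits <- function(read_seq, ref_aligned, sample_id = "S1",
                    taxon_id = 30L) {
  n <- length(read_seq)
  gaps <- vapply(strsplit(ref_aligned, ""), function(a) sum(a == "-"),
                 integer(1))
  matches <- mapply(function(r, a) {
    rr <- strsplit(r, "")[[1]]; aa <- strsplit(a, "")[[1]]
    sum(aa != "-" & aa == rr)
  }, read_seq, ref_aligned)
  columns <- nchar(read_seq)
  data.frame(read_id = sprintf("r%03d", seq_len(n)),
             sample_id = rep_len(sample_id, n),
             taxon_id = rep_len(taxon_id, n),
             identity = as.integer(matches) / columns, gaps = gaps,
             columns = columns, matches = as.integer(matches),
             read_seq = read_seq, ref_aligned = ref_aligned,
             stringsAsFactors = FALSE)
}

test_that("substitution spectra count positional deamination frequencies", {
  clean <- random_dna(10, 40, seed = 50L)
  # force reference C at position 1 everywhere; one read shows T
  ref <- paste0("C", substr(clean, 2, 40))
  reads <- ref
  reads[1] <- paste0("T", substr(ref[1], 2, 40))
  sp <- substitution_spectrum(mk_hits(reads, ref))
  expect_equal(sp$f5[1L], 0.1)
  expect_identical(sp$n5[1L], 10L)

  perfect <- substitution_spectrum(mk_hits(clean, clean))
  expect_true(all(perfect$f5[perfect$n5 > 0] == 0))
  expect_true(all(perfect$f3[perfect$n3 > 0] == 0))
  expect_equal(perfect$background, 0)
})

test_that("spectra recover the generating decay model without an aligner", {
  n <- 20000L
  frags <- random_dna(n, 60, seed = 51L)
  with_seed(52L, {
    dmg <- sedapipe:::.damage_batch(frags, rep(0.3, n), r = 0.5, eps = 0)
  })
  hits <- mk_hits(unname(dmg$sequence), frags)
  sp <- substitution_spectrum(hits)
  expect_lt(abs(sp$f5[1L] - 0.30), 0.01)
  expect_lt(abs(sp$f5[2L] / sp$f5[1L] - 0.50), 0.05)
  expect_lt(abs(sp$f3[1L] - 0.30), 0.01)

  fit <- fit_decay(sp)
  expect_lt(abs(fit$d_hat - 0.3), 0.02)
  expect_lt(abs(fit$r_hat - 0.5), 0.05)
  expect_lt(fit$eps_hat, 0.005)
})

test_that("read classification gates on substitution type and position", {
  clean <- random_dna(1, 40, seed = 53L)
  ref <- paste0("CA", substr(clean, 3, 40))
  perfect <- mk_hits(ref, ref)
  expect_identical(classify_read(perfect)$call, "default")

  ct0 <- mk_hits(paste0("TA", substr(ref, 3, 40)), ref)
  expect_identical(classify_read(ct0)$call, "ancient")
  expect_identical(classify_read(ct0)$n_evidence, 1L)

  # A -> G at interior position 2 is not a deamination signature
  ref_ag <- paste0("CAA", substr(clean, 4, 40))
  ag <- mk_hits(paste0("CAG", substr(ref_ag, 4, 40)), ref_ag)
  expect_identical(classify_read(ag)$call, "default")

  # G -> A within the 3' window is
  ref_ga <- paste0(substr(clean, 1, 38), "GA")
  ga <- mk_hits(paste0(substr(ref_ga, 1, 38), "AA"), ref_ga)
  expect_identical(classify_read(ga)$call, "ancient")

  # low identity fails the stringent gate
  low <- mk_hits(mutate_at(ref, 5:12), ref)
  expect_identical(classify_read(low)$call, "rejected")
})

test_that("damage proportions are grouped, flagged and order-invariant", {
  calls <- data.frame(
    read_id = sprintf("r%d", 1:11),
    sample_id = "A",
    taxon_id = c(rep(30L, 10L), 21L),
    call = c(rep("ancient", 3L), rep("default", 7L), "ancient"),
    stringsAsFactors = FALSE)
  s <- damage_proportion(calls)
  expect_equal(s$proportion[s$taxon_id == "30"], 0.30)
  expect_true(s$low_confidence[s$taxon_id == "30"])
  expect_equal(s$proportion[s$taxon_id == "21"], 1.0)   # single-read case
  expect_true(s$low_confidence[s$taxon_id == "21"])

  shuffled <- damage_proportion(calls[sample(11L), ])
  expect_identical(s[order(s$taxon_id), ], shuffled[order(shuffled$taxon_id), ])

  rej <- data.frame(read_id = "r1", sample_id = "A", taxon_id = 30L,
                    call = "rejected", stringsAsFactors = FALSE)
  expect_true(is.na(damage_proportion(rej)$proportion))
})

test_that("decay fitting inverts noiseless spectra and flags degeneracy", {
  exact <- structure(list(
    f5 = 0.3 * 0.5^(0:19), f3 = rep(NA_real_, 20),
    n5 = rep(1000L, 20), n3 = rep(0L, 20), background = 0, m = 20L),
    class = "damage_spectrum")
  fit <- fit_decay(exact)
  expect_lt(abs(fit$d_hat - 0.3), 1e-6)
  expect_lt(abs(fit$r_hat - 0.5), 1e-6)
  expect_lt(fit$eps_hat, 1e-6)

  flat <- exact; flat$f5 <- rep(0.01, 20)
  ffit <- fit_decay(flat)
  expect_lt(abs(ffit$d_hat * 1 + ffit$eps_hat - 0.01), 0.003)
  expect_lt(ffit$rss, 1e-8)

  zero <- exact; zero$f5 <- rep(0, 20)
  zfit <- fit_decay(zero)
  expect_identical(zfit$d_hat, 0)
  expect_true(is.na(zfit$r_hat))
  expect_true(zfit$degenerate)

  sparse <- exact; sparse$f5 <- c(0.1, 0.05, rep(NA_real_, 18))
  expect_error(fit_decay(sparse), "at least 3")
})

test_that("classifier sensitivity matches the closed form; false-ancient rate bounded", {
  n <- 20000L
  frags <- random_dna(n, 56, seed = 54L)
  with_seed(55L, {
    dmg <- sedapipe:::.damage_batch(frags, rep(0.25, n), r = 0.5, eps = 0)
  })
  calls <- classify_reads(mk_hits(unname(dmg$sequence), frags))
  emp <- mean(calls$call == "ancient")
  pred <- mean(classifier_sensitivity(frags, 0.25, 0.5))
  sigma <- sqrt(pred * (1 - pred) / n)
  expect_lt(abs(emp - pred), 3 * sigma)

  # undamaged contaminants: only background errors can fake damage
  eps <- 0.005
  with_seed(56L, {
    und <- sedapipe:::.damage_batch(frags, rep(0, n), r = 0.5, eps = eps)
  })
  calls0 <- classify_reads(mk_hits(unname(und$sequence), frags))
  bound <- 1 - (1 - eps / 3)^10     # 10 terminal positions, eps/3 per type
  expect_lte(mean(calls0$call == "ancient"),
             bound + 3 * sqrt(bound * (1 - bound) / n))
})
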