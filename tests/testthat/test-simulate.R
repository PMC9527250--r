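two_sample_sheet <- function() {
  data.frame(sample_id = c("Y1", "O1"), site = "SITE1",
             depth_mbsf = c(1, 50), age_ka = c(5, 100),
             type = "sample", stringsAsFactors = FALSE)
}

test_that("simulation is deterministic and conserves library sizes", {
  cfg <- simulation_config(seed = 7L, samples = two_sample_sheet(),
                           library_size = 100L,
                           contaminants = contaminant_model(rate = 0))
  sim1 <- simulate_core(cfg)
  sim2 <- simulate_core(cfg)
  expect_identical(nrow(sim1$reads), 200L)
  expect_identical(sim1$reads, sim2$reads)
  expect_identical(sim1$truth_reads, sim2$truth_reads)
  expect_identical(sim1$geochem, sim2$geochem)

  cfg_full <- simulation_config(seed = 8L, library_size = 50L)
  sim <- simulate_core(cfg_full)
  expect_identical(nrow(sim$reads),
                   sum(sim$truth_samples$library_size))
})

test_that("controls and mudline carry only contaminants; rate 0 empties them", {
  cfg <- simulation_config(seed = 9L, library_size = 100L)
  sim <- simulate_core(cfg)
  meta <- sim$truth_samples
  ctl_ids <- meta$sample_id[meta$type != "sample"]
  ctl_truth <- sim$truth_reads[sim$truth_reads$sample_id %in% ctl_ids, ]
  expect_gt(nrow(ctl_truth), 0L)
  expect_true(all(ctl_truth$is_contaminant))
  expect_true(all(ctl_truth$damage_positions == ""))

  cfg0 <- simulation_config(seed = 9L, library_size = 100L,
                            contaminants = contaminant_model(rate = 0))
  sim0 <- simulate_core(cfg0)
  expect_false(any(sim0$reads$sample_id %in% ctl_ids))
})

test_that("terminal damage follows the configured geometric decay", {
  # null damage leaves the fragment untouched
  frag <- random_dna(1, 50, seed = 10L)
  out <- apply_damage(frag, d5 = 0, r = 0.5, eps = 0, seed = 1L)
  expect_identical(out$sequence, frag)
  expect_length(out$damage_positions, 0L)

  # d5 = 1 makes the 5'-terminal C flip certainly
  for (s in 1:10) {
    out <- apply_damage("CCCC", d5 = 1, r = 0.5, eps = 0, seed = s)
    expect_identical(substr(out$sequence, 1, 1), "T")
    expect_true(0L %in% out$damage_positions)
  }

  # Monte-Carlo flip rates at positions 0 and 1 match d5 * r^i
  n <- 100000L
  frags <- rep(strrep("C", 10L), n)
  with_seed(11L, {
    dmg <- sedapipe:::.damage_batch(frags, rep(0.3, n), r = 0.5, eps = 0)
  })
  first <- substr(unname(dmg$sequence), 1, 2)
  p0 <- mean(substr(first, 1, 1) == "T")
  p1 <- mean(substr(first, 2, 2) == "T")
  expect_lt(abs(p0 - 0.300), 0.005)
  expect_lt(abs(p1 - 0.150), 0.005)
})

test_that("fragment lengths honour mode, truncation and spread", {
  # near-degenerate spread collapses on the mode
  tight <- fragment_model(mode = 56, sdlog = 1e-9)
  expect_true(all(simulate_fragment_length(100L, tight, seed = 12L) == 56L))

  lens <- simulate_fragment_length(10000L, fragment_model(), seed = 13L)
  expect_gte(min(lens), 20L)
  expect_true(stats::median(lens) >= 40 && stats::median(lens) <= 80)
  tab <- table(lens)
  mode_hat <- as.integer(names(tab)[which.max(tab)])
  expect_lt(abs(mode_hat - 56L), 10L)

  expect_error(fragment_model(mode = 10), "min_len")
})

test_that("tracer runs support the blanks-zero regime and known separations", {
  sheet <- data.frame(sample_id = sprintf("T%02d", 1:20),
                      stringsAsFactors = FALSE)
  tr <- simulate_tracer_run(tracer_model(), sheet, seed = 14L)
  expect_true(all(tr$run$blanks == 0))

  # blank draws recover the configured mean
  noisy <- tracer_model(n_blanks = 10000L, blanks_zero = FALSE,
                        blank_mean = 0.1, blank_sd = 0.02)
  tr2 <- simulate_tracer_run(noisy, sheet[1, , drop = FALSE], seed = 15L)
  se <- 0.02 / sqrt(10000)
  expect_lt(abs(mean(tr2$run$blanks) - 0.1), 3 * se)

  # constructed separation: all periphery contaminated, none at centre
  sep <- tracer_model(p_periphery = 1, p_centre = 0, periphery_level = 1.2,
                      noise_sd = 0.01)
  tr3 <- simulate_tracer_run(sep, sheet, seed = 16L)
  m <- tr3$run$measurements
  expect_true(all(m$value[m$location == "periphery"] > 1.0))
  expect_true(all(m$value[m$location == "centre"] < 0.2))
  expect_true(all(tr3$truth$class == "periphery"))
})

test_that("geochemistry hits configured correlation targets", {
  driver <- seq(0.03, 0.33, length.out = 500L)
  null_model <- geochem_model(targets = c(ammonium = 0),
                              means = c(ammonium = 0.5),
                              sds = c(ammonium = 0.2))
  g0 <- simulate_geochem(null_model, driver, seed = 17L)
  expect_lt(abs(stats::cor(g0$ammonium, driver)), 0.1)

  exact <- geochem_model(targets = c(ammonium = 1),
                         means = c(ammonium = 0.5), sds = c(ammonium = 0.2))
  g1 <- simulate_geochem(exact, driver, seed = 18L)
  expect_equal(stats::cor(g1$ammonium, driver), 1)

  g <- simulate_geochem(geochem_model(), driver, seed = 19L)
  r_amm <- stats::cor(g$ammonium, driver)
  ci <- fisher_z_interval(0.56, 500L)
  expect_gt(r_amm, ci[1L])
  expect_lt(r_amm, ci[2L])

  expect_error(geochem_model(targets = c(ammonium = 1.2)), "correlations")
  expect_error(simulate_geochem(geochem_model(), rep(0.1, 10)), "constant")
})

test_that("diatom step change and damage-age gradient appear in the truth", {
  sheet <- rbind(two_sample_sheet(),
                 data.frame(sample_id = c("Y2", "O2"), site = "SITE1",
                            depth_mbsf = c(2, 60), age_ka = c(10, 200),
                            type = "sample", stringsAsFactors = FALSE))
  cfg <- simulation_config(seed = 20L, samples = sheet,
                           library_size = 5000L)
  sim <- simulate_core(cfg)
  tree <- sim$taxonomy
  diatoms <- tree$nodes$taxon_id[vapply(tree$nodes$taxon_id, function(t) {
    10L %in% taxon_ancestors(tree, t)
  }, logical(1))]
  tr <- sim$truth_reads[!sim$truth_reads$is_contaminant, ]
  frac <- tapply(tr$source_taxon %in% diatoms, tr$sample_id, mean)
  expect_true(all(frac[c("Y1", "Y2")] > 0.40))
  expect_true(all(frac[c("O1", "O2")] < 0.12))

  # configured amplitude rises with age, and so does realised damage
  meta <- sim$truth_samples
  sed <- meta[meta$type == "sample", ]
  expect_true(all(diff(sed$d5[order(sed$age_ka)]) >= 0))
  damaged <- sim$truth_reads$damage_positions != "" &
    !sim$truth_reads$is_contaminant
  frac_dmg <- tapply(damaged[!sim$truth_reads$is_contaminant],
                     tr$sample_id, mean)
  ord <- sed$sample_id[order(sed$age_ka)]
  expect_gt(frac_dmg[[ord[4L]]], frac_dmg[[ord[1L]]])
})

test_that("invalid composition weights are rejected", {
  expect_error(composition_model(other_weights = c(`55` = 0.6, `56` = 0.2)),
               "sum to 1")
  expect_error(composition_model(p_pre = 1.2), "\\[0, 1\\]")
})
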