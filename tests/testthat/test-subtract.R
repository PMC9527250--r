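mk_prof <- function(m, samples, taxa) {
  m <- matrix(as.integer(m), length(samples), length(taxa), byrow = TRUE,
              dimnames = list(samples, taxa))
  structure(m, class = c("taxon_profile", class(m)))
}

test_that("both subtraction modes follow their arithmetic", {
  samples <- mk_prof(c(8L, 4L), "S1", c("X", "Y"))
  controls <- mk_prof(c(5L, 0L), "EBC", c("X", "Y"))
  rem <- subtract_controls(samples, controls, mode = "remove_taxon",
                           scope = "global")
  expect_identical(rem$profile["S1", "X"], 0L)
  expect_identical(rem$profile["S1", "Y"], 4L)     # absent from controls

  sub <- subtract_controls(samples, controls, mode = "subtract_counts",
                           scope = "global")
  expect_identical(sub$profile["S1", "X"], 3L)     # 8 - 5
  expect_identical(sub$profile["S1", "Y"], 4L)

  # flooring at zero
  small <- mk_prof(c(2L, 4L), "S1", c("X", "Y"))
  floored <- subtract_controls(small, controls, mode = "subtract_counts",
                               scope = "global")
  expect_identical(floored$profile["S1", "X"], 0L)

  expect_error(subtract_controls(samples, mk_prof(1L, "S1", "X"),
                                 scope = "global"), "share library")
})

test_that("per-site scope confines controls to their own site", {
  samples <- mk_prof(c(5L, 5L, 5L, 5L), c("A1", "B1"), c("X", "Y"))
  controls <- mk_prof(c(3L, 0L), "ctlA", c("X", "Y"))
  out <- subtract_controls(samples, controls, scope = "per_site",
                           sample_sites = c("siteA", "siteB"),
                           control_sites = "siteA")
  expect_identical(out$profile["A1", "X"], 0L)
  expect_identical(out$profile["B1", "X"], 5L)   # other site untouched
})

test_that("subtraction is idempotent, non-increasing and conserves counts", {
  with_seed(61L, {
    for (i in 1:20) {
      samples <- random_profile(4L, 6L, lambda = 10)
      controls <- random_profile(2L, 6L, lambda = 2)
      rownames(controls) <- c("C1", "C2")
      for (mode in c("remove_taxon", "subtract_counts")) {
        out <- subtract_controls(samples, controls, mode = mode,
                                 scope = "global")
        expect_true(all(out$profile <= samples))
        expect_true(all(out$profile >= 0L))
        expect_identical(
          out$report$count_after,
          out$report$count_before - out$report$count_removed)
        if (mode == "remove_taxon") {
          # whole-taxon removal is idempotent (count subtraction, by
          # construction, keeps reducing while counts remain)
          twice <- subtract_controls(out$profile, controls, mode = mode,
                                     scope = "global")
          expect_identical(twice$profile, out$profile)
        }
      }
    }
  })
})

test_that("injected contaminants are fully recalled from the truth table", {
  cfg <- simulation_config(seed = 62L, library_size = 1500L)
  sim <- simulate_core(cfg)
  truth <- sim$truth_reads
  meta <- sim$truth_samples
  ctrl_ids <- meta$sample_id[meta$type %in%
    c("control_air", "control_ebc", "control_drillfluid")]
  samp_ids <- meta$sample_id[meta$type == "sample"]

  counts <- table(factor(truth$sample_id,
                         levels = c(samp_ids, ctrl_ids)),
                  factor(truth$source_taxon))
  prof <- structure(matrix(as.integer(counts), nrow(counts),
                           dimnames = dimnames(counts)),
                    class = c("taxon_profile", "matrix"))
  out <- subtract_controls(prof[samp_ids, , drop = FALSE],
                           prof[ctrl_ids, , drop = FALSE],
                           scope = "global")
  injected <- unique(truth$source_taxon[truth$is_contaminant])
  # all injected contaminant taxa removed everywhere (100% recall)
  expect_true(all(out$profile[, as.character(injected)] == 0L))
  # collateral removal limited to taxa the simulator placed in controls
  removed_taxa <- unique(out$report$taxon_id[out$report$count_removed > 0L])
  expect_true(all(removed_taxa %in% as.character(injected)))
})
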