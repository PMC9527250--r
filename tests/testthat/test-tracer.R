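mk_run <- function(blanks = c(0.1, 0.3),
                   standards = data.frame(nominal_level = rep(c(0.5, 5), each = 3),
                                          value = c(0.40, 0.45, 0.50,
                                                    4.4, 4.5, 4.3)),
                   measurements = data.frame(
                     sample_id = c("A", "A", "B", "B"),
                     location = c("periphery", "centre", "periphery",
                                  "centre"),
                     value = c(1.0, 0.05, 0.02, 0.01),
                     stringsAsFactors = FALSE)) {
  tracer_run("run1", "SITE1", blanks, standards, measurements)
}

test_that("blank correction subtracts the mean and floors at zero", {
  run <- blank_correct(mk_run())
  m <- run$measurements
  expect_equal(m$value[1L], 1.0 - 0.2)
  expect_equal(m$value[3L], 0)                 # 0.02 - 0.2 floored
  expect_error(blank_correct(run), "already")  # fixed order, guarded

  zero <- blank_correct(mk_run(blanks = c(0, 0)))
  expect_equal(zero$measurements$value, mk_run()$measurements$value)

  expect_error(tracer_run("r", "s", numeric(1), mk_run()$standards,
                          mk_run()$measurements), "duplicate blanks")
})

test_that("detection limit is 3 x SD(blanks) with lowest-standard fallback", {
  run <- mk_run(blanks = c(0.1, 0.2, 0.3))
  expect_equal(detection_limit(run), 3 * stats::sd(c(0.1, 0.2, 0.3)))
  expect_equal(detection_limit(run), 0.3)      # sample SD convention

  fb <- mk_run(blanks = c(0, 0, 0))
  expect_equal(detection_limit(fb), 3 * stats::sd(c(0.40, 0.45, 0.50)))

  # constructed run recovering a chosen limit exactly
  reps <- c(0.40, 0.40 + 0.2338 / 3 * sqrt(2))   # sd = limit / 3
  target <- mk_run(blanks = c(0, 0),
                   standards = data.frame(nominal_level = 0.5, value = reps))
  expect_equal(detection_limit(target), 0.2338, tolerance = 1e-12)

  solo <- mk_run(blanks = c(0, 0),
                 standards = data.frame(nominal_level = 0.5, value = 0.44))
  expect_error(detection_limit(solo), "fewer than 2")
})

test_that("isomer calibration scales nominal levels linearly", {
  expect_equal(isomer_calibrate(1.0), 0.88)
  expect_equal(isomer_calibrate(2.5, fraction = 1.0), 2.5)
  levels <- c(0.5, 1, 2, 5)
  fit <- stats::lm(isomer_calibrate(levels) ~ levels)
  expect_equal(unname(stats::coef(fit)[2L]), 0.88)
  expect_equal(unname(stats::coef(fit)[1L]), 0, tolerance = 1e-12)
})

test_that("verdicts reject below-limit values and flag detections", {
  meas <- data.frame(
    sample_id = c("A", "A", "B", "B", "C", "C", "D"),
    location = c("periphery", "centre", "periphery", "centre",
                 "periphery", "centre", "periphery"),
    value = c(1.0, 0.01, 0.02, 0.01, 0.9, 0.5, 0.02),
    stringsAsFactors = FALSE)
  run <- blank_correct(mk_run(blanks = c(0, 0), measurements = meas))
  v <- assess_contamination(run)
  limit <- detection_limit(run)
  expect_equal(v$detection_limit, rep(limit, 4L))

  expect_identical(v$flag[v$sample_id == "A"], "periphery_detected")
  expect_true(is.na(v$corrected_centre[v$sample_id == "A"]))
  expect_identical(v$flag[v$sample_id == "B"], "clean")
  expect_identical(v$flag[v$sample_id == "C"], "centre_detected")
  expect_match(v$note[v$sample_id == "C"], "caution")
  expect_true(v$corrected_centre[v$sample_id == "C"] >= limit)
  expect_true(v$missing_centre[v$sample_id == "D"])
  expect_identical(attr(v, "summary"),
                   c(clean = 2L, periphery_only = 1L, centre = 1L))

  # verdicts invariant to measurement ordering
  run2 <- blank_correct(mk_run(blanks = c(0, 0),
                               measurements = meas[sample(7L), ]))
  v2 <- assess_contamination(run2)
  v2 <- v2[match(v$sample_id, v2$sample_id), ]
  rownames(v2) <- NULL
  expect_identical(v, v2)

  expect_error(assess_contamination(mk_run()), "blank-corrected")
})

test_that("tracer verdicts recover injected ground truth at 5x separation", {
  sheet <- data.frame(sample_id = sprintf("T%02d", 1:40),
                      stringsAsFactors = FALSE)
  model <- tracer_model(blanks_zero = FALSE, blank_mean = 0.1,
                        blank_sd = 0.04, n_blanks = 3L,
                        p_periphery = 0.5, p_centre = 0.2,
                        periphery_level = 1.2, centre_level = 0.64,
                        noise_sd = 0.02)
  tr <- simulate_tracer_run(model, sheet, seed = 71L)
  v <- assess_contamination(blank_correct(tr$run))
  got <- v$flag[match(tr$truth$sample_id, v$sample_id)]
  want <- c(clean = "clean", periphery = "periphery_detected",
            centre = "centre_detected")[tr$truth$class]
  expect_identical(got, unname(want))
})
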