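## Drill-fluid tracer contamination QC: blank correction, detection
## limits with the lowest-standard fallback, stereoisomer calibration of
## nominal standards, and per-sample contamination verdicts.

#' Construct one tracer measurement run
#'
#' @param run_id,site labels.
#' @param blanks numeric blank concentrations (ng/mL), at least two per
#'   run.
#' @param standards data.frame `nominal_level`, `value` (replicate
#'   measurements).
#' @param measurements data.frame `sample_id`, `location` (one of
#'   `periphery`, `centre`, `drill_fluid`), `value`.
#' @return An object of class `tracer_run`.
#' @export
tracer_run <- function(run_id, site, blanks, standards, measurements) {
  if (length(blanks) < 2L) stop("a run needs at least duplicate blanks")
  if (any(blanks < 0) || any(standards$value < 0) ||
      any(measurements$value < 0)) {
    stop("tracer concentrations must be non-negative")
  }
  stopifnot(all(c("nominal_level", "value") %in% names(standards)),
            all(c("sample_id", "location", "value") %in% names(measurements)))
  bad_loc <- setdiff(measurements$location,
                     c("periphery", "centre", "drill_fluid"))
  if (length(bad_loc) > 0L) stop("unknown location: ", bad_loc[1L])
  structure(list(run_id = run_id, site = site, blanks = as.numeric(blanks),
                 standards = standards, measurements = measurements,
                 blank_corrected = FALSE),
            class = "tracer_run")
}

#' @export
print.tracer_run <- function(x, ...) {
  cat("<tracer_run> ", x$run_id, " (", x$site, "): ", length(x$blanks),
      " blanks, ", nrow(x$standards), " standard measurements, ",
      nrow(x$measurements), " sample measurements",
      if (x$blank_corrected) " [blank-corrected]", "\n", sep = "")
  invisible(x)
}

#' Flatten a tracer run to a single table
#'
#' @param run a `tracer_run`.
#' @return data.frame with columns `run_id`, `site`, `kind`, `sample_id`,
#'   `location`, `nominal_level`, `value`.
#' @export
tracer_run_table <- function(run) {
  stopifnot(inherits(run, "tracer_run"))
  rbind(
    data.frame(run_id = run$run_id, site = run$site, kind = "blank",
               sample_id = NA, location = NA, nominal_level = NA,
               value = run$blanks, stringsAsFactors = FALSE),
    data.frame(run_id = run$run_id, site = run$site, kind = "standard",
               sample_id = NA, location = NA,
               nominal_level = run$standards$nominal_level,
               value = run$standards$value, stringsAsFactors = FALSE),
    data.frame(run_id = run$run_id, site = run$site, kind = "sample",
               sample_id = run$measurements$sample_id,
               location = run$measurements$location, nominal_level = NA,
               value = run$measurements$value, stringsAsFactors = FALSE))
}

#' Blank-correct a tracer run
#'
#' Subtracts the mean of the run's blanks from every sample measurement,
#' flooring at zero (concentrations are physical quantities). Correcting
#' an already-corrected run is an error: the fixed order is blank
#' correction, then limit testing.
#'
#' @param run a `tracer_run`.
#' @return The corrected run.
#' @export
blank_correct <- function(run) {
  stopifnot(inherits(run, "tracer_run"))
  if (run$blank_corrected) stop("run is already blank-corrected")
  if (length(run$blanks) == 0L) stop("no blanks in run")
  run$measurements$value <- pmax(0, run$measurements$value - mean(run$blanks))
  run$blank_corrected <- TRUE
  run
}

#' Detection limit of a tracer run
#'
#' Three times the standard deviation of the run's blanks; when the
#' blanks have zero spread (e.g. all zero), three times the standard
#' deviation of the replicates of the lowest standard level instead. The
#' sample standard deviation (n-1 denominator) is the default convention.
#'
#' @param run a `tracer_run`.
#' @param sd_type `"sample"` (n-1) or `"population"` (n).
#' @return Detection limit in ng/mL.
#' @export
detection_limit <- function(run, sd_type = c("sample", "population")) {
  stopifnot(inherits(run, "tracer_run"))
  sd_type <- match.arg(sd_type)
  sdev <- function(x) {
    s <- stats::sd(x)
    if (sd_type == "population") s * sqrt((length(x) - 1) / length(x)) else s
  }
  s_blank <- sdev(run$blanks)
  if (s_blank > 0) return(3 * s_blank)
  low <- min(run$standards$nominal_level)
  reps <- run$standards$value[run$standards$nominal_level == low]
  if (length(reps) < 2L) {
    stop("blank SD is zero and the lowest standard has fewer than 2 ",
         "replicates; detection limit undefined")
  }
  3 * sdev(reps)
}

#' Stereoisomer calibration of nominal standard concentrations
#'
#' The measurable stereoisomer category makes up only a fraction of the
#' bottled tracer; nominal standard levels are scaled by that fraction
#' (default 0.88) before constructing the calibration relationship.
#'
#' @param nominal_level nominal concentration(s).
#' @param fraction measurable fraction in (0, 1].
#' @return Effective concentration(s).
#' @export
isomer_calibrate <- function(nominal_level, fraction = 0.88) {
  stopifnot(fraction > 0, fraction <= 1)
  nominal_level * fraction
}

#' Contamination verdicts for a blank-corrected tracer run
#'
#' Corrected values below the run's detection limit are rejected
#' (reported below-limit, `NA`). Each sample is flagged `clean`,
#' `periphery_detected`, and/or `centre_detected` from its surviving
#' values; a centre detection carries a caution note. Samples missing a
#' location are marked explicitly.
#'
#' @param run a blank-corrected `tracer_run`.
#' @param sd_type passed to [detection_limit()].
#' @return data.frame of class `tracer_verdicts`: `sample_id`,
#'   `corrected_periphery`, `corrected_centre` (`NA` = below limit or
#'   missing), `detection_limit`, `periphery_detected`, `centre_detected`,
#'   `missing_centre`, `flag`, `note`. A `summary` attribute counts
#'   clean / periphery-only / centre detections.
#' @export
assess_contamination <- function(run, sd_type = "sample") {
  stopifnot(inherits(run, "tracer_run"))
  if (!run$blank_corrected) {
    stop("run must be blank-corrected before contamination assessment")
  }
  limit <- detection_limit(run, sd_type = sd_type)
  meas <- run$measurements[run$measurements$location %in%
                             c("periphery", "centre"), , drop = FALSE]
  ids <- unique(meas$sample_id)
  get_val <- function(sid, loc) {
    v <- meas$value[meas$sample_id == sid & meas$location == loc]
    if (length(v) == 0L) NA_real_ else v[1L]
  }
  peri <- vapply(ids, get_val, numeric(1), loc = "periphery")
  cent <- vapply(ids, get_val, numeric(1), loc = "centre")
  missing_centre <- is.na(cent)
  peri_det <- !is.na(peri) & peri >= limit
  cent_det <- !is.na(cent) & cent >= limit
  out <- data.frame(
    sample_id = ids,
    corrected_periphery = ifelse(peri_det, peri, NA_real_),
    corrected_centre = ifelse(cent_det, cent, NA_real_),
    detection_limit = limit,
    periphery_detected = peri_det,
    centre_detected = cent_det,
    missing_centre = missing_centre,
    flag = ifelse(cent_det, "centre_detected",
                  ifelse(peri_det, "periphery_detected", "clean")),
    note = ifelse(cent_det, "interpret with caution: tracer at core centre",
                  ""),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "summary") <- c(
    clean = sum(!peri_det & !cent_det),
    periphery_only = sum(peri_det & !cent_det),
    centre = sum(cent_det))
  class(out) <- c("tracer_verdicts", class(out))
  out
}
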