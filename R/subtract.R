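#' Subtract control-derived contaminants from sample profiles
#'
#' Taxa observed in extraction-blank, air or drill-fluid control
#' libraries are treated as putative contaminants. In `remove_taxon` mode
#' (the default, conservative choice) every taxon with at least one read
#' in any in-scope control is zeroed in all in-scope samples; in
#' `subtract_counts` mode each sample's count for such a taxon is reduced
#' by the maximum count observed for it across in-scope controls, floored
#' at zero. With `scope = "per_site"` controls only act on samples from
#' their own site; `"global"` applies every control everywhere.
#' Subtraction is idempotent and never increases a count.
#'
#' @param samples `taxon_profile` of the sediment samples.
#' @param controls `taxon_profile` of the control libraries.
#' @param mode `"remove_taxon"` or `"subtract_counts"`.
#' @param scope `"per_site"` or `"global"`.
#' @param sample_sites,control_sites named (or positional) character
#'   vectors giving the site of each sample/control row; required for
#'   `per_site` scope.
#' @return list(`profile` = subtracted profile, `report` = per
#'   (taxon, sample) data.frame with `count_before`, `count_removed`,
#'   `count_after`, `contaminants` = data.frame of control-derived taxa
#'   with their supporting control counts).
#' @export
subtract_controls <- function(samples, controls,
                              mode = c("remove_taxon", "subtract_counts"),
                              scope = c("per_site", "global"),
                              sample_sites = NULL, control_sites = NULL) {
  mode <- match.arg(mode)
  scope <- match.arg(scope)
  overlap <- intersect(rownames(samples), rownames(controls))
  if (length(overlap) > 0L) {
    stop("sample and control profiles share library id(s): ",
         paste(overlap, collapse = ", "))
  }
  if (scope == "per_site") {
    if (is.null(sample_sites) || is.null(control_sites)) {
      stop("per_site scope needs sample_sites and control_sites")
    }
    sample_sites <- rep_len(as.character(sample_sites), nrow(samples))
    control_sites <- rep_len(as.character(control_sites), nrow(controls))
  } else {
    sample_sites <- rep("global", nrow(samples))
    control_sites <- rep("global", nrow(controls))
  }

  out <- samples
  removed <- samples * 0L
  cont_rows <- list()
  for (site in unique(sample_sites)) {
    s_idx <- which(sample_sites == site)
    c_idx <- which(control_sites == site)
    if (length(c_idx) == 0L) next
    ctl <- controls[c_idx, , drop = FALSE]
    ctl_max <- apply(ctl, 2L, max)
    flagged <- colnames(controls)[ctl_max > 0L]
    flagged <- intersect(flagged, colnames(samples))
    if (length(flagged) == 0L) next
    cont_rows[[site]] <- data.frame(
      site = site, taxon_id = flagged,
      control_count = as.integer(colSums(ctl[, flagged, drop = FALSE])),
      stringsAsFactors = FALSE)
    for (tx in flagged) {
      before <- out[s_idx, tx]
      after <- if (mode == "remove_taxon") {
        rep(0L, length(s_idx))
      } else {
        pmax(0L, before - as.integer(ctl_max[tx]))
      }
      removed[s_idx, tx] <- removed[s_idx, tx] + (before - after)
      out[s_idx, tx] <- after
    }
  }
  report <- data.frame(
    sample_id = rep(rownames(samples), ncol(samples)),
    taxon_id = rep(colnames(samples), each = nrow(samples)),
    count_before = as.integer(samples),
    count_removed = as.integer(removed),
    count_after = as.integer(out),
    stringsAsFactors = FALSE)
  contaminants <- do.call(rbind, cont_rows)
  if (is.null(contaminants)) {
    contaminants <- data.frame(site = character(0), taxon_id = character(0),
                               control_count = integer(0),
                               stringsAsFactors = FALSE)
  }
  rownames(contaminants) <- NULL
  list(profile = out, report = report, contaminants = contaminants)
}
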