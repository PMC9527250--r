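## Configuration-driven orchestration of the full workflow:
## simulate -> read QC -> align/assign -> control subtraction -> damage
## authentication -> tracer QC -> abundance & correlation statistics.

#' Pipeline configuration
#'
#' One auditable document holding every stage parameter. Defaults follow
#' the workflow's reference settings: 25 bp length cutoff, complexity
#' threshold 0.55 (k = 4), 95% minimum identity with a 10% score window,
#' minimum support off, 5 bp terminal damage window, 50-read
#' low-confidence threshold, conservative whole-taxon control
#' subtraction scoped per site.
#'
#' @param simulation a [simulation_config()] describing the input core.
#' @param seed master seed; overrides the simulation config's seed.
#' @param min_len,complexity_threshold,complexity_k read QC settings.
#' @param min_pid,top_percent hit filtering settings.
#' @param min_support_percent profile support threshold (0 = off).
#' @param k_terminal,min_damage_reads damage-call settings.
#' @param subtraction_mode,subtraction_scope control subtraction settings.
#' @param rarefy_depth `NULL` (no rarefaction, the marker-gene default),
#'   a fixed depth, or `"auto"` for [choose_depth()] on the QC'd library
#'   sizes.
#' @param sd_type tracer SD convention (`"sample"` or `"population"`).
#' @param align an [align_params()] list.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = simulation_config(), seed = NULL,
                            min_len = 25L, complexity_threshold = 0.55,
                            complexity_k = 4L, min_pid = 0.95,
                            top_percent = 0.10, min_support_percent = 0,
                            k_terminal = 5L, min_damage_reads = 50L,
                            subtraction_mode = "remove_taxon",
                            subtraction_scope = "per_site",
                            rarefy_depth = NULL, sd_type = "sample",
                            align = align_params()) {
  if (!is.null(seed)) simulation$seed <- as.integer(seed)
  structure(list(simulation = simulation, min_len = as.integer(min_len),
                 complexity_threshold = complexity_threshold,
                 complexity_k = as.integer(complexity_k),
                 min_pid = min_pid, top_percent = top_percent,
                 min_support_percent = min_support_percent,
                 k_terminal = as.integer(k_terminal),
                 min_damage_reads = as.integer(min_damage_reads),
                 subtraction_mode = subtraction_mode,
                 subtraction_scope = subtraction_scope,
                 rarefy_depth = rarefy_depth, sd_type = sd_type,
                 align = align),
            class = "pipeline_config")
}

.finding <- function(level, field, message) {
  data.frame(level = level, field = field, message = message,
             stringsAsFactors = FALSE)
}

#' Validate a pipeline configuration
#'
#' Pure check without side effects: returns an empty data.frame when the
#' configuration is sound, otherwise typed findings (`error` for values
#' outside their documented range, `warning` for suspicious cross-field
#' combinations such as a rarefaction depth exceeding every library
#' size).
#'
#' @param config a [pipeline_config()].
#' @return data.frame `level`, `field`, `message`.
#' @export
validate_config <- function(config) {
  f <- list()
  chk <- function(cond, level, field, msg) {
    if (cond) f[[length(f) + 1L]] <<- .finding(level, field, msg)
  }
  chk(config$min_len < 1L, "error", "min_len", "must be at least 1")
  chk(config$complexity_threshold < 0 || config$complexity_threshold > 1,
      "error", "complexity_threshold", "must lie in [0, 1]")
  chk(config$complexity_k < 1L, "error", "complexity_k", "must be positive")
  chk(config$min_pid < 0 || config$min_pid > 1, "error", "min_pid",
      "must lie in [0, 1]")
  chk(config$top_percent < 0 || config$top_percent > 1, "error",
      "top_percent", "must lie in [0, 1]")
  chk(config$min_support_percent < 0 || config$min_support_percent >= 1,
      "error", "min_support_percent", "must lie in [0, 1)")
  chk(config$k_terminal < 1L, "error", "k_terminal", "must be positive")
  chk(config$min_damage_reads < 1L, "error", "min_damage_reads",
      "must be positive")
  chk(!config$subtraction_mode %in% c("remove_taxon", "subtract_counts"),
      "error", "subtraction_mode", "unknown mode")
  chk(!config$subtraction_scope %in% c("per_site", "global"),
      "error", "subtraction_scope", "unknown scope")
  chk(!config$sd_type %in% c("sample", "population"), "error", "sd_type",
      "unknown SD convention")
  if (!is.null(config$rarefy_depth) &&
      !identical(config$rarefy_depth, "auto")) {
    chk(config$rarefy_depth <= 0, "error", "rarefy_depth",
        "must be positive")
    sizes <- vapply(config$simulation$samples$type, .library_size,
                    integer(1), config = config$simulation)
    chk(is.numeric(config$rarefy_depth) && all(sizes < config$rarefy_depth),
        "warning", "rarefy_depth", "exceeds every library size")
  }
  out <- do.call(rbind, f)
  if (is.null(out)) {
    out <- data.frame(level = character(0), field = character(0),
                      message = character(0), stringsAsFactors = FALSE)
  }
  out
}

#' Run the full workflow
#'
#' Simulates the configured core, then applies read QC, seed-and-extend
#' alignment with naive-LCA assignment, control subtraction, damage
#' authentication, tracer contamination assessment and the abundance /
#' correlation statistics. Identical configuration and seed give
#' identical outputs. When `outdir` is given, all stage tables and a run
#' manifest (config snapshot, stage-by-stage read counts, seed, package
#' version) are written as TSV/YAML.
#'
#' @param config a [pipeline_config()].
#' @param outdir optional output directory.
#' @return list of class `pipeline_result` with the stage outputs and the
#'   `manifest`.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  findings <- validate_config(config)
  if (any(findings$level == "error")) {
    stop("invalid configuration: ",
         paste(findings$field[findings$level == "error"], collapse = ", "))
  }

  sim <- simulate_core(config$simulation)
  tree <- sim$taxonomy

  qc <- qc_reads(sim$reads, min_len = config$min_len,
                 complexity_threshold = config$complexity_threshold,
                 complexity_k = config$complexity_k)

  hits <- align_reads(qc$reads, sim$reference, config$align)
  assignments <- assign_reads(qc$reads, hits, tree,
                              min_pid = config$min_pid,
                              top_percent = config$top_percent)
  profile <- build_profile(assignments, tree,
                           min_support_percent = config$min_support_percent,
                           samples = unique(sim$reads$sample_id))

  meta <- sim$truth_samples
  is_control <- meta$type %in% c("control_air", "control_ebc",
                                 "control_drillfluid")
  ctrl_ids <- meta$sample_id[is_control]
  samp_ids <- meta$sample_id[!is_control]
  in_prof <- rownames(profile)
  sample_prof <- profile[intersect(samp_ids, in_prof), , drop = FALSE]
  control_prof <- profile[intersect(ctrl_ids, in_prof), , drop = FALSE]
  site_of <- stats::setNames(meta$site, meta$sample_id)
  sub <- subtract_controls(
    sample_prof, control_prof, mode = config$subtraction_mode,
    scope = config$subtraction_scope,
    sample_sites = site_of[rownames(sample_prof)],
    control_sites = site_of[rownames(control_prof)])

  ## damage: best-hit alignments of sediment-sample reads whose taxon
  ## survived subtraction
  best <- best_hits(hits)
  best <- best[best$sample_id %in%
                 meta$sample_id[meta$type == "sample"], , drop = FALSE]
  removed_taxa <- unique(sub$contaminants$taxon_id)
  asg_taxon <- stats::setNames(as.character(assignments$taxon_id),
                               assignments$read_id)
  keep <- !(asg_taxon[best$read_id] %in% removed_taxa)
  keep[is.na(keep)] <- TRUE
  best_kept <- best[keep, , drop = FALSE]
  calls <- classify_reads(best_kept, k_terminal = config$k_terminal,
                          min_pid = config$min_pid)
  spectrum <- substitution_spectrum(best_kept)
  decay <- if (sum(!is.na(spectrum$f5)) >= 3L) {
    fit_decay(spectrum)
  } else NULL
  damage_by_sample <- damage_proportion(calls, by = "sample_id",
                                        min_reads = config$min_damage_reads)

  verdicts <- lapply(sim$tracer, function(run) {
    assess_contamination(blank_correct(run), sd_type = config$sd_type)
  })

  phylum <- project_rank(sub$profile, tree, "phylum")
  rel <- relative_abundance(phylum)
  rel_grouped <- group_rare(rel)
  diatom_id <- as.character(
    tree$nodes$taxon_id[tree$nodes$name == "Bacillariophyta"])
  diatom_fraction <- if (diatom_id %in% colnames(rel)) {
    stats::setNames(rel[, diatom_id], rownames(rel))
  } else {
    stats::setNames(rep(0, nrow(rel)), rownames(rel))
  }
  sed <- meta[meta$type == "sample", , drop = FALSE]
  diatom_table <- data.frame(
    sample_id = sed$sample_id, age_ka = sed$age_ka,
    diatom_fraction = diatom_fraction[sed$sample_id],
    stringsAsFactors = FALSE)
  rownames(diatom_table) <- NULL

  correlations <- NULL
  if (!is.null(sim$geochem)) {
    dmg <- damage_by_sample$proportion[
      match(sim$geochem$sample_id, damage_by_sample$sample_id)]
    if (sum(!is.na(dmg)) >= 3L) {
      gx <- sim$geochem[!names(sim$geochem) %in%
                          c("sample_id", "depth_mbsf")]
      correlations <- pearson_matrix(
        data.frame(damage_proportion = dmg), gx)
    }
  }

  rarefied <- NULL
  if (!is.null(config$rarefy_depth)) {
    depth <- if (identical(config$rarefy_depth, "auto")) {
      choose_depth(rowSums(sub$profile), rowSums(sub$profile) > 0)
    } else config$rarefy_depth
    rarefied <- rarefy(sub$profile, depth, seed = config$simulation$seed)
  }

  n_hit_reads <- length(unique(hits$read_id))
  manifest <- list(
    package_version = as.character(utils::packageVersion("sedapipe")),
    seed = config$simulation$seed,
    counts = list(
      simulated = nrow(sim$reads),
      qc_retained = nrow(qc$reads),
      with_hits = n_hit_reads,
      assigned = sum(!is.na(assignments$taxon_id)),
      post_subtraction = sum(sub$profile)),
    config = .config_snapshot(config))

  result <- structure(
    list(sim = sim, qc = qc, hits = hits, assignments = assignments,
         profile = profile, subtraction = sub, calls = calls,
         spectrum = spectrum, decay = decay,
         damage_by_sample = damage_by_sample, tracer_verdicts = verdicts,
         phylum_profile = phylum, relative_abundance = rel,
         relative_abundance_grouped = rel_grouped,
         diatom_table = diatom_table, correlations = correlations,
         rarefied = rarefied, manifest = manifest),
    class = "pipeline_result")
  if (!is.null(outdir)) write_pipeline_result(result, outdir)
  result
}

.config_snapshot <- function(config) {
  sim <- config$simulation
  list(
    seed = sim$seed, min_len = config$min_len,
    complexity_threshold = config$complexity_threshold,
    complexity_k = config$complexity_k, min_pid = config$min_pid,
    top_percent = config$top_percent,
    min_support_percent = config$min_support_percent,
    k_terminal = config$k_terminal,
    min_damage_reads = config$min_damage_reads,
    subtraction_mode = config$subtraction_mode,
    subtraction_scope = config$subtraction_scope,
    sd_type = config$sd_type,
    align = unclass(config$align),
    simulation = list(
      library_size = sim$library_size, seq_error = sim$seq_error,
      n_samples = nrow(sim$samples),
      composition = unclass(sim$composition)[c("p_pre", "p_post", "t_star")],
      damage = unclass(sim$damage),
      fragment = unclass(sim$fragment)[c("mode", "sdlog", "min_len")],
      contaminant_rate = sim$contaminants$rate))
}

#' Write a pipeline result's tables to disk
#'
#' @param result a `pipeline_result`.
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_pipeline_result <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, name) {
    utils::write.table(x, file.path(outdir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  mat <- function(m, name) {
    utils::write.table(data.frame(sample_id = rownames(m), m,
                                  check.names = FALSE),
                       file.path(outdir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  tsv(result$qc$report, "qc_report.tsv")
  mat(result$profile, "profile_counts.tsv")
  mat(result$subtraction$profile, "profile_subtracted.tsv")
  tsv(result$subtraction$report, "subtraction_report.tsv")
  tsv(result$subtraction$contaminants, "contaminant_taxa.tsv")
  tsv(result$calls, "damage_calls.tsv")
  tsv(data.frame(position = seq_len(result$spectrum$m) - 1L,
                 f5 = result$spectrum$f5, n5 = result$spectrum$n5,
                 f3 = result$spectrum$f3, n3 = result$spectrum$n3),
      "damage_spectrum.tsv")
  tsv(result$damage_by_sample, "damage_by_sample.tsv")
  for (site in names(result$tracer_verdicts)) {
    tsv(result$tracer_verdicts[[site]],
        paste0("tracer_verdicts_", site, ".tsv"))
  }
  mat(result$relative_abundance, "relative_abundance_phylum.tsv")
  tsv(result$diatom_table, "diatom_fraction.tsv")
  if (!is.null(result$correlations)) {
    tsv(result$correlations, "correlations.tsv")
  }
  yaml::write_yaml(result$manifest, file.path(outdir, "manifest.yaml"))
  invisible(outdir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat("  reads simulated:", x$manifest$counts$simulated,
      "| QC retained:", x$manifest$counts$qc_retained,
      "| assigned:", x$manifest$counts$assigned, "\n")
  if (!is.null(x$decay)) {
    cat(sprintf("  damage fit: d = %.3f, r = %.3f, eps = %.4f\n",
                x$decay$d_hat, x$decay$r_hat, x$decay$eps_hat))
  }
  invisible(x)
}
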