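## Ground-truthed synthetic sediment-core generator: per-sample read
## libraries with an age-dependent taxon-composition step change and
## age-graded terminal deamination damage, control libraries carrying only
## modern contaminants, tracer measurement runs, and geochemical
## covariates with configured correlation against the damage driver.

#' Evaluate code under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards. With `seed = NULL` the
#' current stream is used untouched.
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Built-in marine sediment taxonomy
#'
#' A compact rooted taxonomy of marine eukaryote groups typical of
#' Southern Ocean sediment records (diatoms, radiolarians, chlorophytes,
#' dinoflagellates, haptophytes, crustaceans, ...), sediment-dwelling
#' fungi used as modern contaminants, and a cyanobacterial outgroup.
#'
#' @return A `taxonomy` object.
#' @export
default_taxonomy <- function() {
  n <- function(id, parent, rank, name) {
    data.frame(taxon_id = id, parent_id = parent, rank = rank, name = name,
               stringsAsFactors = FALSE)
  }
  nodes <- rbind(
    n(1L, 1L, "root", "root"),
    n(2L, 1L, "domain", "Eukaryota"),
    n(3L, 1L, "domain", "Bacteria"),
    n(10L, 2L, "phylum", "Bacillariophyta"),
    n(11L, 2L, "phylum", "Polycystinea"),
    n(12L, 2L, "phylum", "Chlorophyta"),
    n(13L, 2L, "phylum", "Streptophyta"),
    n(14L, 2L, "phylum", "Cercozoa"),
    n(15L, 2L, "phylum", "Dinophyceae"),
    n(16L, 2L, "phylum", "Haptista"),
    n(17L, 2L, "phylum", "Arthropoda"),
    n(18L, 2L, "phylum", "Ascomycota"),
    n(19L, 2L, "phylum", "Basidiomycota"),
    n(20L, 2L, "phylum", "Annelida"),
    n(21L, 3L, "phylum", "Cyanobacteria"),
    n(30L, 10L, "class", "Mediophyceae"),
    n(31L, 10L, "class", "Bacillariophyceae"),
    n(40L, 30L, "genus", "Chaetoceros"),
    n(41L, 30L, "genus", "Hemiaulus"),
    n(42L, 31L, "genus", "Fragilariopsis"),
    n(50L, 40L, "species", "Chaetoceros affinis"),
    n(51L, 40L, "species", "Chaetoceros dichaeta"),
    n(52L, 41L, "species", "Hemiaulus sinensis"),
    n(53L, 42L, "species", "Fragilariopsis cylindrus"),
    n(54L, 42L, "species", "Fragilariopsis kerguelensis"),
    n(43L, 12L, "genus", "Micromonas"),
    n(55L, 43L, "species", "Micromonas pusilla"),
    n(44L, 12L, "genus", "Coccomyxa"),
    n(56L, 44L, "species", "Coccomyxa subellipsoidea"),
    n(45L, 11L, "genus", "Spongotrochus"),
    n(57L, 45L, "species", "Spongotrochus glacialis"),
    n(46L, 13L, "genus", "Nothofagus"),
    n(58L, 46L, "species", "Nothofagus pumilio"),
    n(47L, 14L, "genus", "Cryothecomonas"),
    n(59L, 47L, "species", "Cryothecomonas aestivalis"),
    n(48L, 15L, "genus", "Polarella"),
    n(60L, 48L, "species", "Polarella glacialis"),
    n(49L, 16L, "genus", "Phaeocystis"),
    n(61L, 49L, "species", "Phaeocystis antarctica"),
    n(62L, 17L, "genus", "Euphausia"),
    n(63L, 62L, "species", "Euphausia superba"),
    n(64L, 20L, "genus", "Harmothoe"),
    n(65L, 64L, "species", "Harmothoe spinosa"),
    n(66L, 18L, "genus", "Aspergillus"),
    n(67L, 66L, "species", "Aspergillus fumigatus"),
    n(69L, 18L, "genus", "Penicillium"),
    n(68L, 69L, "species", "Penicillium chrysogenum"),
    n(70L, 19L, "genus", "Coriolopsis"),
    n(71L, 70L, "species", "Coriolopsis gallica"),
    n(72L, 19L, "genus", "Malassezia"),
    n(73L, 72L, "species", "Malassezia restricta"),
    n(74L, 21L, "genus", "Synechococcus"),
    n(75L, 74L, "species", "Synechococcus elongatus")
  )
  taxonomy(nodes)
}

#' Default down-core sample sheet
#'
#' Twelve dated sediment samples spanning ~1.4-392 ka (six younger and six
#' older than the 14.5 ka composition boundary), a mudline sample, and
#' air, extraction-blank and drill-fluid controls, all at one site.
#' Depths assume ~30 cm per kyr.
#'
#' @return data.frame `sample_id`, `site`, `depth_mbsf`, `age_ka`, `type`.
#' @export
default_samples <- function() {
  ages <- c(1.4, 2.8, 4.4, 7.1, 9.8, 12.7, 34, 74, 118, 195, 262, 392)
  rbind(
    data.frame(sample_id = sprintf("S%02d", seq_along(ages)), site = "SITE1",
               depth_mbsf = round(ages * 0.3, 2), age_ka = ages,
               type = "sample", stringsAsFactors = FALSE),
    data.frame(sample_id = c("MUDLINE", "CTRL_AIR", "CTRL_EBC", "CTRL_PFMD"),
               site = "SITE1", depth_mbsf = c(0, NA, NA, NA),
               age_ka = c(0, NA, NA, NA),
               type = c("mudline", "control_air", "control_ebc",
                        "control_drillfluid"),
               stringsAsFactors = FALSE)
  )
}

#' Taxon-composition model with a dated step change
#'
#' The diatom group holds a fraction `p_pre` of the (non-contaminant)
#' community in samples older than `t_star` and `p_post` in younger
#' samples; the remainder is spread over the other eukaryote species
#' (equally, or by `other_weights`).
#'
#' @param p_pre,p_post diatom fractions before/after the boundary
#'   (defaults 0.08 and 0.50).
#' @param t_star boundary age in ka (default 14.5).
#' @param other_weights optional named vector of weights over
#'   non-diatom taxon ids; must sum to 1.
#' @return list of class `composition_model`.
#' @export
composition_model <- function(p_pre = 0.08, p_post = 0.50, t_star = 14.5,
                              other_weights = NULL) {
  if (p_pre < 0 || p_pre > 1 || p_post < 0 || p_post > 1) {
    stop("diatom proportions must lie in [0, 1]")
  }
  if (!is.null(other_weights) && abs(sum(other_weights) - 1) > 1e-8) {
    stop("composition weights must sum to 1")
  }
  structure(list(p_pre = p_pre, p_post = p_post, t_star = t_star,
                 other_weights = other_weights),
            class = "composition_model")
}

#' Terminal deamination damage model
#'
#' C-to-T at the 5' end and (in double-stranded library mode) G-to-A at
#' the 3' end, with amplitude `d5 * r^i` decaying geometrically from the
#' fragment terminus, plus a uniform background substitution rate `eps`.
#' The per-sample amplitude grows linearly with age up to `age_scale_ka`:
#' `d5(age) = d5_surface + (d5_deep - d5_surface) * min(age, s) / s`.
#'
#' @param d5_surface,d5_deep amplitudes at age 0 and at `age_scale_ka`.
#' @param age_scale_ka age (ka) at which the amplitude saturates.
#' @param r per-position geometric decay ratio, in (0, 1).
#' @param eps background substitution probability per base (at most 0.05).
#' @param single_stranded if `TRUE`, C-to-T at both ends instead of the
#'   double-stranded C-to-T/G-to-A signature.
#' @return list of class `damage_model`.
#' @export
damage_model <- function(d5_surface = 0.03, d5_deep = 0.33,
                         age_scale_ka = 400, r = 0.5, eps = 0.005,
                         single_stranded = FALSE) {
  if (d5_surface < 0 || d5_surface > 1 || d5_deep < 0 || d5_deep > 1) {
    stop("d5 must lie in [0, 1]")
  }
  if (r <= 0 || r >= 1) stop("r must lie in (0, 1)")
  if (eps < 0 || eps > 0.05) stop("eps must lie in [0, 0.05]")
  structure(list(d5_surface = d5_surface, d5_deep = d5_deep,
                 age_scale_ka = age_scale_ka, r = r, eps = eps,
                 single_stranded = single_stranded),
            class = "damage_model")
}

#' Amplitude of the damage model at a given age
#' @param model a `damage_model`.
#' @param age_ka sample age(s) in ka.
#' @return Numeric vector of `d5` amplitudes.
#' @export
damage_d5_at_age <- function(model, age_ka) {
  s <- model$age_scale_ka
  model$d5_surface + (model$d5_deep - model$d5_surface) * pmin(age_ka, s) / s
}

#' Lognormal fragment-length model
#'
#' Parameterised by the distribution mode (default 56 bp, a typical
#' ancient-DNA fragment length) and log-scale spread, truncated below at
#' `min_len` by rejection.
#'
#' @param mode modal fragment length in bp.
#' @param sdlog lognormal log-scale standard deviation.
#' @param min_len hard minimum length (default 20).
#' @return list of class `fragment_model` (carries the implied `meanlog`).
#' @export
fragment_model <- function(mode = 56, sdlog = 0.35, min_len = 20L) {
  if (mode < min_len) stop("fragment mode must be at least min_len")
  structure(list(mode = mode, sdlog = sdlog, min_len = as.integer(min_len),
                 meanlog = log(mode) + sdlog^2),
            class = "fragment_model")
}

#' Draw fragment lengths
#'
#' @param n number of lengths.
#' @param model a [fragment_model()].
#' @param seed optional seed (RNG state restored afterwards).
#' @return Integer lengths, all at least `model$min_len`.
#' @export
simulate_fragment_length <- function(n, model = fragment_model(),
                                     seed = NULL) {
  with_seed(seed, {
    out <- integer(0)
    while (length(out) < n) {
      draw <- as.integer(round(stats::rlnorm(n, model$meanlog, model$sdlog)))
      out <- c(out, draw[draw >= model$min_len])
    }
    out[seq_len(n)]
  })
}

#' Modern-contaminant model
#'
#' Contaminant taxa (by default the fungal species of the built-in
#' taxonomy) are emitted undamaged into sediment samples at rate `rate`
#' and make up the entirety of mudline and control libraries. With
#' `rate = 0` contamination is disabled and control libraries are empty.
#'
#' @param rate fraction of sample reads that are contaminant.
#' @param control_reads library size of each control.
#' @param mudline_reads library size of the mudline sample.
#' @param taxa optional contaminant taxon ids (species level).
#' @return list of class `contaminant_model`.
#' @export
contaminant_model <- function(rate = 0.05, control_reads = 300L,
                              mudline_reads = 200L, taxa = NULL) {
  if (rate < 0 || rate > 1) stop("contaminant rate must lie in [0, 1]")
  structure(list(rate = rate, control_reads = as.integer(control_reads),
                 mudline_reads = as.integer(mudline_reads), taxa = taxa),
            class = "contaminant_model")
}

#' Tracer measurement-run model
#'
#' Emulates one gas-chromatography batch: duplicate blanks, calibrated
#' standards at several nominal levels, and periphery/centre measurements
#' per sediment sample. The default regime has all blanks exactly zero
#' (triggering the lowest-standard fallback when computing detection
#' limits); the lowest-standard replicate spread is chosen so that three
#' times its standard deviation lands near a realistic detection limit of
#' ~0.23 ng/mL.
#'
#' @param n_blanks number of blanks (at least 2).
#' @param blanks_zero if `TRUE` blanks are exactly 0.
#' @param blank_mean,blank_sd blank distribution when not zero.
#' @param standard_levels nominal standard concentrations (ng/mL).
#' @param standard_reps replicates per level (at least 2).
#' @param standard_sd measurement spread of standards.
#' @param isomer_fraction measurable stereoisomer fraction applied to
#'   nominal standard levels (default 0.88).
#' @param noise_sd measurement noise for sample values.
#' @param p_periphery,p_centre probability that a sediment sample has
#'   drill fluid at the core periphery / additionally at the centre.
#' @param periphery_level,centre_level injected true concentrations.
#' @return list of class `tracer_model`.
#' @export
tracer_model <- function(n_blanks = 2L, blanks_zero = TRUE,
                         blank_mean = 0.1, blank_sd = 0.078,
                         standard_levels = c(0.5, 1, 5),
                         standard_reps = 3L, standard_sd = 0.078,
                         isomer_fraction = 0.88, noise_sd = 0.02,
                         p_periphery = 0.6, p_centre = 0.1,
                         periphery_level = 1.2, centre_level = 0.64) {
  if (n_blanks < 2L) stop("at least two blanks per run")
  if (standard_reps < 2L) stop("at least two replicates per standard level")
  structure(list(n_blanks = as.integer(n_blanks), blanks_zero = blanks_zero,
                 blank_mean = blank_mean, blank_sd = blank_sd,
                 standard_levels = standard_levels,
                 standard_reps = as.integer(standard_reps),
                 standard_sd = standard_sd,
                 isomer_fraction = isomer_fraction, noise_sd = noise_sd,
                 p_periphery = p_periphery, p_centre = p_centre,
                 periphery_level = periphery_level,
                 centre_level = centre_level),
            class = "tracer_model")
}

#' Geochemistry generator with target correlations
#'
#' Covariates are generated from a Gaussian model: each column is a linear
#' blend of the standardised damage driver and independent noise so that
#' its population correlation with the driver equals the configured
#' target, then shifted/scaled to a plausible porewater marginal. Default
#' targets follow correlations typical of organic-matter degradation
#' profiles in deep marine cores.
#'
#' @param targets named vector of target Pearson correlations, each in
#'   `(-1, 1)` (exactly +/-1 is allowed and produces an exact linear
#'   copy).
#' @param means,sds marginal means and standard deviations per covariate.
#' @return list of class `geochem_model`.
#' @export
geochem_model <- function(
    targets = c(ammonium = 0.56, alkalinity = 0.52, phosphate = 0.44,
                delta18O = 0.32, temperature = 0.31, silicon = 0.26,
                pH = 0.09, salinity = -0.15, sulfate = -0.42),
    means = c(ammonium = 0.5, alkalinity = 5, phosphate = 0.02,
              delta18O = 4, temperature = 5, silicon = 600,
              pH = 7.8, salinity = 34.7, sulfate = 25),
    sds = c(ammonium = 0.2, alkalinity = 1.5, phosphate = 0.008,
            delta18O = 0.5, temperature = 3, silicon = 150,
            pH = 0.15, salinity = 0.4, sulfate = 3)) {
  if (any(abs(targets) > 1)) stop("target correlations must lie in [-1, 1]")
  stopifnot(all(names(targets) %in% names(means)),
            all(names(targets) %in% names(sds)))
  structure(list(targets = targets, means = means, sds = sds),
            class = "geochem_model")
}

#' Full simulation configuration
#'
#' Bundles the sample sheet, taxonomy, composition/damage/fragment/
#' contaminant/tracer/geochem models, the per-sample library size and the
#' master seed. These defaults constitute the package's reference
#' scenario: a 12-sample core whose diatom fraction steps from 0.08 to
#' 0.50 at 14.5 ka and whose damage amplitude grows from 0.03 near the
#' surface to 0.33 at depth.
#'
#' @param seed master RNG seed.
#' @param samples sample sheet as from [default_samples()].
#' @param taxonomy a `taxonomy` (default [default_taxonomy()]).
#' @param reference optional pre-built `reference_db`; simulated when
#'   `NULL`.
#' @param composition a [composition_model()].
#' @param damage a [damage_model()].
#' @param fragment a [fragment_model()].
#' @param contaminants a [contaminant_model()].
#' @param tracer a [tracer_model()].
#' @param geochem a [geochem_model()].
#' @param library_size reads per sediment sample (default 5000).
#' @param seq_error additional uniform per-base sequencing error.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, samples = default_samples(),
                              taxonomy = default_taxonomy(),
                              reference = NULL,
                              composition = composition_model(),
                              damage = damage_model(),
                              fragment = fragment_model(),
                              contaminants = contaminant_model(),
                              tracer = tracer_model(),
                              geochem = geochem_model(),
                              library_size = 5000L, seq_error = 0) {
  stopifnot(inherits(taxonomy, "taxonomy"),
            inherits(composition, "composition_model"),
            inherits(damage, "damage_model"),
            inherits(fragment, "fragment_model"),
            inherits(contaminants, "contaminant_model"),
            inherits(tracer, "tracer_model"),
            inherits(geochem, "geochem_model"))
  required <- c("sample_id", "site", "depth_mbsf", "age_ka", "type")
  if (!all(required %in% names(samples))) {
    stop("sample sheet needs columns: ", paste(required, collapse = ", "))
  }
  bad_type <- setdiff(samples$type, c("sample", "mudline", "control_air",
                                      "control_ebc", "control_drillfluid"))
  if (length(bad_type) > 0L) stop("unknown sample type: ", bad_type[1L])
  if (seq_error < 0 || seq_error > 0.05) {
    stop("seq_error must lie in [0, 0.05]")
  }
  structure(list(seed = as.integer(seed), samples = samples,
                 taxonomy = taxonomy, reference = reference,
                 composition = composition, damage = damage,
                 fragment = fragment, contaminants = contaminants,
                 tracer = tracer, geochem = geochem,
                 library_size = as.integer(library_size),
                 seq_error = seq_error),
            class = "simulation_config")
}

.random_seq <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

#' Simulate a marker reference database for a taxonomy
#'
#' Every species-level taxon receives an independent random SSU and LSU
#' sequence; photosynthetic groups (diatoms, chlorophytes, cyanobacteria)
#' additionally receive a psbO sequence. Uses the current RNG stream
#' unless `seed` is given.
#'
#' @param tree a `taxonomy`.
#' @param seed optional seed.
#' @param lengths named vector of reference lengths per marker.
#' @param k seed length of the built index.
#' @return A `reference_db`.
#' @export
simulate_reference_db <- function(tree, seed = NULL,
                                  lengths = c(SSU = 600L, LSU = 900L,
                                              psbO = 450L),
                                  k = 12L) {
  with_seed(seed, {
    species <- tree$nodes$taxon_id[tree$nodes$rank == "species"]
    photo_phyla <- tree$nodes$taxon_id[tree$nodes$name %in%
      c("Bacillariophyta", "Chlorophyta", "Cyanobacteria")]
    is_photo <- vapply(species, function(s) {
      any(taxon_ancestors(tree, s) %in% photo_phyla)
    }, TRUE)
    rows <- list()
    for (marker in names(lengths)) {
      who <- if (marker == "psbO") species[is_photo] else species
      if (length(who) == 0L) next
      rows[[marker]] <- data.frame(
        ref_id = sprintf("%s_t%d", marker, who), taxon_id = who,
        marker = marker,
        sequence = .random_seq(length(who), lengths[[marker]]),
        stringsAsFactors = FALSE)
    }
    reference_db(do.call(rbind, rows), tree, k = k)
  })
}

## vectorized damage over a batch of fragments; uses the current RNG
.damage_batch <- function(seqs, d5_per_read, r, eps,
                          single_stranded = FALSE) {
  n <- length(seqs)
  if (n == 0L) return(list(sequence = character(0), positions = list()))
  chars <- strsplit(seqs, "", fixed = TRUE)
  lens <- lengths(chars)
  flat <- unlist(chars, use.names = FALSE)
  ridx <- rep.int(seq_len(n), lens)
  pos5 <- sequence(lens) - 1L
  pos3 <- lens[ridx] - 1L - pos5
  d5v <- d5_per_read[ridx]

  p <- numeric(length(flat))
  isC <- flat == "C"
  isG <- flat == "G"
  if (single_stranded) {
    p[isC] <- pmin(1, d5v[isC] * r^pos5[isC] + d5v[isC] * r^pos3[isC])
  } else {
    p[isC] <- d5v[isC] * r^pos5[isC]
    p[isG] <- d5v[isG] * r^pos3[isG]
  }
  dmg <- stats::runif(length(flat)) < p
  flat[dmg & isC] <- "T"
  if (!single_stranded) flat[dmg & isG] <- "A"

  if (eps > 0) {
    err <- stats::runif(length(flat)) < eps
    if (any(err)) {
      bases <- c("A", "C", "G", "T")
      others <- matrix(c("C", "G", "T",   # alternatives to A
                         "A", "G", "T",   # to C
                         "A", "C", "T",   # to G
                         "A", "C", "G"),  # to T
                       nrow = 4L, byrow = TRUE)
      flat[err] <- others[cbind(match(flat[err], bases),
                                sample.int(3L, sum(err), replace = TRUE))]
    }
  }
  fac <- factor(ridx, levels = seq_len(n))
  list(sequence = vapply(split(flat, fac), paste, character(1),
                         collapse = ""),
       positions = split(pos5[dmg], factor(ridx[dmg], levels = seq_len(n))))
}

#' Apply terminal deamination damage to one fragment
#'
#' Each C at 0-based 5' position `i` flips to T with probability
#' `d5 * r^i`; each G at position `j` from the 3' end flips to A with
#' probability `d5 * r^j` (double-stranded signature). Every base
#' additionally flips uniformly to another base with probability `eps`.
#'
#' @param fragment a single A/C/G/T sequence.
#' @param d5 terminal amplitude in `[0, 1]`.
#' @param r geometric decay ratio in (0, 1).
#' @param eps background substitution probability.
#' @param seed optional seed (RNG state restored afterwards).
#' @param single_stranded C-to-T at both ends instead.
#' @return list(`sequence`, `damage_positions`): the damaged sequence and
#'   the 0-based 5' positions of deamination flips.
#' @export
apply_damage <- function(fragment, d5, r, eps = 0, seed = NULL,
                         single_stranded = FALSE) {
  stopifnot(length(fragment) == 1L, d5 >= 0, d5 <= 1, r > 0, r < 1,
            eps >= 0, eps <= 1)
  with_seed(seed, {
    out <- .damage_batch(fragment, d5, r, eps, single_stranded)
    list(sequence = unname(out$sequence[1L]),
         damage_positions = as.integer(out$positions[[1L]]))
  })
}

.library_size <- function(type, config) {
  cm <- config$contaminants
  disabled <- cm$rate == 0
  switch(type,
         sample = config$library_size,
         mudline = if (disabled) 0L else cm$mudline_reads,
         if (disabled) 0L else cm$control_reads)  # controls
}

#' Simulate one tracer measurement run
#'
#' Draws blanks (exactly zero in the default regime), standard replicate
#' measurements centred on the isomer-calibrated nominal levels, and
#' periphery/centre measurements for each listed sample according to the
#' injected contamination classes.
#'
#' @param model a [tracer_model()].
#' @param samples data.frame with `sample_id` for the sediment samples in
#'   the run.
#' @param run_id,site labels for the run.
#' @param seed optional seed.
#' @return list(`run` = a `tracer_run`, `truth` = data.frame of injected
#'   classes (`clean`, `periphery`, `centre`) per sample).
#' @export
simulate_tracer_run <- function(model, samples, run_id = "run1",
                                site = "SITE1", seed = NULL) {
  stopifnot(inherits(model, "tracer_model"))
  with_seed(seed, {
    blanks <- if (model$blanks_zero) {
      rep(0, model$n_blanks)
    } else {
      pmax(0, stats::rnorm(model$n_blanks, model$blank_mean, model$blank_sd))
    }
    std <- do.call(rbind, lapply(model$standard_levels, function(lv) {
      data.frame(nominal_level = lv,
                 value = pmax(0, stats::rnorm(
                   model$standard_reps,
                   isomer_calibrate(lv, model$isomer_fraction),
                   model$standard_sd)),
                 stringsAsFactors = FALSE)
    }))
    n <- nrow(samples)
    cls <- ifelse(stats::runif(n) < model$p_periphery,
                  ifelse(stats::runif(n) < model$p_centre / model$p_periphery,
                         "centre", "periphery"),
                  "clean")
    true_peri <- ifelse(cls == "clean", 0, model$periphery_level)
    true_cent <- ifelse(cls == "centre", model$centre_level, 0)
    meas <- rbind(
      data.frame(sample_id = samples$sample_id, location = "periphery",
                 value = pmax(0, true_peri + stats::rnorm(n, 0, model$noise_sd)),
                 stringsAsFactors = FALSE),
      data.frame(sample_id = samples$sample_id, location = "centre",
                 value = pmax(0, true_cent + stats::rnorm(n, 0, model$noise_sd)),
                 stringsAsFactors = FALSE))
    list(run = tracer_run(run_id = run_id, site = site, blanks = blanks,
                          standards = std, measurements = meas),
         truth = data.frame(sample_id = samples$sample_id, class = cls,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate geochemical covariates against a damage driver
#'
#' Each covariate is `mean + sd * (rho * z + sqrt(1 - rho^2) * noise)`
#' where `z` is the standardised driver, so its population correlation
#' with the driver is exactly the configured target. Targets of exactly
#' +/-1 produce exact linear copies.
#'
#' @param model a [geochem_model()].
#' @param driver numeric damage driver, one value per sample (must not be
#'   constant).
#' @param seed optional seed.
#' @return data.frame of covariate columns, one row per driver value.
#' @export
simulate_geochem <- function(model, driver, seed = NULL) {
  stopifnot(inherits(model, "geochem_model"))
  if (stats::sd(driver) == 0) stop("damage driver is constant")
  with_seed(seed, {
    z <- as.numeric(scale(driver))
    n <- length(driver)
    out <- lapply(names(model$targets), function(v) {
      rho <- model$targets[[v]]
      zz <- if (abs(rho) == 1) {
        sign(rho) * z
      } else {
        rho * z + sqrt(1 - rho^2) * stats::rnorm(n)
      }
      model$means[[v]] + model$sds[[v]] * zz
    })
    names(out) <- names(model$targets)
    as.data.frame(out)
  })
}

#' Simulate a full sediment core with ground truth
#'
#' Deterministic given the config seed. Emits per-sample read libraries
#' (sediment samples mix community reads carrying age-graded terminal
#' damage with undamaged contaminants; mudline and control libraries
#' contain only contaminants), a per-read truth table, tracer runs with
#' injected contamination classes, and geochemistry correlated with the
#' per-sample damage amplitude.
#'
#' @param config a [simulation_config()].
#' @return list of class `seda_sim` with elements `reads`, `truth_reads`,
#'   `truth_samples`, `tracer` (list of runs), `tracer_truth`, `geochem`,
#'   `reference`, `taxonomy`, `config`.
#' @export
simulate_core <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  tree <- config$taxonomy
  db <- if (is.null(config$reference)) {
    simulate_reference_db(tree)
  } else config$reference

  species <- tree$nodes$taxon_id[tree$nodes$rank == "species"]
  species <- intersect(species, unique(db$sequences$taxon_id))
  diatom_phylum <- tree$nodes$taxon_id[tree$nodes$name == "Bacillariophyta"]
  is_diatom <- vapply(species, function(s) {
    length(diatom_phylum) == 1L &&
      diatom_phylum %in% taxon_ancestors(tree, s)
  }, TRUE)
  fungal_phyla <- tree$nodes$taxon_id[tree$nodes$name %in%
    c("Ascomycota", "Basidiomycota")]
  cont_taxa <- config$contaminants$taxa
  if (is.null(cont_taxa)) {
    cont_taxa <- species[vapply(species, function(s) {
      any(taxon_ancestors(tree, s) %in% fungal_phyla)
    }, TRUE)]
  }
  bacteria <- tree$nodes$taxon_id[tree$nodes$name == "Bacteria"]
  is_euk_other <- !is_diatom & !(species %in% cont_taxa) &
    !vapply(species, function(s) {
      length(bacteria) == 1L && bacteria %in% taxon_ancestors(tree, s)
    }, TRUE)
  other_taxa <- species[is_euk_other]
  diatom_taxa <- species[is_diatom]
  if (length(diatom_taxa) == 0L || length(other_taxa) == 0L) {
    stop("taxonomy/reference must provide diatom and non-diatom species")
  }
  ow <- config$composition$other_weights
  if (is.null(ow)) {
    ow <- stats::setNames(rep(1 / length(other_taxa), length(other_taxa)),
                          as.character(other_taxa))
  } else {
    .check_taxa(tree, as.integer(names(ow)))
    other_taxa <- as.integer(names(ow))
  }

  ref_by_taxon <- split(seq_len(nrow(db$sequences)),
                        db$sequences$taxon_id)
  ## contaminants and community reads are drawn from non-psbO markers so
  ## SSU/LSU profiles carry the composition signal
  ref_by_taxon <- lapply(ref_by_taxon, function(idx) {
    keep <- db$sequences$marker[idx] != "psbO"
    if (any(keep)) idx[keep] else idx
  })

  reads <- list(); truths <- list()
  samp <- config$samples
  d5_sample <- rep(NA_real_, nrow(samp))
  p_diatom_sample <- rep(NA_real_, nrow(samp))
  for (si in seq_len(nrow(samp))) {
    type <- samp$type[si]
    sid <- samp$sample_id[si]
    n <- .library_size(type, config)
    if (type == "sample") {
      p_diatom <- if (samp$age_ka[si] > config$composition$t_star) {
        config$composition$p_pre
      } else config$composition$p_post
      d5 <- damage_d5_at_age(config$damage, samp$age_ka[si])
      d5_sample[si] <- d5
      p_diatom_sample[si] <- p_diatom
    }
    if (n == 0L) next
    if (type == "sample") {
      is_cont <- stats::runif(n) < config$contaminants$rate
      n_comm <- sum(!is_cont)
      src <- integer(n)
      if (n_comm > 0L) {
        probs <- c(rep(p_diatom / length(diatom_taxa), length(diatom_taxa)),
                   (1 - p_diatom) * unname(ow))
        src[!is_cont] <- sample(c(diatom_taxa, other_taxa), n_comm,
                                replace = TRUE, prob = probs)
      }
      if (any(is_cont)) {
        src[is_cont] <- sample(cont_taxa, sum(is_cont), replace = TRUE)
      }
      d5_read <- ifelse(is_cont, 0, d5)
    } else {
      is_cont <- rep(TRUE, n)
      src <- sample(cont_taxa, n, replace = TRUE)
      d5_read <- rep(0, n)
    }
    flen <- simulate_fragment_length(n, config$fragment)
    frag <- character(n)
    for (i in seq_len(n)) {
      ridx <- ref_by_taxon[[as.character(src[i])]]
      ri <- if (length(ridx) == 1L) ridx else ridx[sample.int(length(ridx), 1L)]
      rs <- db$sequences$sequence[ri]
      L <- nchar(rs)
      fl <- min(flen[i], L)
      start <- sample.int(L - fl + 1L, 1L)
      frag[i] <- substr(rs, start, start + fl - 1L)
    }
    minus <- stats::runif(n) < 0.5
    frag[minus] <- rev_comp(frag[minus])
    dmg <- .damage_batch(frag, d5_read, config$damage$r, config$damage$eps,
                         config$damage$single_stranded)
    seqs <- unname(dmg$sequence)
    if (config$seq_error > 0) {
      se <- .damage_batch(seqs, rep(0, n), config$damage$r,
                          config$seq_error, FALSE)
      seqs <- unname(se$sequence)
    }
    read_id <- sprintf("%s_r%05d", sid, seq_len(n))
    reads[[sid]] <- data.frame(read_id = read_id, sample_id = sid,
                               sequence = seqs, stringsAsFactors = FALSE)
    truths[[sid]] <- data.frame(
      read_id = read_id, sample_id = sid, source_taxon = src,
      is_contaminant = is_cont,
      damage_positions = vapply(dmg$positions, paste, character(1),
                                collapse = ","),
      fragment = frag, frag_len = nchar(frag), stringsAsFactors = FALSE)
  }
  reads <- do.call(rbind, reads)
  truth_reads <- do.call(rbind, truths)
  rownames(reads) <- rownames(truth_reads) <- NULL

  truth_samples <- cbind(samp,
                         d5 = d5_sample, p_diatom = p_diatom_sample,
                         library_size = vapply(samp$type, .library_size,
                                               integer(1), config = config))

  sed <- samp[samp$type == "sample", , drop = FALSE]
  tracer <- list(); tracer_truth <- NULL
  geochem <- NULL
  if (nrow(sed) > 0L) {
    for (site in unique(sed$site)) {
      tr <- simulate_tracer_run(config$tracer,
                                sed[sed$site == site, , drop = FALSE],
                                run_id = paste0("run_", site), site = site)
      tracer[[site]] <- tr$run
      tracer_truth <- rbind(tracer_truth, tr$truth)
    }
    driver <- d5_sample[samp$type == "sample"]
    if (length(driver) >= 3L && !is.na(stats::sd(driver)) &&
        stats::sd(driver) > 0) {
      geochem <- cbind(
        data.frame(sample_id = sed$sample_id,
                   depth_mbsf = sed$depth_mbsf, age_ka = sed$age_ka,
                   stringsAsFactors = FALSE),
        simulate_geochem(config$geochem, driver))
    }
  }

  structure(list(reads = reads, truth_reads = truth_reads,
                 truth_samples = truth_samples, tracer = tracer,
                 tracer_truth = tracer_truth, geochem = geochem,
                 reference = db, taxonomy = tree, config = config),
            class = "seda_sim")
}

#' @export
print.seda_sim <- function(x, ...) {
  cat("<seda_sim> ", nrow(x$reads), " reads across ",
      length(unique(x$reads$sample_id)), " libraries; seed = ",
      x$config$seed, "\n", sep = "")
  invisible(x)
}

#' Write a simulated core to disk
#'
#' One FASTQ per library (Phred 33, constant quality), plus TSV truth
#' tables, sample sheet, tracer tables and geochemistry.
#'
#' @param sim a `seda_sim` from [simulate_core()].
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_core <- function(sim, dir) {
  stopifnot(inherits(sim, "seda_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sid in unique(sim$reads$sample_id)) {
    r <- sim$reads[sim$reads$sample_id == sid, , drop = FALSE]
    qual <- vapply(nchar(r$sequence),
                   function(L) paste(rep("I", L), collapse = ""), character(1))
    writeLines(as.vector(rbind(paste0("@", r$read_id), r$sequence,
                               "+", qual)),
               file.path(dir, paste0(sid, ".fastq")))
  }
  tsv <- function(x, name) {
    utils::write.table(x, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  tsv(sim$truth_reads, "truth_reads.tsv")
  tsv(sim$truth_samples, "truth_samples.tsv")
  if (!is.null(sim$tracer_truth)) tsv(sim$tracer_truth, "tracer_truth.tsv")
  if (!is.null(sim$geochem)) tsv(sim$geochem, "geochem.tsv")
  for (site in names(sim$tracer)) {
    tsv(tracer_run_table(sim$tracer[[site]]),
        paste0("tracer_", site, ".tsv"))
  }
  write_reference_fasta(sim$reference, file.path(dir, "reference.fasta"))
  write_taxonomy(sim$taxonomy, file.path(dir, "taxonomy.tsv"))
  invisible(dir)
}

#' Read a FASTQ library into the package's read table
#'
#' @param path FASTQ file.
#' @param sample_id sample label attached to the reads.
#' @return data.frame `read_id`, `sample_id`, `sequence`.
#' @export
read_fastq <- function(path, sample_id) {
  seqs <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(read_id = sub("\\s.*$", "", names(seqs)),
             sample_id = sample_id, sequence = as.character(seqs),
             stringsAsFactors = FALSE)
}
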