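#!/usr/bin/env Rscript
# Stage 7: abundance and correlation statistics - phylum-level relative
# abundances with rare-taxon grouping, the diatom step change across the
# 14.5 ka boundary, marker-restricted profile comparisons (SSU vs LSU vs
# combined), and Pearson correlations of damage against geochemistry.

library(sedapipe)

tree <- load_taxonomy("results/01_core/taxonomy.tsv")
meta <- read.delim("results/01_core/truth_samples.tsv",
                   stringsAsFactors = FALSE)
prof_tab <- read.delim("results/04_subtract/profile_subtracted.tsv",
                       check.names = FALSE, stringsAsFactors = FALSE)
profile <- as.matrix(prof_tab[, -1, drop = FALSE])
rownames(profile) <- prof_tab$sample_id
storage.mode(profile) <- "integer"
class(profile) <- c("taxon_profile", class(profile))

phylum <- project_rank(profile, tree, "phylum")
rel <- relative_abundance(phylum)
rel_grouped <- group_rare(rel)

dir.create("results/07_stats", showWarnings = FALSE)
write.table(data.frame(sample_id = rownames(rel_grouped), rel_grouped,
                       check.names = FALSE),
            "results/07_stats/relative_abundance_phylum.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

## diatom step change across the dated boundary
diatom_id <- as.character(
  tree$nodes$taxon_id[tree$nodes$name == "Bacillariophyta"])
sed <- meta[meta$type == "sample", ]
frac <- if (diatom_id %in% colnames(rel)) rel[sed$sample_id, diatom_id] else 0
tab <- data.frame(sample_id = sed$sample_id, age_ka = sed$age_ka,
                  diatom_fraction = frac)
write.table(tab, "results/07_stats/diatom_fraction.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
older <- tab$diatom_fraction[tab$age_ka > 14.5]
younger <- tab$diatom_fraction[tab$age_ka <= 14.5]
message(sprintf(
  "diatom relative abundance: %.1f%% before 14.5 ka -> %.1f%% after",
  100 * mean(older), 100 * mean(younger)))

## marker-restricted profiles: SSU vs LSU vs combined
best <- read.delim("results/03_align/best_hits.tsv",
                   stringsAsFactors = FALSE)
reads <- read.delim("results/02_qc/reads_retained.tsv",
                    stringsAsFactors = FALSE)
hits_all <- read.delim("results/03_align/best_hits.tsv",
                       stringsAsFactors = FALSE)
marker_rel <- function(marker) {
  h <- if (identical(marker, "all")) hits_all else
    hits_all[hits_all$marker == marker, , drop = FALSE]
  asg <- assign_reads(reads, h, tree)
  p <- project_rank(build_profile(asg, tree,
                                  samples = unique(reads$sample_id)),
                    tree, "phylum")
  relative_abundance(p)
}
rel_ssu <- marker_rel("SSU")
rel_lsu <- marker_rel("LSU")
rel_both <- marker_rel("all")
pairs <- list(ssu_lsu = regress_between_tables(rel_ssu, rel_lsu),
              ssu_combined = regress_between_tables(rel_ssu, rel_both),
              lsu_combined = regress_between_tables(rel_lsu, rel_both))
reg <- data.frame(pair = names(pairs),
                  r = vapply(pairs, `[[`, numeric(1), "r"),
                  r_squared = vapply(pairs, `[[`, numeric(1), "r_squared"),
                  n_taxa = vapply(pairs, `[[`, numeric(1), "n_taxa"))
write.table(reg, "results/07_stats/marker_regressions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("marker profile agreement (R^2): SSU~LSU %.2f, SSU~both %.2f, LSU~both %.2f",
                reg$r_squared[1L], reg$r_squared[2L], reg$r_squared[3L]))

## damage vs geochemistry
geochem <- read.delim("results/01_core/geochem.tsv",
                      stringsAsFactors = FALSE)
dmg <- read.delim("results/05_damage/damage_by_sample.tsv",
                  stringsAsFactors = FALSE)
x <- data.frame(damage_proportion = dmg$proportion[
  match(geochem$sample_id, dmg$sample_id)])
cors <- pearson_matrix(x, geochem[!names(geochem) %in%
                                    c("sample_id", "depth_mbsf")])
write.table(cors, "results/07_stats/correlations.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
top <- cors[order(-abs(cors$r)), ]
message("strongest damage correlates: ",
        paste(sprintf("%s (r = %.2f)", top$var2[1:3], top$r[1:3]),
              collapse = ", "))
message("statistics written to results/07_stats/")
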