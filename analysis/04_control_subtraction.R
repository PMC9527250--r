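#!/usr/bin/env Rscript
# Stage 4: remove putative contaminants - every taxon seen in the
# extraction-blank, air or drill-fluid controls is zeroed in the sediment
# samples of the same site (conservative whole-taxon mode).

library(sedapipe)

meta <- read.delim("results/01_core/truth_samples.tsv",
                   stringsAsFactors = FALSE)
prof_tab <- read.delim("results/03_align/profile_counts.tsv",
                       check.names = FALSE, stringsAsFactors = FALSE)
profile <- as.matrix(prof_tab[, -1, drop = FALSE])
rownames(profile) <- prof_tab$sample_id
storage.mode(profile) <- "integer"

ctrl <- meta$sample_id[meta$type %in%
  c("control_air", "control_ebc", "control_drillfluid")]
samp <- setdiff(rownames(profile), ctrl)
site_of <- setNames(meta$site, meta$sample_id)

out <- subtract_controls(profile[samp, , drop = FALSE],
                         profile[intersect(ctrl, rownames(profile)), ,
                                 drop = FALSE],
                         sample_sites = site_of[samp],
                         control_sites = site_of[intersect(ctrl,
                                                           rownames(profile))])

dir.create("results/04_subtract", showWarnings = FALSE)
write.table(data.frame(sample_id = rownames(out$profile), out$profile,
                       check.names = FALSE),
            "results/04_subtract/profile_subtracted.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(out$report, "results/04_subtract/subtraction_report.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(out$contaminants, "results/04_subtract/contaminant_taxa.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

message(sprintf("control-derived contaminant taxa: %d; reads removed: %d",
                nrow(out$contaminants), sum(out$report$count_removed)))
message("subtraction tables written to results/04_subtract/")
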