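#!/usr/bin/env Rscript
# Stage 5: damage authentication - positional C->T / G->A substitution
# spectra on best-hit alignments (post subtraction), per-read
# ancient/default classification, per-sample damage proportions, and the
# geometric decay-model fit.

library(sedapipe)

meta <- read.delim("results/01_core/truth_samples.tsv",
                   stringsAsFactors = FALSE)
best <- read.delim("results/03_align/best_hits.tsv",
                   stringsAsFactors = FALSE)
assignments <- read.delim("results/03_align/assignments.tsv",
                          stringsAsFactors = FALSE)
contam <- read.delim("results/04_subtract/contaminant_taxa.tsv",
                     stringsAsFactors = FALSE)

sed <- meta$sample_id[meta$type == "sample"]
best <- best[best$sample_id %in% sed, , drop = FALSE]
asg <- setNames(as.character(assignments$taxon_id), assignments$read_id)
keep <- !(asg[best$read_id] %in% as.character(contam$taxon_id))
keep[is.na(keep)] <- TRUE
best <- best[keep, , drop = FALSE]

spectrum <- substitution_spectrum(best)
fit <- fit_decay(spectrum)
calls <- classify_reads(best)
by_sample <- damage_proportion(calls, by = "sample_id")
by_taxon <- damage_proportion(calls)

dir.create("results/05_damage", showWarnings = FALSE)
write.table(data.frame(position = seq_len(spectrum$m) - 1L,
                       f5 = spectrum$f5, n5 = spectrum$n5,
                       f3 = spectrum$f3, n3 = spectrum$n3),
            "results/05_damage/spectrum.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(calls, "results/05_damage/read_calls.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(by_sample, "results/05_damage/damage_by_sample.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(by_taxon, "results/05_damage/damage_by_taxon.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

message(sprintf("decay fit: d = %.3f, r = %.3f, background = %.4f",
                fit$d_hat, fit$r_hat, fit$eps_hat))
ord <- order(meta$age_ka[match(by_sample$sample_id, meta$sample_id)])
message("damage proportion by sample (young -> old): ",
        paste(sprintf("%.1f%%", 100 * by_sample$proportion[ord]),
              collapse = " "))
rho <- cor(by_sample$proportion,
           meta$age_ka[match(by_sample$sample_id, meta$sample_id)],
           method = "spearman")
message(sprintf("Spearman(damage proportion, age) = %.3f", rho))
message("damage tables written to results/05_damage/")
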