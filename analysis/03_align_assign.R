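#!/usr/bin/env Rscript
# Stage 3: seed-and-extend semiglobal alignment of the QC'd reads against
# the merged marker reference (95% identity, 10% score window), naive-LCA
# assignment, and the sample x taxon count profile.

library(sedapipe)

tree <- load_taxonomy("results/01_core/taxonomy.tsv")
db <- read_reference_fasta("results/01_core/reference.fasta", tree)
reads <- read.delim("results/02_qc/reads_retained.tsv",
                    stringsAsFactors = FALSE)

hits <- align_reads(reads, db)
assignments <- assign_reads(reads, hits, tree)
profile <- build_profile(assignments, tree,
                         samples = unique(reads$sample_id))
best <- best_hits(hits)

dir.create("results/03_align", showWarnings = FALSE)
write.table(assignments, "results/03_align/assignments.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(best, "results/03_align/best_hits.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(sample_id = rownames(profile), profile,
                       check.names = FALSE),
            "results/03_align/profile_counts.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

message(sprintf("aligned %d of %d reads; %d assigned (%.1f%%), %d taxa",
                length(unique(hits$read_id)), nrow(reads),
                sum(!is.na(assignments$taxon_id)),
                100 * mean(!is.na(assignments$taxon_id)), ncol(profile)))
message("alignment tables written to results/03_align/")
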