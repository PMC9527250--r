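#!/usr/bin/env Rscript
# Stage 2: read filtering - minimum length 25 bp, distinct-k-mer
# complexity >= 0.55 (k = 4), exact per-library deduplication - with a
# per-library accounting report.

library(sedapipe)

fq <- list.files("results/01_core", pattern = "\\.fastq$",
                 full.names = TRUE)
reads <- do.call(rbind, lapply(fq, function(f) {
  read_fastq(f, sub("\\.fastq$", "", basename(f)))
}))

qc <- qc_reads(reads)
dir.create("results/02_qc", showWarnings = FALSE)
write.table(qc$report, "results/02_qc/qc_report.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(qc$reads, "results/02_qc/reads_retained.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

r <- qc$report
message(sprintf(
  "input %d | removed: %d short, %d low-complexity, %d duplicate | retained %d (%.1f%%)",
  sum(r$input), sum(r$removed_short), sum(r$removed_low_complexity),
  sum(r$removed_duplicate), sum(r$retained),
  100 * sum(r$retained) / sum(r$input)))
stopifnot(identical(r$input, r$removed_short + r$removed_low_complexity +
                      r$removed_duplicate + r$retained))
message("QC tables written to results/02_qc/")
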