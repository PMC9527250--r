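#' Length filter
#'
#' Removes reads shorter than `min_len` (a read of exactly `min_len`
#' bases is retained). Input order is preserved.
#'
#' @param reads data.frame with at least a `sequence` column.
#' @param min_len minimum retained length (default 25).
#' @return list(`reads`, `removed`): retained reads and removed count.
#' @export
filter_length <- function(reads, min_len = 25L) {
  stopifnot(min_len >= 1L)
  keep <- nchar(reads$sequence) >= min_len
  list(reads = reads[keep, , drop = FALSE], removed = sum(!keep))
}

#' Distinct k-mer complexity score
#'
#' Score = distinct k-mers / k-mer windows. Windows containing `N` are
#' excluded from both numerator and denominator. Sequences too short to
#' hold a single window pass with score 1 and a warning, as do sequences
#' whose windows are all ambiguous. A homopolymer of length L scores
#' `1 / (L - k + 1)`; a sequence with all windows distinct scores 1.
#'
#' @param sequence character vector of sequences.
#' @param k window size (default 4).
#' @return Numeric vector of scores in `[0, 1]`.
#' @export
complexity_score <- function(sequence, k = 4L) {
  stopifnot(k >= 1L)
  vapply(sequence, function(s) {
    L <- nchar(s)
    if (L < k) {
      warning("sequence shorter than k = ", k, "; passes with score 1")
      return(1)
    }
    starts <- seq_len(L - k + 1L)
    kms <- substring(s, starts, starts + k - 1L)
    kms <- kms[!grepl("N", kms, fixed = TRUE)]
    if (length(kms) == 0L) {
      warning("all k-mer windows ambiguous; passes with score 1")
      return(1)
    }
    length(unique(kms)) / length(kms)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Low-complexity filter
#'
#' Retains reads whose [complexity_score()] is at least `threshold`
#' (a score of exactly the threshold is retained).
#'
#' @param reads data.frame with a `sequence` column.
#' @param threshold minimum score (default 0.55).
#' @param k window size passed to [complexity_score()].
#' @return list(`reads`, `removed`).
#' @export
filter_complexity <- function(reads, threshold = 0.55, k = 4L) {
  stopifnot(threshold >= 0, threshold <= 1)
  keep <- complexity_score(reads$sequence, k = k) >= threshold
  list(reads = reads[keep, , drop = FALSE], removed = sum(!keep))
}

#' Exact deduplication within samples
#'
#' Collapses reads with identical sequences within a sample to the first
#' occurrence in input order. Identical sequences in different samples are
#' all retained (per-library scope).
#'
#' @param reads data.frame with `sample_id` and `sequence` columns.
#' @return list(`reads`, `removed`).
#' @export
deduplicate <- function(reads) {
  keep <- !duplicated(paste(reads$sample_id, reads$sequence, sep = "\r"))
  list(reads = reads[keep, , drop = FALSE], removed = sum(!keep))
}

#' Full read-filtering chain with per-sample accounting
#'
#' Applies, in this fixed order: length filter, low-complexity filter,
#' exact per-sample deduplication. The chain is idempotent. The report
#' satisfies `input == removed_short + removed_low_complexity +
#' removed_duplicate + retained` for every sample.
#'
#' @param reads data.frame with `read_id`, `sample_id`, `sequence`.
#' @param min_len length cutoff (default 25).
#' @param complexity_threshold score cutoff (default 0.55).
#' @param complexity_k window size (default 4).
#' @return list(`reads` = retained reads, `report` = per-sample QC count
#'   data.frame).
#' @export
qc_reads <- function(reads, min_len = 25L, complexity_threshold = 0.55,
                     complexity_k = 4L) {
  samples <- unique(reads$sample_id)
  count_by <- function(r) {
    as.integer(table(factor(r$sample_id, levels = samples)))
  }
  input <- count_by(reads)
  st1 <- filter_length(reads, min_len = min_len)
  after1 <- count_by(st1$reads)
  st2 <- filter_complexity(st1$reads, threshold = complexity_threshold,
                           k = complexity_k)
  after2 <- count_by(st2$reads)
  st3 <- deduplicate(st2$reads)
  retained <- count_by(st3$reads)
  report <- data.frame(
    sample_id = samples,
    input = input,
    removed_short = input - after1,
    removed_low_complexity = after1 - after2,
    removed_duplicate = after2 - retained,
    retained = retained,
    stringsAsFactors = FALSE
  )
  list(reads = st3$reads, report = report)
}
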