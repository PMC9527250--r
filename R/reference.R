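#' Marker labels accepted for reference sequences
#' @keywords internal
MARKER_LABELS <- c("SSU", "LSU", "psbO", "other")

#' Reverse-complement DNA strings
#'
#' @param x character vector of A/C/G/T sequences.
#' @return Character vector of reverse complements.
#' @export
rev_comp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

.build_kmer_index <- function(seqs, k) {
  index <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    L <- nchar(s)
    if (L < k) next
    starts <- seq_len(L - k + 1L)
    kms <- substring(s, starts, starts + k - 1L)
    by_km <- split(starts, kms)
    for (km in names(by_km)) {
      post <- cbind(i, by_km[[km]])
      index[[km]] <- if (is.null(index[[km]])) post else rbind(index[[km]], post)
    }
  }
  index
}

#' Build a k-mer indexed marker reference database
#'
#' Validates taxon-labelled reference sequences against a taxonomy and
#' indexes the forward strand with exact k-mers (queries are searched on
#' both strands at alignment time). Sequences containing ambiguity codes
#' (anything outside A/C/G/T after upper-casing) are rejected at load with
#' a single warning reporting how many were dropped; sequences shorter
#' than 50 bp are an error.
#'
#' @param sequences data.frame with columns `ref_id`, `taxon_id`,
#'   `marker` (one of SSU, LSU, psbO, other) and `sequence`.
#' @param tree the `taxonomy` the labels refer to.
#' @param k seed length for the k-mer index (default 12).
#' @return An object of class `reference_db`.
#' @export
reference_db <- function(sequences, tree, k = 12L) {
  stopifnot(inherits(tree, "taxonomy"))
  required <- c("ref_id", "taxon_id", "marker", "sequence")
  missing_cols <- setdiff(required, names(sequences))
  if (length(missing_cols) > 0L) {
    stop("reference table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  sequences <- as.data.frame(sequences)[required]
  sequences$ref_id <- as.character(sequences$ref_id)
  sequences$taxon_id <- as.integer(sequences$taxon_id)
  sequences$marker <- as.character(sequences$marker)
  sequences$sequence <- toupper(as.character(sequences$sequence))

  if (anyDuplicated(sequences$ref_id)) {
    stop("duplicate ref_id in reference set")
  }
  bad_marker <- setdiff(unique(sequences$marker), MARKER_LABELS)
  if (length(bad_marker) > 0L) {
    stop("unknown marker label(s): ", paste(bad_marker, collapse = ", "))
  }
  .check_taxa(tree, unique(sequences$taxon_id))

  ambiguous <- grepl("[^ACGT]", sequences$sequence)
  if (any(ambiguous)) {
    warning(sum(ambiguous),
            " reference sequence(s) with ambiguity codes rejected at load")
    sequences <- sequences[!ambiguous, , drop = FALSE]
  }
  if (any(nchar(sequences$sequence) < 50L)) {
    stop("reference sequences must be at least 50 bp")
  }
  rownames(sequences) <- NULL

  structure(
    list(sequences = sequences, taxonomy = tree, k = as.integer(k),
         index = .build_kmer_index(sequences$sequence, k)),
    class = "reference_db"
  )
}

#' @export
print.reference_db <- function(x, ...) {
  cat("<reference_db> ", nrow(x$sequences), " sequences (",
      paste(sprintf("%s: %d", names(table(x$sequences$marker)),
                    as.integer(table(x$sequences$marker))), collapse = ", "),
      "), k = ", x$k, "\n", sep = "")
  invisible(x)
}

#' Read a taxon-labelled marker FASTA into a reference database
#'
#' Headers follow the convention
#' `>ref_id taxid=<int> marker=<SSU|LSU|psbO|other>`.
#'
#' @param path FASTA file path.
#' @param tree the `taxonomy` the taxid labels refer to.
#' @param k seed length for the index.
#' @return A `reference_db`.
#' @export
read_reference_fasta <- function(path, tree, k = 12L) {
  seqs <- Biostrings::readDNAStringSet(path)
  headers <- names(seqs)
  ref_id <- sub("\\s.*$", "", headers)
  taxid <- suppressWarnings(
    as.integer(sub(".*taxid=([0-9]+).*", "\\1", headers))
  )
  marker <- sub(".*marker=([A-Za-z]+).*", "\\1", headers)
  if (anyNA(taxid)) {
    stop("FASTA header(s) missing taxid= field")
  }
  reference_db(
    data.frame(ref_id = ref_id, taxon_id = taxid, marker = marker,
               sequence = as.character(seqs), stringsAsFactors = FALSE),
    tree, k = k
  )
}

#' Write a reference database as a labelled FASTA
#'
#' @param db a `reference_db`.
#' @param path output FASTA path.
#' @export
write_reference_fasta <- function(db, path) {
  stopifnot(inherits(db, "reference_db"))
  seqs <- Biostrings::DNAStringSet(db$sequences$sequence)
  names(seqs) <- sprintf("%s taxid=%d marker=%s", db$sequences$ref_id,
                         db$sequences$taxon_id, db$sequences$marker)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Merge several reference databases into one
#'
#' All inputs must share one taxonomy. `ref_id` collisions across inputs
#' are resolved by prefixing the colliding ids with their marker label;
#' the k-mer index is rebuilt for the union.
#'
#' @param dbs list of `reference_db` objects.
#' @return A merged `reference_db` whose sequence count is the sum of the
#'   inputs'.
#' @export
merge_databases <- function(dbs) {
  stopifnot(length(dbs) >= 1L, all(vapply(dbs, inherits, TRUE, "reference_db")))
  tree <- dbs[[1L]]$taxonomy
  same <- vapply(dbs, function(d) identical(d$taxonomy$nodes, tree$nodes), TRUE)
  if (!all(same)) stop("reference databases built on conflicting taxonomies")

  tabs <- lapply(dbs, function(d) d$sequences)
  all_ids <- unlist(lapply(tabs, `[[`, "ref_id"), use.names = FALSE)
  clashes <- unique(all_ids[duplicated(all_ids)])
  if (length(clashes) > 0L) {
    tabs <- lapply(tabs, function(tab) {
      hit <- tab$ref_id %in% clashes
      tab$ref_id[hit] <- paste(tab$marker[hit], tab$ref_id[hit], sep = ":")
      tab
    })
  }
  merged <- do.call(rbind, tabs)
  reference_db(merged, tree, k = dbs[[1L]]$k)
}
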