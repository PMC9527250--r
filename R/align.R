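#' Alignment scoring parameters
#'
#' Linear gap scoring used by the semiglobal aligner. `min_seed` is the
#' number of exact shared k-mers (on either strand) a reference must share
#' with a read to be extended.
#'
#' @param match,mismatch,gap integer scores (gap is the per-column gap
#'   penalty, negative).
#' @param min_seed minimum number of shared k-mers.
#' @return A list of class `align_params`.
#' @export
align_params <- function(match = 1L, mismatch = -1L, gap = -2L, min_seed = 1L) {
  stopifnot(match > 0L, mismatch < match, gap < 0L, min_seed >= 1L)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap = as.integer(gap), min_seed = as.integer(min_seed)),
            class = "align_params")
}

## per reference: number of distinct read k-mers shared (either value is
## what min_seed gates on) and the reference offset range of the matches,
## used to window the dynamic programming
.seed_counts <- function(seq, db) {
  k <- db$k
  L <- nchar(seq)
  if (L < k) return(NULL)
  starts <- seq_len(L - k + 1L)
  kms <- unique(substring(seq, starts, starts + k - 1L))
  posts <- mget(kms, envir = db$index, ifnotfound = list(NULL))
  posts <- posts[!vapply(posts, is.null, TRUE)]
  if (length(posts) == 0L) return(NULL)
  m <- do.call(rbind, posts)
  refv <- m[, 1L]
  offv <- m[, 2L]
  km_id <- rep.int(seq_along(posts), vapply(posts, nrow, integer(1)))
  distinct <- !duplicated(km_id * 1e7 + refv)
  cand <- unique(refv)
  count <- tabulate(refv[distinct])[cand]
  lo <- vapply(cand, function(r) min(offv[refv == r]), numeric(1))
  hi <- vapply(cand, function(r) max(offv[refv == r]), numeric(1))
  list(ref = cand, count = count, lo = lo, hi = hi)
}

.rev_orient <- function(ref_aligned) {
  ## convert a ref_aligned string recorded against the reverse-complemented
  ## read back into original read orientation: reverse and complement
  ## (gaps stay gaps)
  chars <- rev(strsplit(ref_aligned, "", fixed = TRUE)[[1L]])
  paste(chartr("ACGT", "TGCA", chars), collapse = "")
}

#' Align one read against a k-mer indexed reference database
#'
#' Seed-and-extend: every reference sharing at least `min_seed` exact
#' k-mers with the read (on either strand) is aligned by semiglobal
#' dynamic programming (read global, reference local). For each reference
#' the better strand is kept (ties resolve to `+`). Hits are sorted by
#' score descending, ties broken by `ref_id`.
#'
#' Mismatch positions are recorded in read orientation: `ref_aligned`
#' gives, for each 0-based read position from the 5' end, the reference
#' base aligned to it (or `-` for an insertion). For minus-strand hits
#' bases are complemented back, so a genomic C-to-T deamination on the
#' opposite strand surfaces as G-to-A at the read's 3' end.
#'
#' @param read_seq a single A/C/G/T read sequence.
#' @param db a `reference_db`.
#' @param params an [align_params()] list.
#' @return data.frame of hits (possibly 0 rows): `ref_id`, `taxon_id`,
#'   `marker`, `strand`, `score`, `columns`, `matches`, `n_mismatch`,
#'   `gaps`, `identity`, `ref_aligned`, `read_seq`.
#' @export
align_read <- function(read_seq, db, params = align_params()) {
  stopifnot(inherits(db, "reference_db"), length(read_seq) == 1L)
  if (nchar(read_seq) < db$k) {
    warning("read shorter than seed length k = ", db$k, "; no hits")
    return(.empty_hits())
  }
  h <- .align_core(read_seq, rev_comp(read_seq), db, params)
  if (is.null(h)) return(.empty_hits())
  .hits_frame(h, db, read_seq)
}

.hits_frame <- function(h, db, read_seq) {
  data.frame(
    ref_id = db$sequences$ref_id[h$ref_idx],
    taxon_id = db$sequences$taxon_id[h$ref_idx],
    marker = db$sequences$marker[h$ref_idx],
    strand = h$strand, score = h$score, columns = h$columns,
    matches = h$matches, n_mismatch = h$n_mismatch, gaps = h$gaps,
    identity = h$matches / h$columns, ref_aligned = h$ref_aligned,
    read_seq = read_seq, stringsAsFactors = FALSE)
}

.empty_hits <- function() {
  data.frame(ref_id = character(0), taxon_id = integer(0),
             marker = character(0), strand = character(0),
             score = integer(0), columns = integer(0),
             matches = integer(0), n_mismatch = integer(0),
             gaps = integer(0), identity = numeric(0),
             ref_aligned = character(0), read_seq = character(0),
             stringsAsFactors = FALSE)
}

## hot path shared by align_read / align_reads: returns NULL or a
## score-sorted data.frame of hits for one read
.align_core <- function(read_seq, rc, db, params) {
  L <- nchar(read_seq)
  fwd <- .seed_counts(read_seq, db)
  rev <- .seed_counts(rc, db)
  sel <- function(s) {
    if (is.null(s)) return(s)
    keep <- s$count >= params$min_seed
    if (!any(keep)) return(NULL)
    lapply(s, `[`, keep)
  }
  fwd <- sel(fwd)
  rev <- sel(rev)
  idx <- union(fwd$ref, rev$ref)
  nc <- length(idx)
  if (nc == 0L) return(NULL)
  strand <- character(nc); score <- integer(nc); columns <- integer(nc)
  matches <- integer(nc); n_mismatch <- integer(nc); gaps <- integer(nc)
  ref_aligned <- character(nc)
  ## window the reference around the seed matches: any alignment that
  ## contains a shared k-mer lies within one read length of its offsets
  win <- function(s, ci, ref_len) {
    w <- which(s$ref == ci)
    c(max(1, min(s$lo[w]) - L - 4L),
      min(ref_len, max(s$hi[w]) + db$k + L + 4L))
  }
  for (ci in seq_len(nc)) {
    ref_seq <- db$sequences$sequence[idx[ci]]
    ref_len <- nchar(ref_seq)
    aln_f <- if (idx[ci] %in% fwd$ref) {
      w <- win(fwd, idx[ci], ref_len)
      semiglobal_align_cpp(read_seq, substr(ref_seq, w[1L], w[2L]),
                           params$match, params$mismatch, params$gap)
    } else NULL
    aln_r <- if (idx[ci] %in% rev$ref) {
      w <- win(rev, idx[ci], ref_len)
      semiglobal_align_cpp(rc, substr(ref_seq, w[1L], w[2L]),
                           params$match, params$mismatch, params$gap)
    } else NULL
    if (is.null(aln_r) || (!is.null(aln_f) && aln_f$score >= aln_r$score)) {
      aln <- aln_f
      strand[ci] <- "+"
      ref_aligned[ci] <- aln$ref_aligned
    } else {
      aln <- aln_r
      strand[ci] <- "-"
      ref_aligned[ci] <- .rev_orient(aln$ref_aligned)
    }
    score[ci] <- aln$score; columns[ci] <- aln$columns
    matches[ci] <- aln$matches; n_mismatch[ci] <- aln$mismatches
    gaps[ci] <- aln$gaps
  }
  ord <- order(-score, db$sequences$ref_id[idx])
  list(ref_idx = idx[ord], strand = strand[ord], score = score[ord],
       columns = columns[ord], matches = matches[ord],
       n_mismatch = n_mismatch[ord], gaps = gaps[ord],
       ref_aligned = ref_aligned[ord])
}

#' Align a batch of reads
#'
#' Applies [align_read()] to every read and binds the hits, prefixed with
#' `read_id` and `sample_id` columns. Reads shorter than the seed length
#' produce no hits (counted in the `n_unseeded` attribute).
#'
#' @param reads data.frame with `read_id`, `sample_id`, `sequence`.
#' @param db a `reference_db`.
#' @param params an [align_params()] list.
#' @return data.frame of hits for all reads.
#' @export
align_reads <- function(reads, db, params = align_params()) {
  stopifnot(all(c("read_id", "sample_id", "sequence") %in% names(reads)))
  short <- nchar(reads$sequence) < db$k
  rcs <- character(nrow(reads))
  rcs[!short] <- rev_comp(reads$sequence[!short])
  chunks <- vector("list", nrow(reads))
  which_read <- vector("list", nrow(reads))
  for (i in which(!short)) {
    h <- .align_core(reads$sequence[i], rcs[i], db, params)
    if (!is.null(h)) {
      chunks[[i]] <- h
      which_read[[i]] <- rep.int(i, length(h$score))
    }
  }
  keep <- !vapply(chunks, is.null, TRUE)
  if (!any(keep)) {
    hits <- cbind(data.frame(read_id = character(0),
                             sample_id = character(0),
                             stringsAsFactors = FALSE), .empty_hits())
  } else {
    chunks <- chunks[keep]
    ri <- unlist(which_read[keep], use.names = FALSE)
    cat_field <- function(f) {
      unlist(lapply(chunks, `[[`, f), use.names = FALSE)
    }
    h <- list(ref_idx = cat_field("ref_idx"), strand = cat_field("strand"),
              score = cat_field("score"), columns = cat_field("columns"),
              matches = cat_field("matches"),
              n_mismatch = cat_field("n_mismatch"),
              gaps = cat_field("gaps"),
              ref_aligned = cat_field("ref_aligned"))
    hits <- cbind(data.frame(read_id = reads$read_id[ri],
                             sample_id = reads$sample_id[ri],
                             stringsAsFactors = FALSE),
                  .hits_frame(h, db, reads$sequence[ri]))
  }
  rownames(hits) <- NULL
  attr(hits, "n_unseeded") <- sum(short)
  hits
}

#' Filter alignment hits on identity and score window
#'
#' Retains hits whose percent identity (matches over all alignment
#' columns, gaps included) is at least `min_pid` and whose score lies
#' within `top_percent` of the best score. When the hits span several
#' reads (a `read_id` column is present) the score window is applied per
#' read.
#'
#' @param hits hit data.frame as returned by [align_read()] or
#'   [align_reads()], sorted by score.
#' @param min_pid minimum percent identity (default 0.95).
#' @param top_percent score window below the best hit (default 0.10).
#' @return The retained hits.
#' @export
filter_hits <- function(hits, min_pid = 0.95, top_percent = 0.10) {
  if (nrow(hits) == 0L) return(hits)
  if ("read_id" %in% names(hits)) {
    best <- stats::ave(hits$score, hits$read_id, FUN = max)
  } else {
    best <- max(hits$score)
  }
  keep <- hits$identity >= min_pid & hits$score >= (1 - top_percent) * best
  hits[keep, , drop = FALSE]
}

#' Assign one read's filtered hits to a taxon
#'
#' Implements the naive-LCA rule: if a read has significant matches to two
#' taxa where one is a strict ancestor of the other, only the more
#' specific taxon is used; the read is then placed on the lowest common
#' ancestor of the remaining taxa. No hits give `NA` (unassigned).
#'
#' @param hits filtered hits for a single read.
#' @param tree the `taxonomy`.
#' @return A taxon id, or `NA_integer_` when unassigned.
#' @export
assign_read <- function(hits, tree) {
  taxa <- unique(as.integer(hits$taxon_id))
  if (length(taxa) == 0L) return(NA_integer_)
  if (length(taxa) > 1L) {
    paths <- lapply(taxa, function(t) taxon_ancestors(tree, t))
    drop <- vapply(seq_along(taxa), function(i) {
      any(vapply(seq_along(taxa), function(j) {
        i != j && taxa[i] %in% paths[[j]][-length(paths[[j]])]
      }, TRUE))
    }, TRUE)
    taxa <- taxa[!drop]
  }
  lca(tree, taxa)
}

#' Assign a batch of reads
#'
#' Filters hits per read and applies [assign_read()]. Reads absent from
#' `hits` (no seeded alignment) are reported unassigned.
#'
#' @param reads data.frame with `read_id` and `sample_id`.
#' @param hits hits from [align_reads()].
#' @param tree the `taxonomy`.
#' @param min_pid,top_percent passed to [filter_hits()].
#' @return data.frame `read_id`, `sample_id`, `taxon_id` (`NA` =
#'   unassigned).
#' @export
assign_reads <- function(reads, hits, tree, min_pid = 0.95,
                         top_percent = 0.10) {
  kept <- filter_hits(hits, min_pid = min_pid, top_percent = top_percent)
  taxon <- rep(NA_integer_, nrow(reads))
  if (nrow(kept) > 0L) {
    by_read <- split(kept$taxon_id, kept$read_id)
    assigned <- vapply(by_read, function(taxa) {
      assign_read(data.frame(taxon_id = taxa), tree)
    }, integer(1))
    hit_idx <- match(reads$read_id, names(assigned))
    taxon <- ifelse(is.na(hit_idx), NA_integer_, assigned[hit_idx])
  }
  data.frame(read_id = reads$read_id, sample_id = reads$sample_id,
             taxon_id = as.integer(taxon), stringsAsFactors = FALSE)
}

#' Best hit per read
#'
#' The top-scoring hit for each read (ties broken by `ref_id`), used for
#' damage spectra so a read is never counted more than once.
#'
#' @param hits hits from [align_reads()].
#' @return One row per read.
#' @export
best_hits <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  hits <- hits[order(hits$read_id, -hits$score, hits$ref_id), , drop = FALSE]
  hits[!duplicated(hits$read_id), , drop = FALSE]
}

#' Expand a hit table's mismatch records
#'
#' @param hits hit data.frame carrying `ref_aligned` and `read_seq`.
#' @return data.frame `read_id` (if present), `ref_id`, `read_pos`
#'   (0-based from the read 5' end), `ref_base`, `read_base`.
#' @export
mismatch_table <- function(hits) {
  rows <- lapply(seq_len(nrow(hits)), function(i) {
    r <- strsplit(hits$read_seq[i], "", fixed = TRUE)[[1L]]
    a <- strsplit(hits$ref_aligned[i], "", fixed = TRUE)[[1L]]
    mm <- which(a != "-" & a != r)
    if (length(mm) == 0L) return(NULL)
    data.frame(read_id = if ("read_id" %in% names(hits)) hits$read_id[i] else NA,
               ref_id = hits$ref_id[i], read_pos = mm - 1L,
               ref_base = a[mm], read_base = r[mm],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(read_id = character(0), ref_id = character(0),
                      read_pos = integer(0), ref_base = character(0),
                      read_base = character(0), stringsAsFactors = FALSE)
  }
  out
}

#' Build a sample-by-taxon count profile from read assignments
#'
#' Counts assigned reads per `(sample_id, taxon_id)`. With a positive
#' `min_support_percent`, taxa whose per-sample share of assigned reads
#' falls below the threshold have their reads re-assigned to the parent
#' taxon (applied leaf-to-root so re-assigned counts accumulate upward);
#' with the default 0 this is a no-op. Unassigned reads are tracked in the
#' `unassigned` attribute, one count per sample.
#'
#' @param assignments data.frame `read_id`, `sample_id`, `taxon_id`
#'   (`NA` = unassigned).
#' @param tree the `taxonomy`.
#' @param min_support_percent minimum per-sample share (fraction, default
#'   0).
#' @param samples optional vector of sample ids the profile must cover
#'   (so libraries with no assigned reads still appear as zero rows).
#' @return An integer matrix (samples x taxa) of class `taxon_profile`,
#'   with taxon ids as column names.
#' @export
build_profile <- function(assignments, tree, min_support_percent = 0,
                          samples = NULL) {
  stopifnot(min_support_percent >= 0, min_support_percent < 1)
  if (is.null(samples)) samples <- unique(assignments$sample_id)
  assigned <- assignments[!is.na(assignments$taxon_id), , drop = FALSE]
  taxa <- sort(unique(assigned$taxon_id))
  prof <- matrix(0L, nrow = length(samples), ncol = length(taxa),
                 dimnames = list(samples, as.character(taxa)))
  if (nrow(assigned) > 0L) {
    tab <- table(factor(assigned$sample_id, levels = samples),
                 factor(assigned$taxon_id, levels = taxa))
    prof[] <- as.integer(tab)
  }
  if (min_support_percent > 0 && length(taxa) > 0L) {
    ord <- order(tree$depth[as.character(taxa)], decreasing = TRUE)
    for (s in seq_along(samples)) {
      total <- sum(prof[s, ])
      if (total == 0L) next
      for (ti in ord) {
        id <- taxa[ti]
        cnt <- prof[s, as.character(id)]
        if (cnt > 0L && cnt / total < min_support_percent &&
            id != tree$root_id) {
          par <- tree$parent[as.character(id)]
          pk <- as.character(par)
          if (!pk %in% colnames(prof)) {
            prof <- cbind(prof, matrix(0L, nrow(prof), 1L,
                                       dimnames = list(NULL, pk)))
          }
          prof[s, pk] <- prof[s, pk] + cnt
          prof[s, as.character(id)] <- 0L
        }
      }
    }
    prof <- prof[, colSums(prof) > 0L | colnames(prof) %in% as.character(taxa),
                 drop = FALSE]
  }
  una <- table(factor(assignments$sample_id[is.na(assignments$taxon_id)],
                      levels = samples))
  structure(prof, unassigned = stats::setNames(as.integer(una), samples),
            class = c("taxon_profile", class(prof)))
}

#' Project a taxon profile to a fixed rank
#'
#' Each taxon's counts are mapped to its ancestor at the requested rank.
#' Taxa assigned above that rank (no such ancestor) are kept, not dropped:
#' they form explicit unclassified-at-rank buckets named
#' `"<name>_unclassified"` after their deepest classified ancestor (the
#' taxon itself).
#'
#' @param profile a `taxon_profile` matrix (columns are taxon ids).
#' @param tree the `taxonomy`.
#' @param rank target rank label.
#' @return A `taxon_profile` at the requested rank; per-sample totals are
#'   preserved.
#' @export
project_rank <- function(profile, tree, rank) {
  if (!rank %in% tree$ranks) stop("unknown rank: ", rank)
  taxa <- as.integer(colnames(profile))
  target <- vapply(taxa, function(t) taxon_rank_ancestor(tree, t, rank),
                   integer(1))
  key <- ifelse(is.na(target),
                paste0(tree$name[as.character(taxa)], "_unclassified"),
                as.character(target))
  groups <- unique(key)
  out <- matrix(0L, nrow = nrow(profile), ncol = length(groups),
                dimnames = list(rownames(profile), groups))
  for (g in groups) {
    out[, g] <- as.integer(rowSums(profile[, key == g, drop = FALSE]))
  }
  structure(out, unassigned = attr(profile, "unassigned"),
            class = c("taxon_profile", class(out)))
}

#' Human-readable taxon labels for profile columns
#'
#' @param profile a `taxon_profile`.
#' @param tree the `taxonomy`.
#' @return Character vector of display names (unclassified buckets keep
#'   their bucket label).
#' @export
profile_labels <- function(profile, tree) {
  cols <- colnames(profile)
  is_id <- grepl("^[0-9]+$", cols)
  out <- cols
  out[is_id] <- tree$name[cols[is_id]]
  out
}
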