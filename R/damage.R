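## Terminal-deamination damage authentication: positional substitution
## spectra, per-read ancient/default classification, per-group damage
## proportions and geometric decay-model fitting.

.explode_hits <- function(hits) {
  rs <- strsplit(hits$read_seq, "", fixed = TRUE)
  as <- strsplit(hits$ref_aligned, "", fixed = TRUE)
  lens <- lengths(rs)
  list(read = unlist(rs, use.names = FALSE),
       ref = unlist(as, use.names = FALSE),
       hit = rep.int(seq_len(nrow(hits)), lens),
       pos5 = sequence(lens) - 1L,
       pos3 = rep.int(lens, lens) - sequence(lens))
}

#' Positional substitution spectrum of a hit set
#'
#' For 0-based 5' position `i`, `f5[i+1]` is the fraction of alignment
#' columns with reference C at that position in which the read shows T;
#' `f3` is the analogous G-to-A fraction counted from the 3' end.
#' Denominators are stored alongside; positions with zero denominator
#' yield `NA` frequencies. All other substitution types are pooled into a
#' single background rate over all aligned columns.
#'
#' @param hits hit data.frame (typically [best_hits()] output) carrying
#'   `read_seq` and `ref_aligned`.
#' @param m number of terminal positions to profile (default 20).
#' @return list of class `damage_spectrum`: `f5`, `f3`, `n5`, `n3`
#'   (denominators), `background`, `m`.
#' @export
substitution_spectrum <- function(hits, m = 20L) {
  if (nrow(hits) == 0L) {
    z <- rep(NA_real_, m)
    return(structure(list(f5 = z, f3 = z, n5 = integer(m), n3 = integer(m),
                          background = NA_real_, m = m),
                     class = "damage_spectrum"))
  }
  e <- .explode_hits(hits)
  aligned <- e$ref != "-"
  tab <- function(cond, pos) {
    idx <- cond & aligned & pos < m
    tabulate(pos[idx] + 1L, nbins = m)
  }
  n5 <- tab(e$ref == "C", e$pos5)
  k5 <- tab(e$ref == "C" & e$read == "T", e$pos5)
  n3 <- tab(e$ref == "G", e$pos3)
  k3 <- tab(e$ref == "G" & e$read == "A", e$pos3)
  mism <- aligned & e$ref != e$read
  deam <- (e$ref == "C" & e$read == "T") | (e$ref == "G" & e$read == "A")
  background <- sum(mism & !deam) / sum(aligned)
  structure(list(f5 = ifelse(n5 > 0, k5 / n5, NA_real_),
                 f3 = ifelse(n3 > 0, k3 / n3, NA_real_),
                 n5 = n5, n3 = n3, background = background, m = m),
            class = "damage_spectrum")
}

#' @export
print.damage_spectrum <- function(x, ...) {
  cat("<damage_spectrum> f5[0..2] =",
      paste(sprintf("%.3f", x$f5[1:3]), collapse = ", "),
      " background =", sprintf("%.4f", x$background), "\n")
  invisible(x)
}

#' Classify reads as ancient, default or rejected
#'
#' A read is `rejected` when its best hit fails the stringent criteria
#' (identity below `min_pid` or gap fraction above `max_gap_frac`);
#' otherwise it is `ancient` iff it shows at least one C-to-T mismatch
#' within the first `k_terminal` 5' positions or one G-to-A within the
#' last `k_terminal` 3' positions, and `default` otherwise. Other
#' substitution types are never damage evidence.
#'
#' @param hits best-hit table (one row per read) with `read_seq`,
#'   `ref_aligned`, `identity`, `gaps`, `columns`.
#' @param k_terminal terminal window in bp (default 5).
#' @param min_pid,max_gap_frac stringent filtering gate.
#' @return data.frame `read_id`, `sample_id` (if present), `taxon_id`,
#'   `call`, `n_evidence`.
#' @export
classify_reads <- function(hits, k_terminal = 5L, min_pid = 0.95,
                           max_gap_frac = 0.1) {
  n <- nrow(hits)
  evid <- integer(n)
  if (n > 0L) {
    e <- .explode_hits(hits)
    qual <- (e$ref == "C" & e$read == "T" & e$pos5 < k_terminal) |
      (e$ref == "G" & e$read == "A" & e$pos3 < k_terminal)
    evid <- tabulate(e$hit[qual], nbins = n)
  }
  rejected <- hits$identity < min_pid | hits$gaps / hits$columns > max_gap_frac
  call <- ifelse(rejected, "rejected", ifelse(evid > 0L, "ancient", "default"))
  out <- data.frame(read_id = hits$read_id, stringsAsFactors = FALSE)
  if ("sample_id" %in% names(hits)) out$sample_id <- hits$sample_id
  out$taxon_id <- hits$taxon_id
  out$call <- call
  out$n_evidence <- as.integer(evid)
  out
}

#' Classify a single read's best hit
#'
#' Single-hit convenience wrapper around [classify_reads()].
#'
#' @param hit a one-row best-hit data.frame.
#' @param k_terminal,min_pid,max_gap_frac see [classify_reads()].
#' @return One classification row.
#' @export
classify_read <- function(hit, k_terminal = 5L, min_pid = 0.95,
                          max_gap_frac = 0.1) {
  stopifnot(nrow(hit) == 1L)
  classify_reads(hit, k_terminal = k_terminal, min_pid = min_pid,
                 max_gap_frac = max_gap_frac)
}

#' Damage proportions per group
#'
#' Proportion of `ancient` among `ancient + default` calls (rejected
#' reads are excluded from the denominator), grouped by the given
#' columns. Groups with fewer than `min_reads` retained reads are still
#' reported but flagged low-confidence; groups with no retained reads get
#' an `NA` proportion.
#'
#' @param calls classification table from [classify_reads()].
#' @param by grouping columns (default sample and taxon).
#' @param min_reads low-confidence threshold (default 50).
#' @return data.frame of class `damage_summary`: grouping columns,
#'   `n_ancient`, `n_default`, `n_rejected`, `proportion`,
#'   `low_confidence`.
#' @export
damage_proportion <- function(calls, by = c("sample_id", "taxon_id"),
                              min_reads = 50L) {
  stopifnot(all(by %in% names(calls)))
  if (nrow(calls) == 0L) {
    out <- stats::setNames(
      as.data.frame(matrix(character(0), 0L, length(by)),
                    stringsAsFactors = FALSE), by)
    out$n_ancient <- integer(0); out$n_default <- integer(0)
    out$n_rejected <- integer(0); out$proportion <- numeric(0)
    out$low_confidence <- logical(0)
    class(out) <- c("damage_summary", class(out))
    return(out)
  }
  key <- interaction(calls[by], drop = TRUE, lex.order = TRUE, sep = "\t")
  cnt <- function(what) {
    as.integer(tapply(calls$call == what, key, sum))
  }
  groups <- do.call(rbind, strsplit(levels(key), "\t", fixed = TRUE))
  out <- as.data.frame(groups, stringsAsFactors = FALSE)
  names(out) <- by
  out$n_ancient <- cnt("ancient")
  out$n_default <- cnt("default")
  out$n_rejected <- cnt("rejected")
  total <- out$n_ancient + out$n_default
  out$proportion <- ifelse(total > 0L, out$n_ancient / total, NA_real_)
  out$low_confidence <- total < min_reads
  class(out) <- c("damage_summary", class(out))
  out
}

#' Fit the geometric decay model to a damage spectrum
#'
#' Least-squares fit of `f[i] = d * r^i + eps` over the positions with a
#' defined frequency, with `d` in `[0, 1]`, `r` in (0, 1) and `eps >= 0`.
#' A spectrum that is zero everywhere returns `d_hat = 0` with `r_hat`
#' flagged undefined.
#'
#' @param spectrum a `damage_spectrum`.
#' @param end which end to fit, `"5"` (C-to-T) or `"3"` (G-to-A).
#' @return list(`d_hat`, `r_hat`, `eps_hat`, `rss`, `n_positions`,
#'   `degenerate`).
#' @export
fit_decay <- function(spectrum, end = c("5", "3")) {
  end <- match.arg(end)
  f <- if (end == "5") spectrum$f5 else spectrum$f3
  ok <- !is.na(f)
  if (sum(ok) < 3L) stop("need at least 3 positions with defined frequency")
  f <- f[ok]
  pos <- (seq_along(ok) - 1L)[ok]
  if (all(f == 0)) {
    return(list(d_hat = 0, r_hat = NA_real_, eps_hat = 0, rss = 0,
                n_positions = length(f), degenerate = TRUE))
  }
  rss <- function(par) {
    sum((f - (par[1L] * par[2L]^pos + par[3L]))^2)
  }
  starts <- list(
    c(d = max(f[1L] - f[length(f)], 1e-3),
      r = if (f[1L] > 0 && f[2L] > 0) min(max(f[2L] / f[1L], 0.05), 0.95)
          else 0.5,
      eps = max(min(f), 1e-6)),
    c(d = 0.2, r = 0.5, eps = 0.01),
    c(d = 0.05, r = 0.8, eps = 0.001)
  )
  best <- NULL
  for (p0 in starts) {
    fit <- stats::optim(p0, rss, method = "L-BFGS-B",
                        lower = c(0, 1e-6, 0), upper = c(1, 1 - 1e-6, 0.5),
                        control = list(factr = 10, maxit = 500))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  list(d_hat = unname(best$par[1L]), r_hat = unname(best$par[2L]),
       eps_hat = unname(best$par[3L]), rss = best$value,
       n_positions = length(f), degenerate = FALSE)
}

#' Closed-form per-read classifier sensitivity
#'
#' With zero background error, a read from a damaged source is called
#' ancient with probability `1 - prod(1 - d5 * r^pos)` over the C
#' positions in the first `k_terminal` bases and the G positions in the
#' last `k_terminal` bases of the undamaged fragment (double-stranded
#' signature).
#'
#' @param fragments character vector of undamaged fragment sequences.
#' @param d5 terminal amplitude.
#' @param r decay ratio.
#' @param k_terminal terminal window (default 5).
#' @return Numeric vector of per-fragment detection probabilities.
#' @export
classifier_sensitivity <- function(fragments, d5, r, k_terminal = 5L) {
  vapply(fragments, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    L <- length(ch)
    w <- min(k_terminal, L)
    p5 <- which(ch[seq_len(w)] == "C") - 1L
    tail_idx <- seq.int(L - w + 1L, L)
    p3 <- (L - tail_idx)[ch[tail_idx] == "G"]
    1 - prod(1 - d5 * r^p5) * prod(1 - d5 * r^p3)
  }, numeric(1), USE.NAMES = FALSE)
}
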