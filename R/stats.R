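## Relative-abundance tables, rare-taxon grouping, rarefaction with
## data-driven depth selection, and the correlation/regression analyses.

#' Relative abundance of a taxon profile
#'
#' Divides each sample row by its total assigned count. Samples with no
#' assigned reads are kept as all-zero rows and flagged in the
#' `empty_samples` attribute rather than being NaN-filled.
#'
#' @param profile a `taxon_profile` count matrix.
#' @return Numeric matrix of per-sample fractions; non-empty rows sum
#'   to 1.
#' @export
relative_abundance <- function(profile) {
  totals <- rowSums(profile)
  out <- profile / ifelse(totals > 0, totals, 1)
  out <- matrix(as.numeric(out), nrow(profile), ncol(profile),
                dimnames = dimnames(profile))
  attr(out, "empty_samples") <- rownames(profile)[totals == 0]
  out
}

#' Pool rare taxa into one explicit group
#'
#' Taxa whose unweighted mean relative abundance across all samples is
#' below `threshold` are pooled into a single `rare` column (a taxon at
#' exactly the threshold is kept separate). Per-sample totals are
#' preserved.
#'
#' @param rel_abund relative-abundance matrix from
#'   [relative_abundance()].
#' @param threshold mean-abundance cutoff (default 0.01).
#' @param rare_label name of the pooled column.
#' @return Matrix with abundant taxa kept and a pooled rare column (only
#'   present when some taxon is rare).
#' @export
group_rare <- function(rel_abund, threshold = 0.01, rare_label = "rare") {
  means <- colMeans(rel_abund)
  keep <- means >= threshold
  if (all(keep)) return(rel_abund)
  out <- rel_abund[, keep, drop = FALSE]
  pooled <- rowSums(rel_abund[, !keep, drop = FALSE])
  out <- cbind(out, pooled)
  colnames(out)[ncol(out)] <- rare_label
  out
}

#' Data-driven rarefaction depth
#'
#' The smallest library size among libraries that contain the marker of
#' interest — the depth at which quantitative comparisons lose no
#' marker-bearing library.
#'
#' @param library_sizes numeric vector of library sizes.
#' @param marker_presence logical vector, `TRUE` where the library
#'   contains the marker.
#' @return The chosen depth.
#' @export
choose_depth <- function(library_sizes, marker_presence) {
  stopifnot(length(library_sizes) == length(marker_presence))
  if (!any(marker_presence)) {
    stop("no library contains the marker; depth undefined")
  }
  min(library_sizes[marker_presence])
}

#' Rarefy a taxon profile to fixed depth
#'
#' Draws exactly `depth` reads per sample without replacement
#' (multivariate hypergeometric). Samples whose total falls below the
#' depth are excluded with a warning. Deterministic given `seed`.
#'
#' @param profile a `taxon_profile` count matrix.
#' @param depth target reads per sample (positive).
#' @param seed optional seed (RNG state restored afterwards).
#' @return Rarefied profile; every included row sums to `depth`.
#' @export
rarefy <- function(profile, depth, seed = NULL) {
  if (depth <= 0) stop("depth must be positive")
  totals <- rowSums(profile)
  drop <- totals < depth
  if (any(drop)) {
    warning(sum(drop), " sample(s) below depth ", depth, " excluded: ",
            paste(rownames(profile)[drop], collapse = ", "))
  }
  kept <- profile[!drop, , drop = FALSE]
  with_seed(seed, {
    out <- t(apply(kept, 1L, function(counts) {
      pool <- rep.int(seq_along(counts), counts)
      take <- pool[sample.int(length(pool), depth)]
      tabulate(take, nbins = length(counts))
    }))
    dimnames(out) <- dimnames(kept)
    structure(out, class = class(profile))
  })
}

#' Pairwise Pearson correlations between two tables
#'
#' Standard Pearson r for every (column of `x`, column of `y`) pair using
#' pairwise-complete observations. Pairs with fewer than 3 complete
#' observations or with a constant column are skipped with a warning.
#'
#' @param x,y data.frames or matrices with samples as rows (`y` defaults
#'   to `x`).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return data.frame `var1`, `var2`, `r`, `n`.
#' @export
pearson_matrix <- function(x, y = x, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  x <- as.data.frame(x); y <- as.data.frame(y)
  stopifnot(nrow(x) == nrow(y))
  rows <- list()
  for (i in names(x)) {
    for (j in names(y)) {
      ok <- stats::complete.cases(x[[i]], y[[j]])
      n <- sum(ok)
      if (n < 3L) {
        warning("pair (", i, ", ", j, ") skipped: fewer than 3 complete ",
                "observations")
        next
      }
      if (stats::sd(x[[i]][ok]) == 0 || stats::sd(y[[j]][ok]) == 0) {
        warning("pair (", i, ", ", j, ") skipped: constant column")
        next
      }
      rows[[paste(i, j)]] <- data.frame(
        var1 = i, var2 = j,
        r = stats::cor(x[[i]][ok], y[[j]][ok], method = method),
        n = n, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(var1 = character(0), var2 = character(0),
                      r = numeric(0), n = integer(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Regression between mean taxon abundances of two tables
#'
#' Simple linear regression of table A's mean relative abundance per
#' taxon on table B's (taxa averaged across samples), reporting Pearson r
#' and R-squared. For simple regression R-squared equals r squared.
#'
#' @param table_a,table_b relative-abundance matrices sharing taxon
#'   columns.
#' @return list(`r`, `r_squared`, `n_taxa`, `slope`, `intercept`).
#' @export
regress_between_tables <- function(table_a, table_b) {
  shared <- intersect(colnames(table_a), colnames(table_b))
  if (length(shared) < 3L) stop("fewer than 3 shared taxa")
  a <- colMeans(table_a[, shared, drop = FALSE])
  b <- colMeans(table_b[, shared, drop = FALSE])
  fit <- stats::lm(a ~ b)
  r <- stats::cor(a, b)
  list(r = r, r_squared = r^2, n_taxa = length(shared),
       slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]))
}

#' Fisher-z confidence interval for a correlation
#'
#' @param r observed (or target) correlation.
#' @param n sample size.
#' @param level confidence level (default 0.95).
#' @return c(lower, upper) on the correlation scale.
#' @export
fisher_z_interval <- function(r, n, level = 0.95) {
  z <- atanh(r)
  half <- stats::qnorm(1 - (1 - level) / 2) / sqrt(n - 3)
  tanh(c(z - half, z + half))
}
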