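# Independent oracles, kept deliberately separate from the package's
# implementation paths.

# Full unbanded semiglobal DP (read global, reference local), score only.
# Row-vectorised: within-row horizontal gap chains are resolved with the
# cummax identity max_h(tmp[h] + (j - h) * gap) = cummax(tmp - h*gap) + j*gap.
semiglobal_score_oracle <- function(read, ref, match = 1, mismatch = -1,
                                    gap = -2) {
  r <- strsplit(read, "")[[1]]
  f <- strsplit(ref, "")[[1]]
  m <- length(r)
  n <- length(f)
  prev <- rep(0, n + 1)                    # row i = 0: free ref prefix
  js <- seq_len(n)
  for (i in seq_len(m)) {
    sub <- ifelse(f == r[i], match, mismatch)
    tmp <- pmax(prev[js] + sub, prev[js + 1] + gap)
    cur0 <- i * gap                        # read prefix against empty ref
    d <- cummax(c(cur0, tmp - js * gap))
    prev <- c(cur0, d[js + 1] + js * gap)
  }
  max(prev)
}

# best full-DP score of a read against every reference in a db
exhaustive_best_score <- function(read, db, match = 1, mismatch = -1,
                                  gap = -2) {
  max(vapply(db$sequences$sequence, function(ref) {
    semiglobal_score_oracle(read, ref, match, mismatch, gap)
  }, numeric(1)))
}

root_path <- function(tree, id) {
  path <- id
  while (unname(tree$parent[as.character(id)]) != id) {
    id <- unname(tree$parent[as.character(id)])
    path <- c(id, path)
  }
  path
}

# LCA by brute-force root-path intersection
lca_oracle <- function(tree, taxa) {
  common <- Reduce(intersect, lapply(taxa, root_path, tree = tree))
  as.integer(unname(common[which.max(tree$depth[as.character(common)])]))
}

# naive-LCA assignment oracle: drop strict ancestors of other hit taxa,
# then root-path-intersection LCA
assign_oracle <- function(tree, taxa) {
  taxa <- unique(taxa)
  if (length(taxa) == 0) return(NA_integer_)
  paths <- lapply(taxa, root_path, tree = tree)
  strict_anc <- vapply(seq_along(taxa), function(i) {
    any(vapply(seq_along(taxa), function(j) {
      i != j && taxa[i] %in% head(paths[[j]], -1)
    }, logical(1)))
  }, logical(1))
  lca_oracle(tree, taxa[!strict_anc])
}
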