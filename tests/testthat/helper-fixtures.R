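# Fixtures built in code: small fixed trees/databases and random
# generators used across the suite.

toy_tree_nodes <- function() {
  data.frame(
    taxon_id  = c(1L, 2L, 10L, 11L, 20L, 21L, 22L, 30L),
    parent_id = c(1L, 1L, 2L, 2L, 10L, 10L, 11L, 20L),
    rank = c("root", "domain", "phylum", "phylum", "genus", "genus",
             "genus", "species"),
    name = c("root", "Eukaryota", "PhylumA", "PhylumB", "GenusA1",
             "GenusA2", "GenusB1", "SpeciesA1a"),
    stringsAsFactors = FALSE)
}

toy_tree <- function() taxonomy(toy_tree_nodes())

# random rooted tree: node 1 is the root, each later node picks an
# earlier parent; rank follows depth (capped at species)
random_tree <- function(n = 50L, seed = 1L) {
  with_seed(seed, {
    parent <- c(1L, vapply(2:n, function(i) {
      sample.int(i - 1L, 1L)
    }, integer(1)))
    depth <- integer(n)
    for (i in 2:n) depth[i] <- depth[parent[i]] + 1L
    rank <- DEFAULT_RANKS[pmin(depth + 1L, length(DEFAULT_RANKS))]
    taxonomy(data.frame(taxon_id = seq_len(n), parent_id = parent,
                        rank = rank, name = paste0("n", seq_len(n)),
                        stringsAsFactors = FALSE))
  })
}

random_dna <- function(n, len, seed = NULL) {
  with_seed(seed, {
    vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
            collapse = "")
    }, character(1))
  })
}

# substitute bases at 1-based positions, never to the original base
mutate_at <- function(seq, positions) {
  ch <- strsplit(seq, "")[[1]]
  for (p in positions) {
    ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  }
  paste(ch, collapse = "")
}

toy_db <- function(k = 12L, seed = 99L) {
  tree <- toy_tree()
  reference_db(data.frame(
    ref_id = c("refA1a", "refA2", "refB1"),
    taxon_id = c(30L, 21L, 22L),
    marker = c("SSU", "SSU", "LSU"),
    sequence = random_dna(3, 400, seed = seed),
    stringsAsFactors = FALSE), tree, k = k)
}

reads_frame <- function(seqs, sample_id = "S1") {
  data.frame(read_id = sprintf("%s_r%03d", sample_id, seq_along(seqs)),
             sample_id = rep_len(sample_id, length(seqs)), sequence = seqs,
             stringsAsFactors = FALSE)
}

random_profile <- function(n_samples = 5L, n_taxa = 8L, lambda = 30,
                           seed = NULL, taxa = NULL) {
  with_seed(seed, {
    m <- matrix(stats::rpois(n_samples * n_taxa, lambda), n_samples,
                n_taxa)
    rownames(m) <- sprintf("P%02d", seq_len(n_samples))
    colnames(m) <- if (is.null(taxa)) as.character(seq_len(n_taxa)) else taxa
    structure(m, class = c("taxon_profile", class(m)))
  })
}

with_seed <- sedapipe:::with_seed
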