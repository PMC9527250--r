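#' Ordered taxonomic ranks
#'
#' Default rank ladder used throughout the package, highest rank first.
#' A child node may never carry a rank higher in this ladder than its
#' parent's.
#'
#' @export
DEFAULT_RANKS <- c("root", "domain", "phylum", "class", "order",
                   "family", "genus", "species")

#' Construct a validated taxonomy
#'
#' Builds a rooted taxonomy from a node table and validates its structure:
#' exactly one root (a node whose `parent_id` equals its own `taxon_id`),
#' no duplicate ids, no orphans, no cycles, every node reachable from the
#' root, and child ranks never higher than their parent's rank.
#'
#' @param nodes data.frame with columns `taxon_id`, `parent_id`, `rank`,
#'   `name`.
#' @param ranks ordered character vector of admissible ranks, highest
#'   first.
#' @return An object of class `taxonomy`: the node table plus parent,
#'   depth and rank-index lookups.
#' @export
taxonomy <- function(nodes, ranks = DEFAULT_RANKS) {
  required <- c("taxon_id", "parent_id", "rank", "name")
  missing_cols <- setdiff(required, names(nodes))
  if (length(missing_cols) > 0L) {
    stop("taxonomy table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  nodes <- as.data.frame(nodes)[required]
  nodes$taxon_id <- as.integer(nodes$taxon_id)
  nodes$parent_id <- as.integer(nodes$parent_id)
  nodes$rank <- as.character(nodes$rank)
  nodes$name <- as.character(nodes$name)

  if (anyNA(nodes$taxon_id) || any(nodes$taxon_id <= 0L)) {
    stop("taxon_id must be positive integers")
  }
  dup <- nodes$taxon_id[duplicated(nodes$taxon_id)]
  if (length(dup) > 0L) {
    stop("duplicate taxon_id: ", paste(unique(dup), collapse = ", "))
  }
  bad_rank <- setdiff(unique(nodes$rank), ranks)
  if (length(bad_rank) > 0L) {
    stop("unknown rank label(s): ", paste(bad_rank, collapse = ", "))
  }

  ids <- nodes$taxon_id
  is_root <- nodes$parent_id == ids
  if (sum(is_root) != 1L) {
    stop("taxonomy must have exactly one root (parent_id == taxon_id), found ",
         sum(is_root))
  }
  root_id <- ids[is_root]

  orphan <- !(nodes$parent_id %in% ids)
  if (any(orphan)) {
    stop("orphan node(s) with missing parent: taxon_id ",
         paste(ids[orphan], collapse = ", "))
  }

  key <- as.character(ids)
  parent <- stats::setNames(nodes$parent_id, key)
  rank_index <- stats::setNames(match(nodes$rank, ranks), key)

  ## reachability from root (also proves acyclicity given unique parents)
  children <- split(ids[!is_root], as.character(nodes$parent_id[!is_root]))
  depth <- stats::setNames(rep(NA_integer_, length(ids)), key)
  depth[as.character(root_id)] <- 0L
  frontier <- root_id
  while (length(frontier) > 0L) {
    nxt <- unlist(children[as.character(frontier)], use.names = FALSE)
    nxt <- nxt[is.na(depth[as.character(nxt)])]
    if (length(nxt) == 0L) break
    depth[as.character(nxt)] <-
      depth[as.character(parent[as.character(nxt)])] + 1L
    frontier <- nxt
  }
  unreachable <- ids[is.na(depth[key])]
  if (length(unreachable) > 0L) {
    stop("cycle or unreachable subtree involving taxon_id: ",
         paste(unreachable, collapse = ", "))
  }

  parent_rank <- rank_index[as.character(parent)]
  bad <- !is_root & rank_index[key] < parent_rank
  if (any(bad)) {
    stop("child rank higher than parent's for taxon_id: ",
         paste(ids[bad], collapse = ", "))
  }

  structure(
    list(nodes = nodes, ranks = ranks, root_id = root_id,
         parent = parent, depth = depth, rank_index = rank_index,
         name = stats::setNames(nodes$name, key),
         rank = stats::setNames(nodes$rank, key)),
    class = "taxonomy"
  )
}

#' @export
print.taxonomy <- function(x, ...) {
  cat("<taxonomy> ", nrow(x$nodes), " nodes, root = ",
      x$name[as.character(x$root_id)],
      ", max depth = ", max(x$depth), "\n", sep = "")
  invisible(x)
}

#' Load a taxonomy from a tab-separated file
#'
#' The file must have a header row and columns `taxon_id`, `parent_id`,
#' `rank`, `name`. The root points to itself.
#'
#' @param path path to the TSV file.
#' @param ranks ordered rank ladder passed to [taxonomy()].
#' @return A validated `taxonomy` object.
#' @export
load_taxonomy <- function(path, ranks = DEFAULT_RANKS) {
  nodes <- utils::read.delim(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  taxonomy(nodes, ranks = ranks)
}

#' Write a taxonomy node table to TSV
#'
#' @param tree a `taxonomy` object.
#' @param path output path.
#' @export
write_taxonomy <- function(tree, path) {
  stopifnot(inherits(tree, "taxonomy"))
  utils::write.table(tree$nodes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.check_taxa <- function(tree, taxa) {
  unknown <- setdiff(taxa, tree$nodes$taxon_id)
  if (length(unknown) > 0L) {
    stop("unknown taxon id(s): ", paste(unknown, collapse = ", "))
  }
}

#' Path from the root to a taxon
#'
#' @param tree a `taxonomy` object.
#' @param taxon_id a single taxon id.
#' @return Integer vector of taxon ids from the root down to (and
#'   including) `taxon_id`.
#' @export
taxon_ancestors <- function(tree, taxon_id) {
  stopifnot(inherits(tree, "taxonomy"), length(taxon_id) == 1L)
  taxon_id <- as.integer(taxon_id)
  .check_taxa(tree, taxon_id)
  path <- integer(tree$depth[as.character(taxon_id)] + 1L)
  cur <- taxon_id
  for (i in rev(seq_along(path))) {
    path[i] <- cur
    cur <- tree$parent[as.character(cur)]
  }
  path
}

.lca2 <- function(tree, a, b) {
  da <- tree$depth[as.character(a)]
  db <- tree$depth[as.character(b)]
  while (da > db) { a <- tree$parent[as.character(a)]; da <- da - 1L }
  while (db > da) { b <- tree$parent[as.character(b)]; db <- db - 1L }
  while (a != b) {
    a <- tree$parent[as.character(a)]
    b <- tree$parent[as.character(b)]
  }
  as.integer(a)
}

#' Lowest common ancestor of a set of taxa
#'
#' Returns the deepest node that is an ancestor-or-self of every member of
#' `taxa`. Commutative and associative over set union.
#'
#' @param tree a `taxonomy` object.
#' @param taxa non-empty vector of taxon ids present in the tree.
#' @return A single taxon id.
#' @export
lca <- function(tree, taxa) {
  stopifnot(inherits(tree, "taxonomy"))
  taxa <- unique(as.integer(taxa))
  if (length(taxa) == 0L || anyNA(taxa)) {
    stop("'taxa' must be a non-empty set of taxon ids")
  }
  .check_taxa(tree, taxa)
  cur <- taxa[1L]
  for (t in taxa[-1L]) cur <- .lca2(tree, cur, t)
  cur
}

#' Ancestor of a taxon at a given rank
#'
#' Walks up the root path and returns the ancestor whose rank equals
#' `rank`, or `NA` when the taxon sits above that rank (no such ancestor
#' exists).
#'
#' @param tree a `taxonomy` object.
#' @param taxon_id a single taxon id.
#' @param rank a rank label from the tree's rank ladder.
#' @return A taxon id or `NA_integer_`.
#' @export
taxon_rank_ancestor <- function(tree, taxon_id, rank) {
  stopifnot(inherits(tree, "taxonomy"))
  if (!rank %in% tree$ranks) stop("unknown rank: ", rank)
  path <- taxon_ancestors(tree, taxon_id)
  at <- path[tree$rank[as.character(path)] == rank]
  if (length(at) == 0L) NA_integer_ else at[length(at)]
}

#' Test whether one taxon is a strict ancestor of another
#'
#' @param tree a `taxonomy` object.
#' @param a,b taxon ids.
#' @return `TRUE` iff `a` lies on the root path of `b` and `a != b`.
#' @export
is_strict_ancestor <- function(tree, a, b) {
  a <- as.integer(a); b <- as.integer(b)
  if (a == b) return(FALSE)
  a %in% taxon_ancestors(tree, b)
}
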