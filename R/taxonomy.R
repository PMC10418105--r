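#' Build a taxonomy tree from genome taxon paths
#'
#' The tree is rooted at `"root"`; ranks are assigned by depth
#' (`root`, `domain`, `genus`, `genome`). Every taxon must have a unique
#' parent across all paths.
#'
#' @param genomes List of [genome_record]s (or a list of character taxon
#'   paths).
#' @return An object of class `taxonomy_tree`: a list with `parent`
#'   (named character; `root` maps to `NA`), `rank` (named character) and
#'   `nodes` (taxon names in insertion order, root first).
#' @export
build_taxonomy <- function(genomes) {
  paths <- lapply(genomes, function(g)
    if (inherits(g, "genome_record")) g$taxon_path else as.character(g))
  if (!length(paths)) stop("no genomes given")
  if (any(vapply(paths, `[`, character(1), 1L) != "root"))
    stop("every taxon_path must start at 'root'")
  parent <- c(root = NA_character_)
  depth <- c(root = 0L)
  ranks <- c("root", "domain", "genus", "genome")
  for (p in paths) {
    for (i in seq_along(p)[-1L]) {
      tx <- p[i]
      if (tx %in% names(parent)) {
        if (!identical(parent[[tx]], p[i - 1L]))
          stop("conflicting parent for taxon '", tx, "': '",
               parent[[tx]], "' vs '", p[i - 1L], "'")
      } else {
        parent[tx] <- p[i - 1L]
        depth[tx] <- i - 1L
      }
    }
  }
  rank <- ranks[pmin(depth, length(ranks) - 1L) + 1L]
  names(rank) <- names(depth)
  structure(list(parent = parent, rank = rank, nodes = names(parent)),
            class = "taxonomy_tree")
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat(sprintf("<taxonomy_tree> %d nodes (%s)\n", length(x$nodes),
              paste(names(table(x$rank)), table(x$rank), sep = ":", collapse = ", ")))
  invisible(x)
}

ancestors_of <- function(tree, taxon) {
  if (!taxon %in% tree$nodes) stop("unknown taxon: ", taxon)
  out <- character(0)
  while (!is.na(taxon)) {
    out <- c(out, taxon)
    taxon <- tree$parent[[taxon]]
  }
  out  # self first, root last
}

#' Lowest common ancestor of two taxa
#'
#' @param tree A `taxonomy_tree`.
#' @param taxon_a,taxon_b Taxon names present in the tree.
#' @return The deepest node ancestral to both (`lca(x, x) = x`).
#' @export
taxon_lca <- function(tree, taxon_a, taxon_b) {
  anc_a <- ancestors_of(tree, taxon_a)
  anc_b <- ancestors_of(tree, taxon_b)
  # deepest shared node: first element of a's self-to-root chain found in b's
  anc_a[match(TRUE, anc_a %in% anc_b)]
}

# n x n matrix of LCA node indices (1-based, in tree$nodes order); the tree
# is small, so the quadratic table is the simplest handoff to the C++ core.
lca_table <- function(tree) {
  n <- length(tree$nodes)
  anc <- lapply(tree$nodes, function(t) ancestors_of(tree, t))
  m <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in i:n) {
    l <- anc[[i]][match(TRUE, anc[[i]] %in% anc[[j]])]
    m[i, j] <- m[j, i] <- match(l, tree$nodes)
  }
  m
}

# indicator matrix: anc[t, a] = 1 when a is an ancestor-or-self of t
ancestor_matrix <- function(tree) {
  n <- length(tree$nodes)
  m <- matrix(0L, n, n, dimnames = list(tree$nodes, tree$nodes))
  for (t in tree$nodes) m[t, ancestors_of(tree, t)] <- 1L
  m
}

leaf_nodes <- function(tree) {
  setdiff(tree$nodes, tree$parent[!is.na(tree$parent)])
}
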