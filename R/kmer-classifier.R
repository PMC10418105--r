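#' Build an exact k-mer LCA database
#'
#' Kraken-style database construction: every canonical k-mer (the
#' lexicographic minimum of a k-mer and its reverse complement) occurring
#' in any genome is stored, mapped to the lowest common ancestor of all
#' genomes containing it. K-mers containing non-ACGT characters are
#' skipped; genomes shorter than `k` contribute nothing. The database is
#' what determines classification behaviour — in particular, whether the
#' host genome is present decides the fate of host-derived reads matching
#' a contaminated draft.
#'
#' @param genomes List of [genome_record]s (non-empty).
#' @param tree A `taxonomy_tree` from [build_taxonomy()]; defaults to one
#'   built from `genomes`.
#' @param k Odd k-mer width, at least 11 (default 31).
#' @return An object of class `kmer_db`: the sorted encoded k-mers
#'   (`hi`/`lo` 31-bit halves), the LCA taxon index per k-mer, the tree,
#'   and the source genome ids.
#' @export
build_kmer_database <- function(genomes, tree = build_taxonomy(genomes), k = 31L) {
  if (inherits(genomes, "genome_record")) genomes <- list(genomes)
  if (!length(genomes)) stop("empty genome list")
  k <- as.integer(k)
  if (k %% 2L == 0L || k < 11L) stop("k must be odd and >= 11")
  leaf_tx <- vapply(genomes, function(g) g$taxon_path[length(g$taxon_path)], character(1))
  idx <- match(leaf_tx, tree$nodes)
  if (anyNA(idx)) stop("genome taxa missing from tree: ",
                       paste(leaf_tx[is.na(idx)], collapse = ", "))
  seqs <- vapply(genomes, `[[`, character(1), "sequence")
  db <- .kmer_db_build_cpp(seqs, idx, lca_table(tree), k)
  structure(list(k = k, hi = db$hi, lo = db$lo, taxon = db$taxon,
                 tree = tree,
                 source_genomes = vapply(genomes, `[[`, character(1), "id"),
                 source_taxa = leaf_tx),
            class = "kmer_db")
}

#' @export
print.kmer_db <- function(x, ...) {
  cat(sprintf("<kmer_db> k=%d, %s canonical k-mers, %d source genomes\n",
              x$k, format(length(x$hi), big.mark = ","),
              length(x$source_genomes)))
  invisible(x)
}

#' Dump a k-mer database as a data frame
#'
#' Decodes the stored canonical k-mers back to strings; intended for small
#' databases (inspection, diffing, and equivalence checks against
#' brute-force construction).
#'
#' @param db A `kmer_db`.
#' @return `data.frame` with columns `kmer` (sorted) and `taxon`.
#' @export
kmer_db_as_data_frame <- function(db) {
  data.frame(kmer = .kmer_decode_cpp(db$hi, db$lo, db$k),
             taxon = db$tree$nodes[db$taxon],
             stringsAsFactors = FALSE)
}

classify_engine <- function(db, sequences, return_hits = FALSE) {
  tree <- db$tree
  leaves <- match(leaf_nodes(tree), tree$nodes)
  res <- .kmer_classify_cpp(db$hi, db$lo, db$taxon, sequences, db$k,
                            ancestor_matrix(tree), leaves, lca_table(tree),
                            return_hits)
  assigned <- ifelse(res$assigned == 0L, NA_character_, tree$nodes[res$assigned])
  if (return_hits) {
    colnames(res$hits) <- tree$nodes
    list(assigned = assigned, hits = res$hits)
  } else list(assigned = assigned)
}

#' Classify a single read
#'
#' Collects k-mer hit counts per taxon over all canonical k-mers of the
#' read, scores each root-to-leaf path of the taxonomy by the sum of hits
#' on its nodes, and assigns the leaf of the maximal path; ties are
#' resolved by the LCA of all tied leaves. A read with no database k-mers
#' (including any read shorter than `k`) is unclassified.
#'
#' @param read Read sequence (character scalar) or a single-row [read_set].
#' @param db A `kmer_db`.
#' @return A list with `taxon` (assigned taxon name or `NA` for
#'   unclassified) and `hits` (named k-mer hit counts per taxon).
#' @export
classify_read <- function(read, db) {
  if (inherits(read, "read_set")) read <- read$reads$sequence[1L]
  res <- classify_engine(db, read, return_hits = TRUE)
  list(taxon = res$assigned[1L], hits = res$hits[1L, ])
}

#' Classify a read set and aggregate counts at genus rank
#'
#' Applies [classify_read()] logic to every read and aggregates read
#' counts per genus: a read counts toward a genus when its assigned taxon
#' is that genus or a genome below it. Reads assigned above genus rank
#' (domain or root) count toward no genus; unclassified reads are excluded
#' from all genus counts.
#'
#' An optional host pre-filter models re-alignment screening against the
#' host reference: reads whose fraction of host-lineage k-mer hits (among
#' all database hits) is at least `host_prefilter` are dropped before
#' classification. It requires the host lineage to be present in the
#' database.
#'
#' @param reads A [read_set] (or character vector of sequences).
#' @param db A `kmer_db`.
#' @param host_prefilter `NULL` (default, no pre-filter) or a fraction in
#'   (0, 1]; requires `host_taxon`.
#' @param host_taxon Taxon name whose lineage counts as host for the
#'   pre-filter.
#' @return An object of class `classification_result`: per-read
#'   `assignments`, named `genus_counts`, `n_unclassified`, `n_prefiltered`
#'   and the index of retained reads.
#' @export
classify_readset <- function(reads, db, host_prefilter = NULL, host_taxon = NULL) {
  sequences <- if (inherits(reads, "read_set")) reads$reads$sequence else as.character(reads)
  tree <- db$tree
  keep <- seq_along(sequences)
  n_prefiltered <- 0L
  if (!is.null(host_prefilter)) {
    if (is.null(host_taxon)) stop("host_prefilter requires host_taxon")
    res <- classify_engine(db, sequences, return_hits = TRUE)
    host_cols <- tree$nodes[vapply(tree$nodes, function(t)
      host_taxon %in% ancestors_of(tree, t), logical(1))]
    host_hits <- rowSums(res$hits[, host_cols, drop = FALSE])
    tot_hits <- rowSums(res$hits)
    frac <- ifelse(tot_hits > 0, host_hits / tot_hits, 0)
    keep <- which(frac < host_prefilter)
    n_prefiltered <- length(sequences) - length(keep)
    assigned <- res$assigned[keep]
  } else {
    assigned <- classify_engine(db, sequences)$assigned
  }
  genera <- tree$nodes[tree$rank == "genus"]
  anc <- ancestor_matrix(tree)
  genus_counts <- stats::setNames(integer(length(genera)), genera)
  tab <- table(assigned[!is.na(assigned)])
  for (tx in names(tab)) {
    g <- intersect(ancestors_of(tree, tx), genera)
    if (length(g)) genus_counts[g[1L]] <- genus_counts[g[1L]] + as.integer(tab[[tx]])
  }
  structure(list(assignments = assigned,
                 genus_counts = genus_counts,
                 n_unclassified = sum(is.na(assigned)),
                 n_prefiltered = n_prefiltered,
                 retained = keep),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification_result> %d reads (%d unclassified, %d prefiltered)\n",
              length(x$assignments) + x$n_prefiltered, x$n_unclassified,
              x$n_prefiltered))
  nz <- x$genus_counts[x$genus_counts > 0]
  if (length(nz)) {
    cat("  genus counts:\n")
    for (g in names(sort(nz, decreasing = TRUE)))
      cat(sprintf("    %-24s %d\n", g, nz[[g]]))
  }
  invisible(x)
}

#' Host-inclusion experiment
#'
#' The central database-composition demonstration: the same reads are
#' classified against a microbes-only database and against the same
#' database plus the host genome. Because the host-derived k-mers of a
#' contaminated draft then occur in two domains, their LCA collapses to
#' the root and the false genus assignments of host reads disappear.
#' Reported are per-genus counts under both databases, the fold decline
#' for the contaminated genus (denominator floored at 1), and — among the
#' reads the microbes-only database assigned to the contaminated genus —
#' the fraction whose recorded true source is the host genome.
#'
#' @param readset A [read_set] with provenance labels.
#' @param microbial_genomes List of [genome_record]s, one of which is the
#'   contaminated draft.
#' @param host_genome The host [genome_record]; its taxon path should sit
#'   under its own domain (e.g. `root;Eukaryota;host_genus;host`).
#' @param contaminated_id Genome id of the contaminated draft; must be one
#'   of `microbial_genomes`.
#' @param k K-mer width (default 31).
#' @return A list with `genus_counts` (matrix: genus x database),
#'   `contaminated_genus`, `fold_decline`, `host_fraction`,
#'   `n_unclassified` per database.
#' @export
host_inclusion_experiment <- function(readset, microbial_genomes, host_genome,
                                      contaminated_id, k = 31L) {
  ids <- vapply(microbial_genomes, `[[`, character(1), "id")
  if (!contaminated_id %in% ids)
    stop("contaminated genome '", contaminated_id,
         "' is not among the microbial genomes")
  cg <- microbial_genomes[[match(contaminated_id, ids)]]
  contaminated_genus <- cg$taxon_path[min(3L, length(cg$taxon_path))]
  tree <- build_taxonomy(c(microbial_genomes, list(host_genome)))
  db1 <- build_kmer_database(microbial_genomes, tree, k)
  db2 <- build_kmer_database(c(microbial_genomes, list(host_genome)), tree, k)
  r1 <- classify_readset(readset, db1)
  r2 <- classify_readset(readset, db2)
  counts <- cbind(microbes_only = r1$genus_counts,
                  microbes_plus_host = r2$genus_counts[names(r1$genus_counts)])
  c1 <- counts[contaminated_genus, "microbes_only"]
  c2 <- counts[contaminated_genus, "microbes_plus_host"]
  # which reads counted toward the contaminated genus under the microbes-only DB
  anc <- ancestor_matrix(tree)
  under <- tree$nodes[anc[, contaminated_genus] == 1L]
  in_genus <- !is.na(r1$assignments) & r1$assignments %in% under
  host_fraction <- if (any(in_genus))
    mean(readset$reads$true_source[in_genus] == host_genome$id) else NA_real_
  list(genus_counts = counts,
       contaminated_genus = contaminated_genus,
       fold_decline = c1 / max(c2, 1L),
       host_fraction = host_fraction,
       n_unclassified = c(microbes_only = r1$n_unclassified,
                          microbes_plus_host = r2$n_unclassified))
}
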