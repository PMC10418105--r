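#' Genome record with contamination provenance
#'
#' A genome is a DNA string plus a taxonomic label (`taxon_path`,
#' root-to-leaf) and a provenance table of `segments`: half-open 0-based
#' intervals `[start, end)` that tile the sequence and record which genome
#' each stretch of sequence truly came from. A clean genome has a single
#' segment sourced from itself; a contaminated draft carries an extra
#' segment sourced from the host. The taxon label never reflects the
#' contamination — mislabeling is the phenomenon under study.
#'
#' @param id Genome identifier.
#' @param taxon_path Character vector of taxon names from `"root"` to the
#'   genome-level leaf.
#' @param sequence DNA string over `A,C,G,T` (other letters are tolerated
#'   and skipped by the classifier).
#' @param segments `data.frame` with columns `start`, `end`, `source`
#'   (source genome id). Defaults to one segment covering the whole
#'   sequence, sourced from `id`.
#' @return An object of class `genome_record`.
#' @export
genome_record <- function(id, taxon_path, sequence, segments = NULL) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(taxon_path), length(taxon_path) >= 1L,
            is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  n <- nchar(sequence)
  if (is.null(segments)) {
    segments <- data.frame(start = 0, end = n, source = id,
                           stringsAsFactors = FALSE)
  }
  stopifnot(all(c("start", "end", "source") %in% names(segments)))
  segments$start <- as.numeric(segments$start)
  segments$end <- as.numeric(segments$end)
  o <- order(segments$start)
  segments <- segments[o, , drop = FALSE]
  row.names(segments) <- NULL
  if (segments$start[1L] != 0 || segments$end[nrow(segments)] != n ||
      (nrow(segments) > 1L &&
       any(segments$start[-1L] != segments$end[-nrow(segments)])))
    stop("segments must tile [0, ", n, ") without gaps or overlap")
  structure(list(id = id, taxon_path = taxon_path, sequence = sequence,
                 segments = segments),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s  (%s)\n  %s bp, %d segment(s)\n",
              x$id, paste(x$taxon_path, collapse = ";"),
              format(nchar(x$sequence), big.mark = ","), nrow(x$segments)))
  invisible(x)
}

#' @export
length.genome_record <- function(x) nchar(x$sequence)

#' Simulated read set with hidden true-origin labels
#'
#' Reads carry an audit trail: the genome they were drawn from, the 0-based
#' start position, and `true_source` — the id of the genome the covering
#' provenance segment was sourced from. For a read drawn from the
#' host-derived portion of a contaminated draft, `true_origin_genome` is the
#' draft but `true_source` is the host.
#'
#' @param reads `data.frame` with columns `id`, `sequence`,
#'   `true_origin_genome`, `true_origin_pos`, `true_source`.
#' @return An object of class `read_set`.
#' @export
read_set <- function(reads) {
  need <- c("id", "sequence", "true_origin_genome", "true_origin_pos", "true_source")
  stopifnot(is.data.frame(reads), all(need %in% names(reads)))
  if (nrow(reads) && any(nchar(reads$sequence) == 0L)) stop("empty read sequence")
  row.names(reads) <- NULL
  structure(list(reads = reads), class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("<read_set> %d reads", nrow(x$reads)))
  if (nrow(x$reads))
    cat(sprintf(", %d bp, sources: %s", nchar(x$reads$sequence[1L]),
                paste(names(table(x$reads$true_source)), collapse = ", ")))
  cat("\n")
  invisible(x)
}

#' @export
length.read_set <- function(x) nrow(x$reads)

#' Sample-by-genus count matrix with sample metadata
#'
#' The central container: a non-negative integer matrix (rows = samples,
#' columns = genera) plus per-sample metadata holding the class label
#' (e.g. cancer type), the sample type (`tumor`, `normal`, `blood`) and the
#' sequencing library size. The library size must be at least the row sum,
#' the difference being reads classified elsewhere (mostly host).
#'
#' @param counts Integer matrix with `dimnames` (sample ids, genus ids).
#' @param metadata `data.frame` with columns `sample_id`, `class_label`,
#'   `sample_type`, `library_size`, one row per sample of `counts`.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, metadata) {
  stopifnot(is.matrix(counts),
            nrow(counts) == 0L || !is.null(rownames(counts)),
            ncol(counts) == 0L || !is.null(colnames(counts)))
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  need <- c("sample_id", "class_label", "sample_type", "library_size")
  stopifnot(is.data.frame(metadata), all(need %in% names(metadata)))
  metadata <- metadata[match(rownames(counts), metadata$sample_id), , drop = FALSE]
  if (anyNA(metadata$sample_id))
    stop("metadata missing for samples: ",
         paste(setdiff(rownames(counts), metadata$sample_id), collapse = ", "))
  row.names(metadata) <- NULL
  metadata$library_size <- as.numeric(metadata$library_size)
  if (any(metadata$library_size <= 0)) stop("library_size must be positive")
  if (any(metadata$library_size < rowSums(counts)))
    stop("library_size must be >= row sum of counts")
  structure(list(counts = counts, metadata = metadata), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d samples x %d genera; %.1f%% zero entries\n",
              nrow(x$counts), ncol(x$counts), 100 * mean(x$counts == 0)))
  cat("  classes:", paste(unique(x$metadata$class_label), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Normalized expression-like matrix with provenance
#'
#' Holds the real-valued transform of a [count_matrix], along with a
#' provenance record (transform name, parameters, leak mode) and the facts
#' about the source that downstream forensics and leak modes need: which
#' raw feature columns were identically zero, and the library sizes.
#'
#' @param values Numeric matrix, same shape and dimnames as the source counts.
#' @param provenance Named list describing the transform.
#' @param zero_features Logical vector per feature: raw column all zero.
#' @param library_size Named numeric vector per sample.
#' @param source Optional source [count_matrix] (kept for leak modes that
#'   re-transform the raw counts).
#' @return An object of class `normalized_matrix`.
#' @export
normalized_matrix <- function(values, provenance, zero_features, library_size,
                              source = NULL) {
  stopifnot(is.matrix(values), is.numeric(values), all(is.finite(values)))
  stopifnot(length(zero_features) == ncol(values),
            length(library_size) == nrow(values))
  structure(list(values = values, provenance = provenance,
                 zero_features = zero_features, library_size = library_size,
                 source = source),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("<normalized_matrix> %d x %d; transform: %s; leak_mode: %s\n",
              nrow(x$values), ncol(x$values),
              x$provenance$transform %||% "?", x$provenance$leak_mode %||% "none"))
  invisible(x)
}

#' @export
dim.normalized_matrix <- function(x) dim(x$values)

`%||%` <- function(a, b) if (is.null(a)) b else a
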