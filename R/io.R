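#' Read and write genomes as FASTA with taxon-path headers
#'
#' Headers carry the taxon path (semicolon-separated, root first) after a
#' `"|"` delimiter, and optionally the provenance segments after a second
#' `"|"` as `start-end:source` (semicolon-separated), so that a write/read
#' round trip preserves the full [genome_record] including contamination
#' provenance. Sequences are uppercased on read; non-ACGT letters are
#' preserved (the classifier skips them).
#'
#' @param path File path.
#' @param genomes List of [genome_record]s (for writing).
#' @return `read_genomes_fasta()` returns a list of [genome_record]s
#'   (empty list for an empty file).
#' @name fasta_io
NULL

#' @rdname fasta_io
#' @export
read_genomes_fasta <- function(path) {
  if (file.size(path) == 0) return(list())
  dss <- Biostrings::readDNAStringSet(path)
  lapply(seq_along(dss), function(i) {
    hdr <- names(dss)[i]
    parts <- strsplit(hdr, "|", fixed = TRUE)[[1L]]
    if (length(parts) < 2L)
      stop("malformed FASTA header at record ", i,
           ": expected 'id|taxon;path[|segments]', got '", hdr, "'")
    segments <- NULL
    if (length(parts) >= 3L && nzchar(parts[3L])) {
      sp <- strsplit(strsplit(parts[3L], ";", fixed = TRUE)[[1L]], "[-:]")
      segments <- data.frame(
        start = as.numeric(vapply(sp, `[`, character(1), 1L)),
        end = as.numeric(vapply(sp, `[`, character(1), 2L)),
        source = vapply(sp, `[`, character(1), 3L),
        stringsAsFactors = FALSE)
    }
    genome_record(id = parts[1L],
                  taxon_path = strsplit(parts[2L], ";", fixed = TRUE)[[1L]],
                  sequence = toupper(as.character(dss[[i]])),
                  segments = segments)
  })
}

#' @rdname fasta_io
#' @export
write_genomes_fasta <- function(genomes, path) {
  if (inherits(genomes, "genome_record")) genomes <- list(genomes)
  dss <- Biostrings::DNAStringSet(vapply(genomes, `[[`, character(1), "sequence"))
  names(dss) <- vapply(genomes, function(g) {
    segs <- paste(sprintf("%d-%d:%s", as.integer(g$segments$start),
                          as.integer(g$segments$end), g$segments$source),
                  collapse = ";")
    paste(g$id, paste(g$taxon_path, collapse = ";"), segs, sep = "|")
  }, character(1))
  Biostrings::writeXStringSet(dss, path, width = 80L)
  invisible(path)
}

#' Read and write simulated reads as FASTQ with provenance comments
#'
#' The FASTQ comment field (after the first space in the header) carries
#' the hidden true origin as `origin=<genome>:<pos>:<source>`, so external
#' tools can consume the reads while the audit trail survives a round
#' trip. Qualities are written as a constant `I` (Phred 40); the simulator
#' does not model quality.
#'
#' @param path File path.
#' @param reads A [read_set] (for writing).
#' @return `read_reads_fastq()` returns a [read_set].
#' @name fastq_io
NULL

#' @rdname fastq_io
#' @export
write_reads_fastq <- function(reads, path) {
  stopifnot(inherits(reads, "read_set"))
  r <- reads$reads
  lines <- character(4L * nrow(r))
  lines[seq(1L, length(lines), 4L)] <-
    sprintf("@%s origin=%s:%d:%s", r$id, r$true_origin_genome,
            r$true_origin_pos, r$true_source)
  lines[seq(2L, length(lines), 4L)] <- r$sequence
  lines[seq(3L, length(lines), 4L)] <- "+"
  lines[seq(4L, length(lines), 4L)] <- strrep("I", nchar(r$sequence))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname fastq_io
#' @export
read_reads_fastq <- function(path) {
  dss <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = FALSE)
  hdr <- names(dss)
  sp <- regmatches(hdr, regexec("^(\\S+) origin=([^:]+):(\\d+):(\\S+)$", hdr))
  bad <- which(vapply(sp, length, integer(1)) != 5L)
  if (length(bad))
    stop("malformed FASTQ provenance comment at record ", bad[1L])
  read_set(data.frame(
    id = vapply(sp, `[`, character(1), 2L),
    sequence = as.character(dss),
    true_origin_genome = vapply(sp, `[`, character(1), 3L),
    true_origin_pos = as.integer(vapply(sp, `[`, character(1), 4L)),
    true_source = vapply(sp, `[`, character(1), 5L),
    stringsAsFactors = FALSE))
}

#' Read and write count matrices as TSV
#'
#' The matrix TSV has samples as rows and genera as columns, first column
#' `sample_id`; the metadata TSV is keyed by `sample_id` with columns
#' `class_label`, `sample_type`, `library_size`. Cells are validated as
#' non-negative integers; a violation is reported with its coordinates.
#'
#' @param path,meta_path File paths for the count and metadata tables.
#' @param x A [count_matrix] (for writing).
#' @return `read_counts_tsv()` returns a [count_matrix].
#' @name counts_io
NULL

#' @rdname counts_io
#' @export
write_counts_tsv <- function(x, path, meta_path) {
  stopifnot(inherits(x, "count_matrix"))
  dt <- data.table::data.table(sample_id = rownames(x$counts))
  for (cn in colnames(x$counts)) data.table::set(dt, j = cn, value = x$counts[, cn])
  data.table::fwrite(dt, path, sep = "\t")
  data.table::fwrite(x$metadata, meta_path, sep = "\t")
  invisible(path)
}

#' @rdname counts_io
#' @export
read_counts_tsv <- function(path, meta_path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  if (names(dt)[1L] != "sample_id") stop("first column must be sample_id")
  ids <- as.character(dt[[1L]])
  m <- as.matrix(dt[, -1L, drop = FALSE])
  for (j in seq_len(ncol(m))) {
    bad <- which(is.na(m[, j]) | m[, j] < 0 | m[, j] != round(m[, j]))
    if (length(bad))
      stop("non-integer or negative count at sample '", ids[bad[1L]],
           "', genus '", colnames(m)[j], "'")
  }
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  meta <- as.data.frame(data.table::fread(meta_path, sep = "\t", header = TRUE))
  count_matrix(m, meta)
}

#' Write a normalized matrix as TSV with a provenance sidecar
#'
#' @param x A [normalized_matrix].
#' @param path TSV path (samples as rows, first column `sample_id`).
#' @param provenance_path JSON sidecar path (default `path` +
#'   `".provenance.json"`).
#' @return The TSV path, invisibly.
#' @export
write_normalized_tsv <- function(x, path,
                                 provenance_path = paste0(path, ".provenance.json")) {
  stopifnot(inherits(x, "normalized_matrix"))
  dt <- data.table::data.table(sample_id = rownames(x$values))
  for (cn in colnames(x$values)) data.table::set(dt, j = cn, value = x$values[, cn])
  data.table::fwrite(dt, path, sep = "\t")
  jsonlite::write_json(
    list(provenance = x$provenance,
         zero_features = colnames(x$values)[x$zero_features]),
    provenance_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a normalized matrix written by [write_normalized_tsv()]
#'
#' @param path TSV path.
#' @param provenance_path JSON sidecar path.
#' @param library_size Optional per-sample library sizes (default 1).
#' @return A [normalized_matrix].
#' @export
read_normalized_tsv <- function(path,
                                provenance_path = paste0(path, ".provenance.json"),
                                library_size = NULL) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  ids <- as.character(dt[[1L]])
  m <- as.matrix(dt[, -1L, drop = FALSE])
  rownames(m) <- ids
  prov <- if (file.exists(provenance_path))
    jsonlite::read_json(provenance_path, simplifyVector = TRUE)
  else list(provenance = list(transform = "unknown"), zero_features = character(0))
  if (is.null(library_size)) library_size <- rep(1, nrow(m))
  normalized_matrix(m, provenance = as.list(prov$provenance),
                    zero_features = colnames(m) %in% prov$zero_features,
                    library_size = stats::setNames(rep_len(library_size, nrow(m)), ids))
}
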