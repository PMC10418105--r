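#' Simulate a random genome
#'
#' Bases are drawn i.i.d. with `P(G) + P(C) = gc`. The result carries a
#' single provenance segment covering the whole sequence, sourced from
#' itself.
#'
#' @param length Genome length in bases; must be at least 31 so that at
#'   least one default-width k-mer exists.
#' @param gc GC fraction in (0, 1).
#' @param seed Integer seed.
#' @param id Genome identifier.
#' @param taxon_path Root-to-leaf taxon names; defaults to a genus named
#'   after the id under domain `"Bacteria"`.
#' @return A [genome_record].
#' @export
simulate_genome <- function(length, gc = 0.5, seed = 1L,
                            id = "genome1",
                            taxon_path = c("root", "Bacteria", paste0("genus_", id), id)) {
  stopifnot(length >= 31)
  stopifnot(gc > 0, gc < 1)
  seqc <- with_rng(seed, {
    bases <- sample(c("A", "C", "G", "T"), length, replace = TRUE,
                    prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
    paste0(bases, collapse = "")
  })
  genome_record(id = id, taxon_path = taxon_path, sequence = seqc)
}

#' Contaminate a draft genome with a host-derived contig
#'
#' Models a mis-assembled draft: a contiguous substring of the host genome
#' (uniform random start) is appended to the microbial sequence, while the
#' taxon label stays microbial. The appended stretch is recorded as a
#' provenance segment sourced from the host, so reads drawn from it can be
#' audited later.
#'
#' @param microbe A [genome_record] (the draft to contaminate).
#' @param host A [genome_record] (the contamination source).
#' @param contig_length Length of the host-derived contig; `0` returns the
#'   microbe unchanged.
#' @param seed Integer seed for the contig start position.
#' @return A [genome_record] with unchanged `taxon_path` and an extra
#'   host-sourced segment.
#' @export
contaminate_draft <- function(microbe, host, contig_length, seed = 1L) {
  stopifnot(inherits(microbe, "genome_record"), inherits(host, "genome_record"))
  hl <- nchar(host$sequence)
  if (contig_length > hl) stop("contig_length exceeds host genome length")
  if (contig_length == 0) return(microbe)
  start <- with_rng(seed, sample.int(hl - contig_length + 1L, 1L) - 1L)
  contig <- substr(host$sequence, start + 1L, start + contig_length)
  ml <- nchar(microbe$sequence)
  segs <- rbind(microbe$segments,
                data.frame(start = ml, end = ml + contig_length,
                           source = host$id, stringsAsFactors = FALSE))
  genome_record(id = microbe$id, taxon_path = microbe$taxon_path,
                sequence = paste0(microbe$sequence, contig),
                segments = segs)
}

#' Simulate fixed-length single-end reads with known origin
#'
#' Start positions are uniform over `[0, genome_length - read_length]`
#' (reads never wrap the genome end); substitution errors are i.i.d. per
#' base at `error_rate`; no indels. Each read records its source genome,
#' its start position, and `true_source`: the source of the provenance
#' segment covering the start position, which is how reads drawn from a
#' contaminated stretch of a draft are later recognized as host reads.
#'
#' @param genomes List of [genome_record]s.
#' @param n_reads Integer vector, reads to draw per genome (recycled if
#'   scalar).
#' @param read_length Read length in bases; must not exceed any genome
#'   length.
#' @param error_rate Per-base substitution probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return A [read_set].
#' @export
simulate_reads <- function(genomes, n_reads, read_length = 150L,
                           error_rate = 0.001, seed = 1L) {
  if (inherits(genomes, "genome_record")) genomes <- list(genomes)
  n_reads <- as.integer(rep_len(n_reads, length(genomes)))
  stopifnot(error_rate >= 0, error_rate < 1)
  glens <- vapply(genomes, function(g) nchar(g$sequence), integer(1))
  if (any(read_length > glens)) stop("read_length exceeds a genome length")
  with_rng(seed, {
    parts <- lapply(seq_along(genomes), function(i) {
      g <- genomes[[i]]
      n <- n_reads[i]
      if (n == 0L) return(NULL)
      starts <- sample.int(glens[i] - read_length + 1L, n, replace = TRUE) - 1L
      seqs <- substring(g$sequence, starts + 1L, starts + read_length)
      if (error_rate > 0) {
        nerr <- stats::rbinom(n, read_length, error_rate)
        for (j in which(nerr > 0L)) {
          ch <- strsplit(seqs[j], "", fixed = TRUE)[[1L]]
          pos <- sample.int(read_length, nerr[j])
          for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
          seqs[j] <- paste0(ch, collapse = "")
        }
      }
      seg_idx <- findInterval(starts, g$segments$start)
      data.frame(id = sprintf("%s_r%06d", g$id, seq_len(n)),
                 sequence = seqs,
                 true_origin_genome = g$id,
                 true_origin_pos = starts,
                 true_source = g$segments$source[seg_idx],
                 stringsAsFactors = FALSE)
    })
    read_set(do.call(rbind, c(parts, list(make.row.names = FALSE))))
  })
}

#' Simulate a raw sample-by-genus count matrix
#'
#' Emulates the structure of genus-level classification matrices from
#' host-dominated samples: a majority of zero entries, a block of common
#' genera with overdispersed counts, rare genera present in only a handful
#' of samples, and genera with no reads at all. Counts are drawn
#' identically across classes — the raw matrix carries **no** class signal,
#' which is exactly what makes it a null substrate for leakage experiments.
#'
#' Common features are negative binomial with variance
#' `mu + dispersion * mu^2`. Each rare feature is non-zero in exactly
#' `rare_prevalence` randomly chosen samples. Library size is the row sum
#' plus a host-read allowance, reflecting that most reads in such samples
#' are host-derived and unclassified here.
#'
#' @param classes Character vector of class labels.
#' @param n_per_class Samples per class (scalar or per-class vector).
#' @param n_common_features,n_rare_features,n_zero_features Feature counts
#'   per block.
#' @param nb_mean,nb_dispersion Negative binomial mean and dispersion `phi`
#'   (variance `mu + phi mu^2`).
#' @param rare_prevalence Number of samples in which each rare feature is
#'   non-zero; must be less than the total sample count.
#' @param host_reads Host-read allowance added to each library size.
#' @param sample_type Sample type label(s), recycled across samples.
#' @param seed Integer seed.
#' @return A [count_matrix].
#' @export
simulate_count_matrix <- function(classes, n_per_class,
                                  n_common_features = 20L,
                                  n_rare_features = 10L,
                                  n_zero_features = 10L,
                                  nb_mean = 50, nb_dispersion = 0.5,
                                  rare_prevalence = 3L,
                                  host_reads = 1e6,
                                  sample_type = "tumor",
                                  seed = 1L) {
  stopifnot(length(classes) >= 1L, nb_mean > 0, nb_dispersion > 0)
  n_per_class <- rep_len(as.integer(n_per_class), length(classes))
  n <- sum(n_per_class)
  if (rare_prevalence >= n) stop("rare_prevalence must be < total sample count")
  cls <- rep(classes, n_per_class)
  sample_ids <- sprintf("s%04d", seq_len(n))
  feat <- c(sprintf("genus_common%03d", seq_len(n_common_features)),
            sprintf("genus_rare%03d", seq_len(n_rare_features)),
            sprintf("genus_zero%03d", seq_len(n_zero_features)))
  with_rng(seed, {
    counts <- matrix(0L, n, length(feat), dimnames = list(sample_ids, feat))
    if (n_common_features > 0L)
      counts[, seq_len(n_common_features)] <-
        stats::rnbinom(n * n_common_features, mu = nb_mean, size = 1 / nb_dispersion)
    for (j in seq_len(n_rare_features)) {
      rows <- sample.int(n, rare_prevalence)
      counts[rows, n_common_features + j] <-
        1L + stats::rnbinom(rare_prevalence, mu = nb_mean / 10, size = 1 / nb_dispersion)
    }
    meta <- data.frame(sample_id = sample_ids, class_label = cls,
                       sample_type = rep_len(sample_type, n),
                       library_size = rowSums(counts) + host_reads,
                       stringsAsFactors = FALSE)
    count_matrix(counts, meta)
  })
}
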