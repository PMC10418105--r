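#' Designed contamination simulation
#'
#' The package's standard demonstration of database-driven read-count
#' inflation, at a deliberately modest genome scale: a 1 Mbp host genome;
#' ten 200 kbp microbial genomes in distinct genera; one microbe augmented
#' with a 100 kbp host-derived contig while keeping its microbial label;
#' 100,000 error-free 150 bp reads drawn uniformly from the host plus 50
#' reads from the clean portion of the contaminated microbe. The read set
#' is classified with the 31-mer LCA classifier against a microbes-only
#' database and against the same database plus the host genome.
#'
#' About a tenth of the host reads fall inside the region copied into the
#' draft, so the microbes-only database assigns them to the contaminated
#' genus; adding the host genome sends the shared k-mers to the root and
#' the genus count collapses to the 50 genuine microbial reads.
#'
#' @param seed Integer seed; all stage seeds derive from it.
#' @param n_host_reads,n_microbe_reads Read counts (defaults 100,000 / 50).
#' @param host_length,microbe_length,contig_length Genome geometry
#'   (defaults 1e6 / 2e5 / 1e5 bases).
#' @param n_microbes Number of microbial genomes (default 10).
#' @param read_length Read length (default 150).
#' @param k K-mer width (default 31).
#' @return The [host_inclusion_experiment()] report.
#' @export
contamination_experiment <- function(seed = 1L,
                                     n_host_reads = 100000L,
                                     n_microbe_reads = 50L,
                                     host_length = 1000000L,
                                     microbe_length = 200000L,
                                     contig_length = 100000L,
                                     n_microbes = 10L,
                                     read_length = 150L,
                                     k = 31L) {
  host <- simulate_genome(host_length, gc = 0.41,
                          seed = child_seed(seed, "host"), id = "host",
                          taxon_path = c("root", "Eukaryota", "genus_host", "host"))
  microbes <- lapply(seq_len(n_microbes), function(i)
    simulate_genome(microbe_length, gc = 0.5,
                    seed = child_seed(seed, paste0("microbe", i)),
                    id = paste0("m", i)))
  clean_m1 <- microbes[[1L]]
  microbes[[1L]] <- contaminate_draft(clean_m1, host, contig_length,
                                      seed = child_seed(seed, "contig"))
  # the 50 microbial reads come from the clean portion of the draft,
  # i.e. the original (pre-contamination) sequence
  reads <- simulate_reads(list(host, clean_m1),
                          n_reads = c(n_host_reads, n_microbe_reads),
                          read_length = read_length, error_rate = 0,
                          seed = child_seed(seed, "reads"))
  host_inclusion_experiment(reads, microbes, host, "m1", k = k)
}

#' Designed information-free leakage simulation
#'
#' The package's standard demonstration of normalization label leakage:
#' a raw count matrix of `n_classes * n_per_class` samples by `n_features`
#' genera that is identically zero (so it carries no information
#' whatsoever), transformed to log-CPM and then put through
#' [supervised_normalize()] with `leak_mode = "class_offsets"` (per-class
#' per-feature offsets `N(0, offset_sd^2)`, within-class noise
#' `N(0, noise_sd^2)`). One-vs-all gradient-boosted classifiers are then
#' trained and evaluated by stratified cross-validation on the populated
#' matrix via [run_fig6_experiment()].
#'
#' With `leak_mode = "none"` the same pipeline is an honest null: median
#' AUC sits at chance.
#'
#' @param seed Integer seed.
#' @param n_classes,n_per_class,n_features Problem size (defaults 32 /
#'   100 / 66).
#' @param leak_mode Passed to [supervised_normalize()].
#' @param offset_sd,noise_sd Leak generator parameters (defaults 1, 0.05).
#' @param n_folds,n_estimators,max_depth,learning_rate Classifier
#'   configuration (defaults 10, 150, 3, 0.1).
#' @return The [run_fig6_experiment()] result.
#' @export
leakage_experiment <- function(seed = 1L, n_classes = 32L, n_per_class = 100L,
                               n_features = 66L, leak_mode = "class_offsets",
                               offset_sd = 1, noise_sd = 0.05,
                               n_folds = 10L, n_estimators = 150L,
                               max_depth = 3L, learning_rate = 0.1) {
  cm <- simulate_count_matrix(sprintf("C%02d", seq_len(n_classes)), n_per_class,
                              n_common_features = 0L, n_rare_features = 0L,
                              n_zero_features = n_features,
                              seed = child_seed(seed, "counts"))
  biological <- if (leak_mode == "none") rep("all", nrow(cm$counts))
                else cm$metadata$class_label
  norm <- supervised_normalize(voom_logcpm(cm), biological,
                               leak_mode = leak_mode,
                               offset_sd = offset_sd, noise_sd = noise_sd,
                               seed = child_seed(seed, "leak"))
  run_fig6_experiment(cm, norm, n_folds = n_folds,
                      n_estimators = n_estimators, max_depth = max_depth,
                      learning_rate = learning_rate,
                      seed = child_seed(seed, "eval"))
}
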