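# Independent brute-force oracles used to check the fast implementations.

revcomp_chr <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1L]]),
        collapse = "")
}

canonical_chr <- function(s) {
  r <- revcomp_chr(s)
  if (s <= r) s else r
}

# enumerate all canonical k-mers of a sequence (windows with non-ACGT skipped)
enumerate_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  subs <- substring(seq, 1:(n - k + 1L), k:n)
  subs <- subs[!grepl("[^ACGT]", subs)]
  vapply(subs, canonical_chr, character(1), USE.NAMES = FALSE)
}

# set-based LCA database construction: kmer -> LCA over genomes containing it
brute_kmer_db <- function(genomes, tree, k) {
  per_genome <- lapply(genomes, function(g) unique(enumerate_kmers(g$sequence, k)))
  taxa <- vapply(genomes, function(g) g$taxon_path[length(g$taxon_path)], character(1))
  km <- sort(unique(unlist(per_genome)))
  tax <- vapply(km, function(x) {
    holders <- taxa[vapply(per_genome, function(s) x %in% s, logical(1))]
    Reduce(function(a, b) taxon_lca(tree, a, b), holders)
  }, character(1), USE.NAMES = FALSE)
  data.frame(kmer = km, taxon = tax, stringsAsFactors = FALSE)
}

# ancestor-set-intersection LCA
brute_lca <- function(tree, a, b) {
  chain <- function(t) {
    out <- character(0)
    while (!is.na(t)) { out <- c(out, t); t <- tree$parent[[t]] }
    out
  }
  common <- intersect(chain(a), chain(b))
  depth <- vapply(common, function(t) length(chain(t)), integer(1))
  common[which.max(depth)]
}

# brute-force confusion matrix for a threshold rule
brute_rule <- function(values, labels, threshold, direction) {
  cmp <- switch(direction, ge = `>=`, gt = `>`, le = `<=`, lt = `<`)
  pred <- cmp(values, threshold)
  tp <- sum(pred & labels); fp <- sum(pred & !labels)
  fn <- sum(!pred & labels); tn <- sum(!pred & !labels)
  list(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
       error_rate = (fp + fn) / length(labels), n_errors = fp + fn)
}

# write literal text to a temp file and return its path
textConnection_write <- function(txt) {
  p <- tempfile(fileext = ".txt")
  cat(txt, file = p)
  p
}

make_host <- function(len = 5000, seed = 99)
  simulate_genome(len, gc = 0.41, seed = seed, id = "host",
                  taxon_path = c("root", "Eukaryota", "genus_host", "host"))
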