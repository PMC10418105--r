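test_that("database of a single 31 bp genome holds exactly one k-mer", {
  g <- simulate_genome(31, seed = 1, id = "g1")
  db <- build_kmer_database(list(g), k = 31)
  df <- kmer_db_as_data_frame(db)
  expect_equal(nrow(df), 1L)
  expect_equal(df$taxon, "g1")
  expect_equal(df$kmer, canonical_chr(g$sequence))
})

test_that("a k-mer shared by sibling-genus genomes maps to their domain", {
  shared <- strrep("ACGTTGCAGTC", 4)  # 44 bp, contains shared 31-mers
  g1 <- genome_record("g1", c("root", "Bacteria", "G1", "g1"),
                      paste0(shared, simulate_genome(100, seed = 2)$sequence))
  g2 <- genome_record("g2", c("root", "Bacteria", "G2", "g2"),
                      paste0(simulate_genome(100, seed = 3)$sequence, shared))
  db <- build_kmer_database(list(g1, g2), k = 31)
  df <- kmer_db_as_data_frame(db)
  shared_kmers <- enumerate_kmers(shared, 31)
  expect_true(all(df$taxon[df$kmer %in% shared_kmers] == "Bacteria"))
})

test_that("database equals brute-force set-based construction on small genomes", {
  host <- make_host(2000)
  g1 <- simulate_genome(2000, seed = 21, id = "m1")
  g2 <- simulate_genome(1500, seed = 22, id = "m2")
  g2 <- genome_record("m2", g2$taxon_path,
                      paste0(g2$sequence, substr(g1$sequence, 501, 700)))
  draft <- contaminate_draft(g1, host, 300, seed = 23)
  genomes <- list(draft, g2, host)
  tree <- build_taxonomy(genomes)
  for (k in c(11L, 31L)) {
    db <- build_kmer_database(genomes, tree, k = k)
    got <- kmer_db_as_data_frame(db)
    want <- brute_kmer_db(genomes, tree, k)
    expect_equal(got$kmer, want$kmer)
    expect_equal(got$taxon, want$taxon)
  }
})

test_that("genomes shorter than k contribute nothing; k is validated", {
  tiny <- genome_record("t1", c("root", "Bacteria", "Gt", "t1"), strrep("A", 20))
  g <- simulate_genome(100, seed = 5, id = "g1")
  db <- build_kmer_database(list(g, tiny), k = 31)
  expect_false("t1" %in% kmer_db_as_data_frame(db)$taxon)
  expect_error(build_kmer_database(list(g), k = 30), "odd")
  expect_error(build_kmer_database(list(), k = 31), "empty")
})

test_that("classification is strand-symmetric and conserves reads", {
  g1 <- simulate_genome(3000, seed = 6, id = "m1")
  g2 <- simulate_genome(3000, seed = 7, id = "m2")
  db <- build_kmer_database(list(g1, g2), k = 31)
  rs <- simulate_reads(list(g1, g2), c(30, 30), read_length = 100,
                       error_rate = 0, seed = 8)
  for (i in c(1, 15, 60)) {
    s <- rs$reads$sequence[i]
    expect_identical(classify_read(s, db)$hits,
                     classify_read(revcomp_chr(s), db)$hits)
  }
  res <- classify_readset(rs, db)
  expect_equal(sum(!is.na(res$assignments)) + res$n_unclassified, 60L)
  expect_equal(unname(res$genus_counts[c("genus_m1", "genus_m2")]), c(30L, 30L))
})

test_that("reads with no database k-mers are unclassified", {
  g <- simulate_genome(2000, seed = 9, id = "m1")
  db <- build_kmer_database(list(g), k = 31)
  other <- simulate_genome(2000, seed = 10, id = "x")
  expect_true(is.na(classify_read(substr(other$sequence, 1, 100), db)$taxon))
  expect_true(is.na(classify_read("ACGT", db)$taxon))  # shorter than k
  empty <- classify_readset(character(0), db)
  expect_true(all(empty$genus_counts == 0L))
})

test_that("tied root-to-leaf path scores resolve to the LCA of the tied leaves", {
  base <- simulate_genome(37, seed = 11)$sequence  # 37 = k + 6, 7 k-mers
  k <- 31
  shared <- substr(base, 1, k + 2)     # k-mers 1..3
  ua <- substr(base, 4, k + 4)         # k-mers 4..5
  ub <- substr(base, 6, k + 6)         # k-mers 6..7
  gA <- genome_record("gA", c("root", "Bacteria", "GX", "gA"),
                      paste0(shared, "NN", ua))
  gB <- genome_record("gB", c("root", "Bacteria", "GX", "gB"),
                      paste0(shared, "NN", ub))
  db <- build_kmer_database(list(gA, gB), k = k)
  res <- classify_read(base, db)
  # verify the intended hit profile before asserting the tie-break
  expect_equal(unname(res$hits[c("GX", "gA", "gB")]), c(3, 2, 2))
  expect_equal(res$taxon, "GX")
})

test_that("adding the host genome never increases host-origin microbial assignments", {
  host <- make_host(20000)
  microbes <- lapply(1:3, function(i)
    simulate_genome(5000, seed = 30 + i, id = paste0("m", i)))
  microbes[[1]] <- contaminate_draft(microbes[[1]], host, 2000, seed = 34)
  rs <- simulate_reads(c(list(host), microbes), c(2000, 50, 50, 50),
                       read_length = 100, error_rate = 0, seed = 35)
  tree <- build_taxonomy(c(microbes, list(host)))
  db1 <- build_kmer_database(microbes, tree, k = 31)
  db2 <- build_kmer_database(c(microbes, list(host)), tree, k = 31)
  r1 <- classify_readset(rs, db1)
  r2 <- classify_readset(rs, db2)
  host_origin <- rs$reads$true_source == "host"
  for (tx in setdiff(tree$nodes, c("root", "Eukaryota", "genus_host", "host"))) {
    n1 <- sum(host_origin & !is.na(r1$assignments) & r1$assignments == tx)
    n2 <- sum(host_origin & !is.na(r2$assignments) & r2$assignments == tx)
    expect_lte(n2, n1)
  }
})

test_that("host-inclusion experiment quantifies the collapse of false assignments", {
  host <- make_host(50000)
  microbes <- lapply(1:3, function(i)
    simulate_genome(10000, seed = 40 + i, id = paste0("m", i)))
  clean_m1 <- microbes[[1]]
  microbes[[1]] <- contaminate_draft(microbes[[1]], host, 5000, seed = 44)
  rs <- simulate_reads(c(list(host), list(clean_m1)), c(5000, 20),
                       read_length = 100, error_rate = 0, seed = 45)
  expect_error(host_inclusion_experiment(rs, microbes, host, "nope"),
               "not among")
  ex <- host_inclusion_experiment(rs, microbes, host, "m1", k = 31)
  expect_equal(ex$contaminated_genus, "genus_m1")
  expect_gt(ex$fold_decline, 10)
  expect_gt(ex$host_fraction, 0.95)
  # with no host reads present there is nothing to collapse
  rs2 <- simulate_reads(list(clean_m1), 200, read_length = 100,
                        error_rate = 0, seed = 46)
  ex2 <- host_inclusion_experiment(rs2, microbes, host, "m1", k = 31)
  expect_equal(ex2$fold_decline, 1)
})

test_that("host pre-filter drops reads dominated by host-lineage k-mers", {
  host <- make_host(20000)
  m1 <- simulate_genome(5000, seed = 50, id = "m1")
  tree <- build_taxonomy(list(m1, host))
  db <- build_kmer_database(list(m1, host), tree, k = 31)
  rs <- simulate_reads(c(list(host), list(m1)), c(100, 100),
                       read_length = 100, error_rate = 0, seed = 51)
  res <- classify_readset(rs, db, host_prefilter = 0.5, host_taxon = "host")
  expect_equal(res$n_prefiltered, 100L)
  expect_true(all(rs$reads$true_source[res$retained] == "m1"))
})
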