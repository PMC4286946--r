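test_that("a featureless spec yields an empty feature set and valid files", {
  spec <- genome_spec(n_chromosomes = 1, chrom_length = 10000,
                      repeat_copies = 0, gene_models = 0,
                      structural_rna_loci = c(tRNA = 0), pirna_clusters = 0,
                      seed = 1)
  g <- build_genome(spec)
  expect_length(g$features, 0)
  expect_length(g$clusters, 0)
  d <- tempfile()
  paths <- write_genome(g, d)
  fa <- Biostrings::readDNAStringSet(paths$fasta)
  expect_equal(unname(Biostrings::width(fa)), 10000)
  expect_true(file.exists(paths$gff3))
})

test_that("genome construction is deterministic and round-trips", {
  spec <- genome_spec(n_chromosomes = 2, chrom_length = 20000,
                      repeat_copies = 5, gene_models = 2,
                      pirna_clusters = 1, seed = 99)
  d1 <- tempfile(); d2 <- tempfile()
  p1 <- write_genome(build_genome(spec), d1)
  p2 <- write_genome(build_genome(spec), d2)
  for (f in c("fasta", "gff3")) {
    expect_identical(unname(tools::md5sum(p1[[f]])),
                     unname(tools::md5sum(p2[[f]])))
  }
  g <- build_genome(spec)
  g2 <- read_genome(p1$fasta, p1$gff3, p1$clusters)
  expect_identical(as.character(g2$seqs), as.character(g$seqs))
  expect_equal(length(g2$features), length(g$features))
  expect_setequal(g2$features$category, g$features$category)
  expect_equal(BiocGenerics::start(g2$clusters),
               BiocGenerics::start(g$clusters))
})

test_that("planted repeat copies are non-overlapping and total the expected span", {
  spec <- genome_spec(n_chromosomes = 1, chrom_length = 1e5,
                      repeat_copies = 20, repeat_length = 300,
                      gene_models = 0, structural_rna_loci = c(tRNA = 0),
                      pirna_clusters = 0, seed = 21)
  g <- build_genome(spec)
  df <- as.data.frame(g$features)
  expect_equal(nrow(df), 20)
  expect_true(all(df$category == "repeat"))
  expect_equal(sum(df$width), 6000)
  expect_true(all(df$start >= 1 & df$end <= 1e5))
  # brute-force pairwise overlap scan
  df <- df[order(df$start), ]
  for (i in seq_len(nrow(df) - 1)) {
    expect_true(df$start[i + 1] > df$end[i])
  }
})

test_that("infeasible packing fails naming the offending category", {
  spec <- genome_spec(n_chromosomes = 1, chrom_length = 1000,
                      repeat_copies = 10, repeat_length = 300,
                      gene_models = 0, structural_rna_loci = c(tRNA = 0),
                      pirna_clusters = 0, seed = 1)
  expect_error(build_genome(spec), "infeasible packing.*repeat")
})

test_that("zero-depth simulation yields empty FASTQ and truth, not an error", {
  g <- small_genome()
  lib <- simulate_library(g, pgc_profile(depth = 0), seed = 1)
  expect_length(lib$seq, 0)
  expect_equal(nrow(lib$truth), 0)
  fq <- tempfile(fileext = ".fastq")
  write_fastq(lib, fq)
  expect_equal(length(readLines(fq)), 0)
})

test_that("weight on a class without features is an explicit failure", {
  spec <- genome_spec(n_chromosomes = 1, chrom_length = 50000,
                      repeat_copies = 2, gene_models = 1,
                      structural_rna_loci = c(miRNA = 0), pirna_clusters = 1,
                      seed = 3)
  g <- build_genome(spec)
  expect_error(simulate_library(g, pgc_profile(depth = 100), seed = 1),
               "miRNA_like.*no matching feature")
})

test_that("simulation conserves read counts and is byte-deterministic", {
  g <- small_genome()
  prof <- pgc_profile(depth = 5000)
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  lib1 <- simulate_library(g, prof, seed = 5, fastq = f1)
  lib2 <- simulate_library(g, prof, seed = 5, fastq = f2)
  expect_equal(length(lib1$seq), 5000)
  expect_equal(nrow(lib1$truth), 5000)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  lib3 <- simulate_library(g, prof, seed = 6)
  expect_false(identical(lib1$seq, lib3$seq))
})

test_that("empirical class proportions recover the profile weights", {
  g <- small_genome()
  prof <- pgc_profile(depth = 20000)
  lib <- small_pgc_library()
  w <- prof$class_weights
  tab <- table(factor(lib$truth$class, levels = names(w))) / length(lib$seq)
  se <- sqrt(w * (1 - w) / length(lib$seq))
  expect_true(all(abs(as.vector(tab) - w) <= 3 * se + 1e-12))
})

test_that("the 1U bias of cluster reads matches the configured fraction", {
  g <- small_genome()
  prof <- pgc_profile(depth = 10000)
  lib <- simulate_library(g, prof, seed = 13)
  cl <- lib$truth$class == "repeat_piRNA_cluster"
  frac_t <- mean(substr(lib$seq[cl], 1, 1) == "T")
  # configured 0.9 plus ~1/4 chance on unedited reads; binomial tolerance
  expect_gte(frac_t, 0.85)
  se <- sqrt(0.9 * 0.1 / sum(cl))
  expect_gte(frac_t, 0.9 - 3 * se) # at least the planted fraction
})

test_that("cluster reads respect the main-strand fraction", {
  lib <- small_pgc_library()
  tr <- lib$truth[lib$truth$class == "repeat_piRNA_cluster", ]
  g <- small_genome()
  main <- as.data.frame(g$clusters)
  main_of <- setNames(main$main_strand, main$id)
  on_main <- tr$strand == main_of[tr$feature_id]
  se <- sqrt(0.9 * 0.1 / nrow(tr))
  expect_lt(abs(mean(on_main) - 0.9), 3 * se)
})
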