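sig_seq <- function(n, len = 28L) {
  vapply(seq_len(n), function(i)
    paste0("T", strrep("C", len - 1L)), character(1))
}

nosig_seq <- function(n, len = 28L) {
  vapply(seq_len(n), function(i) strrep("G", len), character(1))
}

# n single-locus tags in a tight region of a 100 kb bare chromosome
tight_mapping <- function(n, strand = rep("+", n), seqs = sig_seq(n),
                          at = 10000L, spacing = 40L) {
  len <- nchar(seqs)
  loci <- data.frame(tag = seq_len(n), chrom = rep("chr1", n),
                     start = at + (seq_len(n) - 1L) * spacing,
                     end = at + (seq_len(n) - 1L) * spacing + len,
                     strand = strand, identity = rep(1, n),
                     coverage = rep(1, n), mismatches = rep(0L, n),
                     stringsAsFactors = FALSE)
  manual_mapping(loci, seqs)
}

bg100k <- function() fixture("bg100k", bare_genome(c(chr1 = 100000L)))

test_that("one_u_ten_a follows the 1U-or-10A rule", {
  expect_true(one_u_ten_a("TGGGGGGGGGGG"))          # 1U only
  expect_true(one_u_ten_a("GGGGGGGGGAGG"))          # 10A only
  expect_true(one_u_ten_a("TGGGGGGGGAGG"))          # both
  expect_false(one_u_ten_a("GGGGGGGGGGGG"))         # neither
  expect_equal(one_u_ten_a(c("TGGGGGGGGG", "CGGGGGGGGC")), c(TRUE, FALSE))
  expect_warning(res <- one_u_ten_a("TGGGG"), "shorter than 10")
  expect_false(res)
})

test_that("strand_bias_score is main over minor with a floor of 1", {
  expect_equal(strand_bias_score(c("+", "+", "-")), 2)
  expect_equal(strand_bias_score(rep("+", 3)), 3)   # minor floored at 1
  expect_equal(strand_bias_score(c(rep("+", 13), rep("-", 10))), 1.3)
  expect_equal(strand_bias_score(rep("+", 3), rep(0.2, 3)), 0.6)
  expect_equal(strand_bias_score(c("+", "-"), c(1, 4)), 4)  # sign-free
})

test_that("min_loci separates 5-locus from 6-locus candidates", {
  g <- bg100k()
  c5 <- scan_clusters(tight_mapping(5), g)
  expect_equal(nrow(c5), 1)
  expect_false(c5$accepted)
  expect_equal(c5$n_loci, 5L)
  c6 <- scan_clusters(tight_mapping(6), g)
  expect_equal(nrow(c6), 1)
  expect_true(c6$accepted)
  expect_equal(c6$n_loci, 6L)
  expect_equal(c6$n_tags, 6L)
  expect_equal(c6$chrom, "chr1")
  # trimmed to the outermost loci
  expect_equal(c6$start, 10000L)
  expect_equal(c6$end, 10000L + 5L * 40L + 28L)
  expect_equal(c6$main_strand, "+")
  expect_equal(c6$frac_1u10a, 1)
  expect_equal(c6$frac_typical_length, 1)
  expect_lt(c6$density_p, 1e-6)
})

test_that("the strand-bias threshold applies to the weighted counts", {
  g <- bg100k()
  m42 <- tight_mapping(6, strand = c(rep("+", 4), rep("-", 2)))
  r <- scan_clusters(m42, g)
  expect_equal(r$strand_bias_score, 2)
  expect_true(r$accepted)
  expect_false(scan_clusters(m42, g,
                             cluster_params(min_strand_bias_score = 3))$accepted)
  m33 <- tight_mapping(6, strand = rep(c("+", "-"), 3))
  r33 <- scan_clusters(m33, g)
  expect_equal(r33$strand_bias_score, 1)
  expect_false(r33$accepted)
  expect_equal(r33$main_strand, "+") # ties resolve to plus
})

test_that("length and 1U/10A composition gates reject atypical clusters", {
  g <- bg100k()
  # 22-nt tags: signature present but outside the 26-32 nt typical range
  short <- scan_clusters(tight_mapping(6, seqs = sig_seq(6, 22L)), g)
  expect_false(short$accepted)
  expect_equal(short$frac_typical_length, 0)
  expect_equal(short$frac_1u10a, 1)
  # 28-nt tags without the signature
  plain <- scan_clusters(tight_mapping(6, seqs = nosig_seq(6)), g)
  expect_false(plain$accepted)
  expect_equal(plain$frac_1u10a, 0)
  # both gates relax under permissive thresholds
  lax <- cluster_params(min_length_fraction = 0, min_1u10a_fraction = 0)
  expect_true(scan_clusters(tight_mapping(6, seqs = nosig_seq(6, 22L)),
                            g, lax)$accepted)
})

test_that("one-over-n-loci weighting discounts multi-mapping tags", {
  g <- bg100k()
  seqs <- sig_seq(6)
  # tags 1-5 map once on plus; tag 6 maps 5 times on minus, all inside
  loci <- data.frame(
    tag = c(1:5, rep(6L, 5)), chrom = "chr1",
    start = 10000L + (0:9) * 40L, end = 10000L + (0:9) * 40L + 28L,
    strand = c(rep("+", 5), rep("-", 5)),
    identity = 1, coverage = 1, mismatches = 0L, stringsAsFactors = FALSE)
  m <- manual_mapping(loci, seqs)
  expect_equal(m$n_loci, c(1L, 1L, 1L, 1L, 1L, 5L))
  r <- scan_clusters(m, g) # weighted: 5 vs max(5 * (1/5), 1) = 5
  expect_equal(r$strand_bias_score, 5)
  expect_true(r$accepted)
  ru <- scan_clusters(m, g, cluster_params(locus_weighting = "uniform"))
  expect_equal(ru$strand_bias_score, 1)
  expect_false(ru$accepted)
})

test_that("overlapping significant windows merge into one trimmed cluster", {
  g <- bg100k()
  m <- tight_mapping(12, seqs = sig_seq(12), at = 4000L, spacing = 420L)
  r <- scan_clusters(m, g)
  expect_equal(nrow(r), 1)
  expect_equal(r$start, 4000L)
  expect_equal(r$end, 4000L + 11L * 420L + 28L)
  expect_equal(r$n_loci, 12L)
  expect_true(r$accepted)
})

test_that("distant clusters are reported separately and sorted", {
  g <- bare_genome(c(chr1 = 100000L, chr2 = 100000L))
  seqs <- sig_seq(12)
  loci <- rbind(
    data.frame(tag = 1:6, chrom = "chr2", start = 50000L + (0:5) * 40L,
               end = 50000L + (0:5) * 40L + 28L, strand = "+",
               identity = 1, coverage = 1, mismatches = 0L),
    data.frame(tag = 7:12, chrom = "chr1", start = 20000L + (0:5) * 40L,
               end = 20000L + (0:5) * 40L + 28L, strand = "-",
               identity = 1, coverage = 1, mismatches = 0L))
  r <- scan_clusters(manual_mapping(loci, seqs), g)
  expect_equal(nrow(r), 2)
  expect_equal(r$chrom, c("chr1", "chr2"))
  expect_equal(r$main_strand, c("-", "+"))
  expect_true(all(r$accepted))
})

test_that("the scan is invariant to locus input order", {
  g <- bg100k()
  seqs <- sig_seq(6)
  loci <- tight_mapping(6)$loci
  perm <- loci[c(4, 1, 6, 3, 2, 5), ]
  m1 <- structure(list(loci = loci, n_loci = rep(1L, 6),
                       overflow = rep(FALSE, 6), sequences = seqs),
                  class = "tag_mapping")
  m2 <- structure(list(loci = perm, n_loci = rep(1L, 6),
                       overflow = rep(FALSE, 6), sequences = seqs),
                  class = "tag_mapping")
  expect_equal(scan_clusters(m1, g), scan_clusters(m2, g))
})

test_that("empty mappings and all-rejected scans yield zero piRNAs", {
  g <- bg100k()
  m0 <- structure(list(loci = tight_mapping(0)$loci[0, ],
                       n_loci = integer(), overflow = logical(),
                       sequences = character()), class = "tag_mapping")
  expect_equal(nrow(scan_clusters(m0, g)), 0)
  plain <- tight_mapping(6, seqs = nosig_seq(6))
  rej <- scan_clusters(plain, g)
  ann <- data.frame(tag = 1:6, category = "repeat", n_loci = 1L,
                    repeat_subtype = "LINE/CR1", stringsAsFactors = FALSE)
  p <- call_pirnas(rej, plain, ann)
  expect_equal(nrow(p$calls), 0)
  expect_equal(sum(p$origin$n), 0)
})

test_that("piRNA calls need a locus fully inside an accepted cluster", {
  g <- bg100k()
  seqs <- sig_seq(7)
  inside <- tight_mapping(6)$loci
  straddle <- data.frame(tag = 7L, chrom = "chr1", start = 7400L,
                         end = 7428L, strand = "+", identity = 1,
                         coverage = 1, mismatches = 0L)
  m <- manual_mapping(rbind(inside, straddle), seqs)
  cl <- scan_clusters(m, g)
  acc <- cl[cl$accepted, ]
  expect_equal(nrow(acc), 1)
  ann <- data.frame(tag = 1:7,
                    category = c(rep("repeat", 6), "miRNA"),
                    n_loci = 1L, repeat_subtype = NA_character_,
                    stringsAsFactors = FALSE)
  p <- call_pirnas(cl, m, ann)
  expect_equal(p$calls$tag, 1:6)
  expect_equal(unique(p$calls$origin_category), "repeat")
  expect_equal(p$origin$n[p$origin$category == "repeat"], 6L)
  expect_equal(sum(p$origin$n), 6L)
})

test_that("cluster BED output has one row per candidate", {
  g <- bg100k()
  r <- scan_clusters(tight_mapping(6), g)
  f <- tempfile(fileext = ".bed")
  write_clusters_bed(r, f)
  lines <- read.delim(f, header = FALSE)
  expect_equal(nrow(lines), nrow(r))
  expect_equal(lines$V2, r$start)
  expect_equal(lines$V3, r$end)
})
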