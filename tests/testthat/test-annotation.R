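feat_row <- function(category, subtype = NULL) {
  df <- as.data.frame(small_genome()$features)
  df <- df[df$category == category, , drop = FALSE]
  if (!is.null(subtype)) df <- df[!is.na(df$subtype) &
                                    df$subtype == subtype, , drop = FALSE]
  df[1, ]
}

# a 20-nt locus (0-based half-open) fully inside a feature row
locus_in <- function(fr, tag, strand = NULL) {
  data.frame(tag = tag, chrom = as.character(fr$seqnames),
             start = fr$start - 1L, end = fr$start + 19L,
             strand = if (is.null(strand)) as.character(fr$strand) else
               strand,
             identity = 1, coverage = 1, mismatches = 0L,
             stringsAsFactors = FALSE)
}

test_that("a locus inside a tRNA feature is annotated tRNA", {
  g <- small_genome()
  loci <- locus_in(feat_row("tRNA"), 1L)
  ann <- annotate_tags(manual_mapping(loci, "x"), g)
  expect_equal(ann$category, "tRNA")
  expect_equal(ann$n_loci, 1L)
  expect_true(is.na(ann$repeat_subtype))
})

test_that("the priority hierarchy picks the highest category over loci", {
  g <- small_genome()
  # one tag with an rRNA locus and a miRNA locus: rRNA outranks miRNA
  loci <- rbind(locus_in(feat_row("rRNA"), 1L),
                locus_in(feat_row("miRNA"), 1L))
  loci$end[2] <- loci$start[2] + 20L # miRNA features are 22 nt
  ann <- annotate_tags(manual_mapping(loci, "x", n_loci = 2L), g)
  expect_equal(ann$category, "rRNA")
  # tRNA outranks rRNA
  loci2 <- rbind(locus_in(feat_row("tRNA"), 1L),
                 locus_in(feat_row("rRNA"), 1L))
  ann2 <- annotate_tags(manual_mapping(loci2, "x", n_loci = 2L), g)
  expect_equal(ann2$category, "tRNA")
  # repeat outranks exon and intron
  loci3 <- rbind(locus_in(feat_row("repeat"), 1L),
                 locus_in(feat_row("exon"), 1L),
                 locus_in(feat_row("intron"), 1L))
  ann3 <- annotate_tags(manual_mapping(loci3, "x", n_loci = 3L), g)
  expect_equal(ann3$category, "repeat")
})

test_that("exon and intron hits split by strand, sense winning ties", {
  g <- small_genome()
  fr <- feat_row("exon")
  same <- as.character(fr$strand)
  opp <- if (same == "+") "-" else "+"
  a_s <- annotate_tags(manual_mapping(locus_in(fr, 1L, same), "x"), g)
  expect_equal(a_s$category, "exon_sense")
  a_a <- annotate_tags(manual_mapping(locus_in(fr, 1L, opp), "x"), g)
  expect_equal(a_a$category, "exon_antisense")
  both <- rbind(locus_in(fr, 1L, same), locus_in(fr, 1L, opp))
  a_b <- annotate_tags(manual_mapping(both, "x", n_loci = 2L), g)
  expect_equal(a_b$category, "exon_sense")
  fi <- feat_row("intron")
  a_i <- annotate_tags(manual_mapping(
    locus_in(fi, 1L, if (as.character(fi$strand) == "+") "-" else "+"),
    "x"), g)
  expect_equal(a_i$category, "intron_antisense")
})

test_that("the 50% locus-overlap rule is a sharp threshold", {
  g <- small_genome()
  fr <- feat_row("rRNA")
  base <- locus_in(fr, 1L)
  # 10 of 20 bases inside the feature: annotated
  half <- base; half$start <- fr$start - 11L; half$end <- fr$start + 9L
  a1 <- annotate_tags(manual_mapping(half, "x"), g)
  expect_equal(a1$category, "rRNA")
  # 9 of 20 bases inside: below the threshold
  nine <- base; nine$start <- fr$start - 12L; nine$end <- fr$start + 8L
  a2 <- annotate_tags(manual_mapping(nine, "x"), g)
  expect_equal(a2$category, "unannotated")
})

test_that("repeat subtypes are recorded, with Ambi for mixed families", {
  g <- small_genome()
  r1 <- feat_row("repeat", "LINE/CR1")
  r2 <- feat_row("repeat", "LTR/ERVL")
  a1 <- annotate_tags(manual_mapping(locus_in(r1, 1L), "x"), g)
  expect_equal(a1$repeat_subtype, "LINE/CR1")
  mixed <- rbind(locus_in(r1, 1L), locus_in(r2, 1L))
  a2 <- annotate_tags(manual_mapping(mixed, "x", n_loci = 2L), g)
  expect_equal(a2$category, "repeat")
  expect_equal(a2$repeat_subtype, "Ambi")
})

test_that("annotation agrees with a brute-force oracle on real mappings", {
  g <- small_genome()
  cl <- small_pgc_clean()
  tags <- collapse_tags(list(pgc = cl))
  idx <- seq(1, nrow(tags), length.out = 200)
  sub <- tags[unique(round(idx)), , drop = FALSE]
  m <- map_tags(sub$sequence, g)
  ann <- annotate_tags(m, g)
  want <- oracle_annotate(m$loci, g)
  expect_equal(nrow(ann), nrow(want))
  expect_equal(ann$category, want$category[match(ann$tag, want$tag)])
})

test_that("empty mappings annotate to an empty table without error", {
  g <- small_genome()
  m <- map_tags(character(0), g)
  ann <- annotate_tags(m, g)
  expect_equal(nrow(ann), 0)
  tags <- collapse_tags(list(
    a = list(seq = "ACGTACGTACGTACGTACGTAC")))
  s <- summarize_distributions(ann, tags, sample = "a")
  expect_equal(sum(s$category$total), 0)
  expect_equal(sum(s$length$unique), 0)
})

test_that("distribution summaries conserve counts and split by length", {
  g <- small_genome()
  cl <- small_pgc_clean()
  tags <- collapse_tags(list(pgc = cl))
  m <- map_tags(tags, g)
  ann <- annotate_tags(m, g)
  s <- summarize_distributions(ann, tags, sample = "pgc")
  mapped_counts <- sum(tags$count_pgc[ann$tag])
  expect_equal(sum(s$category$total), mapped_counts)
  expect_equal(sum(s$length$total), mapped_counts)
  expect_equal(sum(s$category$unique), sum(tags$count_pgc[ann$tag] > 0))
  expect_equal(sum(s$length$unique), sum(s$category$unique))
  expect_error(summarize_distributions(ann, tags, sample = "nope"),
               "unknown sample")
})
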