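# Shared fixtures (memoised so expensive objects build once per run) and
# independent brute-force oracles.

.fixture_cache <- new.env()

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache, inherits = FALSE)
}

# 200 kb two-chromosome genome with all feature types
small_genome <- function() {
  fixture("small_genome", build_genome(genome_spec(
    n_chromosomes = 2, chrom_length = 1e5, repeat_copies = 10,
    gene_models = 4, pirna_clusters = 2, seed = 7)))
}

# PGC-like library on the small genome, with truth
small_pgc_library <- function() {
  fixture("small_pgc_library",
          simulate_library(small_genome(), pgc_profile(depth = 20000),
                           seed = 11))
}

small_pgc_clean <- function() {
  fixture("small_pgc_clean", clean_reads(small_pgc_library()))
}

# Extract the genomic sequence of a region as a character tag
genome_substr <- function(genome, chrom, start1, len, strand = "+") {
  s <- substring(as.character(genome$seqs[[chrom]]), start1,
                 start1 + len - 1)
  if (strand == "-") s <- pirnapipe:::revcomp(s)
  s
}

mutate_tag <- function(tag, positions) {
  for (p in positions) {
    b <- substr(tag, p, p)
    substr(tag, p, p) <- sample(setdiff(c("A", "C", "G", "T"), b), 1)
  }
  tag
}

# ---------------------------------------------------------------------------
# Brute-force mapping oracle built on Biostrings::matchPattern: for every
# diagonal, enumerate all windows of >= ceil(min_coverage * L) tag bases,
# keep diagonals with a window at <= floor((1-identity)*m) mismatches, and
# report per diagonal the best window under the same preference order as
# the mapper (longest aligned, then fewest mismatches, then smallest tag
# offset).  Completely independent search path from the k-mer index.
# ---------------------------------------------------------------------------
oracle_map_tag <- function(tag, genome, min_identity = 0.90,
                           min_coverage = 0.95) {
  res <- list()
  for (cn in names(genome$seqs)) {
    chrom <- genome$seqs[[cn]]
    cstr <- as.character(chrom)
    for (strand in c("+", "-")) {
      q <- if (strand == "+") tag else pirnapipe:::revcomp(tag)
      L <- nchar(q)
      m_min <- ceiling(min_coverage * L - 1e-9)
      cand <- list() # per diagonal: list of c(m, mm, s, gstart)
      for (m in seq(L, m_min)) {
        allowed <- floor((1 - min_identity) * m + 1e-9)
        for (s in 0:(L - m)) {
          win <- substr(q, s + 1, s + m)
          hits <- Biostrings::matchPattern(win, chrom,
                                           max.mismatch = allowed)
          for (h in seq_along(hits)) {
            gstart <- BiocGenerics::start(hits)[h] # 1-based window start
            mm <- sum(strsplit(win, "")[[1]] !=
                        strsplit(substring(cstr, gstart,
                                           gstart + m - 1), "")[[1]])
            if (mm > allowed) next
            d <- gstart - s
            key <- as.character(d)
            cand[[key]] <- rbind(cand[[key]], c(m, mm, s, gstart))
          }
        }
      }
      for (key in names(cand)) {
        tab <- cand[[key]]
        o <- order(-tab[, 1], tab[, 2], tab[, 3])
        best <- tab[o[1], ]
        res[[length(res) + 1L]] <- data.frame(
          chrom = cn, start = best[4] - 1L, end = best[4] - 1L + best[1],
          strand = strand, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(res) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character()))
  }
  out <- unique(do.call(rbind, res))
  out <- out[order(out$chrom, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---------------------------------------------------------------------------
# Brute-force annotation oracle: enumerate every (locus, feature) overlap
# by linear scan and take the maximum-priority category.
# ---------------------------------------------------------------------------
oracle_annotate <- function(loci_df, genome, overlap_frac = 0.5) {
  feat <- as.data.frame(genome$features)
  pri <- category_priority()
  tags <- sort(unique(loci_df$tag))
  out <- character(length(tags))
  for (i in seq_along(tags)) {
    li <- loci_df[loci_df$tag == tags[i], , drop = FALSE]
    best_p <- Inf; sense_any <- FALSE
    for (r in seq_len(nrow(li))) {
      ls1 <- li$start[r] + 1L; le <- li$end[r]
      width <- le - ls1 + 1L
      for (f in seq_len(nrow(feat))) {
        if (feat$seqnames[f] != li$chrom[r]) next
        ov <- min(le, feat$end[f]) - max(ls1, feat$start[f]) + 1L
        if (ov < overlap_frac * width) next
        p <- match(feat$category[f], pri)
        if (p < best_p) {
          best_p <- p
          sense_any <- li$strand[r] == as.character(feat$strand[f])
        } else if (p == best_p) {
          sense_any <- sense_any ||
            li$strand[r] == as.character(feat$strand[f])
        }
      }
    }
    if (!is.finite(best_p)) out[i] <- "unannotated"
    else {
      cat0 <- pri[best_p]
      out[i] <- if (cat0 %in% c("exon", "intron"))
        paste0(cat0, if (sense_any) "_sense" else "_antisense") else cat0
    }
  }
  data.frame(tag = tags, category = out, stringsAsFactors = FALSE)
}

# Build a tag_mapping object by hand (for cluster-scan tests)
manual_mapping <- function(loci, sequences, n_loci = NULL) {
  idx <- sort(unique(loci$tag))
  if (is.null(n_loci))
    n_loci <- as.integer(table(factor(loci$tag,
                                      levels = seq_along(sequences))))
  structure(list(loci = loci[order(loci$tag, loci$chrom, loci$start), ,
                             drop = FALSE],
                 n_loci = n_loci,
                 overflow = rep(FALSE, length(sequences)),
                 sequences = sequences),
            class = "tag_mapping")
}

norm_loci <- function(df) {
  df <- df[, c("chrom", "start", "end", "strand")]
  df <- df[order(df$chrom, df$start, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  df
}

two_sample_config <- function(outdir = NULL, seed = 5L) {
  pipeline_config(
    samples = list(pgc = pgc_profile(depth = 4000),
                   cef = cef_profile(depth = 4000)),
    genome = genome_spec(n_chromosomes = 1, chrom_length = 2e5,
                         repeat_copies = 10, gene_models = 3,
                         pirna_clusters = 2, seed = 31),
    outdir = outdir, seed = seed)
}

small_run <- function() fixture("small_run", run_pipeline(two_sample_config()))

# A bare genome model with given chromosome lengths and no features
bare_genome <- function(lengths) {
  seqs <- Biostrings::DNAStringSet(vapply(lengths, function(L)
    paste(rep("A", L), collapse = ""), character(1)))
  names(seqs) <- names(lengths)
  structure(list(seqs = seqs,
                 features = GenomicRanges::GRanges(),
                 clusters = GenomicRanges::GRanges(), spec = NULL),
            class = "genome_model")
}
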