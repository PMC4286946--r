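# Simulation of small-RNA sequencing libraries from a genome_model.

read_classes <- function() {
  c("repeat_piRNA_cluster", "genic_piRNA", "miRNA_like", "rRNA_fragment",
    "tRNA_fragment", "intron_fragment", "exon_fragment",
    "random_background")
}

default_adapter <- function() {
  # 33-nt Illumina-style 3' small-RNA adapter (configurable everywhere)
  "TGGAATTCTCGGGTGCCAAGGAACTCCAGTCAC"
}

# Per-class read length distributions (named probability vectors over nt).
default_length_distributions <- function() {
  pirna <- c(`25` = 0.050, `26` = 0.150, `27` = 0.145, `28` = 0.135,
             `29` = 0.125, `30` = 0.110, `31` = 0.095, `32` = 0.080,
             `33` = 0.055, `34` = 0.025, `35` = 0.030)
  mirna <- c(`21` = 0.10, `22` = 0.80, `23` = 0.07, `24` = 0.03)
  # degradation fragments: peak near 22 with a long tail, as ribosomal/tRNA
  # breakdown products tend to show after size selection
  frag_len <- 18:40
  frag <- exp(-abs(frag_len - 22) / 2.5)
  frag <- setNames(frag / sum(frag), frag_len)
  flat <- setNames(rep(1 / 27, 27), 18:44)
  list(repeat_piRNA_cluster = pirna, genic_piRNA = pirna, miRNA_like = mirna,
       rRNA_fragment = frag, tRNA_fragment = frag, intron_fragment = flat,
       exon_fragment = flat, random_background = flat)
}

#' Library simulation profile
#'
#' Describes the statistical composition of one simulated small-RNA library:
#' the mixture over read classes, per-class length distributions, the 1U/10A
#' bias and strand bias of piRNA-class reads, and the adapter read-through
#' and low-quality rates that the cleaning stage is expected to remove.
#'
#' @param class_weights Named proportions over the classes in
#'   `repeat_piRNA_cluster, genic_piRNA, miRNA_like, rRNA_fragment,
#'   tRNA_fragment, intron_fragment, exon_fragment, random_background`;
#'   must sum to 1.
#' @param length_distributions Named list of per-class probability vectors
#'   (names = lengths in nt, 15-50); each must sum to 1.
#' @param one_u_fraction Probability that a piRNA-class read is forced to
#'   start with T (U on the RNA).
#' @param ten_a_fraction Probability that a piRNA-class read is forced to
#'   carry A at position 10.
#' @param strand_main_fraction Probability that a cluster read is drawn from
#'   the cluster's main strand.
#' @param adapter_rate Proportion of reads with 3' adapter read-through.
#' @param low_quality_rate Proportion of reads whose mean Phred is drawn
#'   from the low-quality component (mean Q8), which the Q<13 filter
#'   removes.
#' @param depth Total number of reads.
#' @param adapter Adapter sequence appended on read-through.
#' @param max_read_length Sequencer read length cap after adapter append.
#' @return An object of class `library_profile`.
#' @export
library_profile <- function(class_weights,
                            length_distributions = default_length_distributions(),
                            one_u_fraction = 0.9,
                            ten_a_fraction = 0.45,
                            strand_main_fraction = 0.9,
                            adapter_rate = 0.15,
                            low_quality_rate = 0.10,
                            depth = 1e5,
                            adapter = default_adapter(),
                            max_read_length = 50L) {
  cls <- read_classes()
  w <- setNames(numeric(length(cls)), cls)
  w[names(class_weights)] <- class_weights
  if (abs(sum(w) - 1) > 1e-8) stop2("class_weights must sum to 1")
  if (any(w < 0)) stop2("class_weights must be non-negative")
  props <- c(one_u_fraction, ten_a_fraction, strand_main_fraction,
             adapter_rate, low_quality_rate)
  if (any(props < 0 | props > 1)) stop2("all proportions must lie in [0,1]")
  for (cl in cls) {
    d <- length_distributions[[cl]]
    if (w[[cl]] > 0) {
      if (is.null(d) || abs(sum(d) - 1) > 1e-8)
        stop2("length distribution for class '", cl, "' must sum to 1")
      lens <- as.integer(names(d))
      if (any(is.na(lens)) || any(lens < 15) || any(lens > 50))
        stop2("length distribution for '", cl, "' must cover 15-50 nt")
    }
  }
  structure(list(class_weights = w,
                 length_distributions = length_distributions,
                 one_u_fraction = one_u_fraction,
                 ten_a_fraction = ten_a_fraction,
                 strand_main_fraction = strand_main_fraction,
                 adapter_rate = adapter_rate,
                 low_quality_rate = low_quality_rate,
                 depth = as.integer(depth),
                 adapter = adapter,
                 max_read_length = as.integer(max_read_length)),
            class = "library_profile")
}

#' Preset library profiles for the four cell types
#'
#' Class mixtures chosen to emulate the published composition of each
#' library: primordial germ cells (PGCs) are dominated by repeat-derived
#' piRNA-cluster reads (unique-tag length mode ~26 nt), stage X blastoderms
#' are intermediate, gonadal stromal cells (GSCs) are rRNA-fragment-rich and
#' chicken embryonic fibroblasts (CEFs) are miRNA-dominated (total-read
#' length mode ~22 nt).
#'
#' @param depth Total reads per library.
#' @param ... Further arguments passed to [library_profile()].
#' @return A `library_profile`.
#' @name preset_profiles
NULL

#' @rdname preset_profiles
#' @export
pgc_profile <- function(depth = 1e5, ...) {
  library_profile(c(repeat_piRNA_cluster = 0.60, genic_piRNA = 0.05,
                    miRNA_like = 0.10, rRNA_fragment = 0.12,
                    tRNA_fragment = 0.03, intron_fragment = 0.01,
                    exon_fragment = 0.01, random_background = 0.08),
                  depth = depth, ...)
}

#' @rdname preset_profiles
#' @export
stagex_profile <- function(depth = 1e5, ...) {
  library_profile(c(repeat_piRNA_cluster = 0.18, genic_piRNA = 0.03,
                    miRNA_like = 0.17, rRNA_fragment = 0.30,
                    tRNA_fragment = 0.07, intron_fragment = 0.02,
                    exon_fragment = 0.03, random_background = 0.20),
                  depth = depth, ...)
}

#' @rdname preset_profiles
#' @export
gsc_profile <- function(depth = 1e5, ...) {
  library_profile(c(repeat_piRNA_cluster = 0.05, genic_piRNA = 0.02,
                    miRNA_like = 0.20, rRNA_fragment = 0.45,
                    tRNA_fragment = 0.05, intron_fragment = 0.03,
                    exon_fragment = 0.05, random_background = 0.15),
                  depth = depth, ...)
}

#' @rdname preset_profiles
#' @export
cef_profile <- function(depth = 1e5, ...) {
  library_profile(c(repeat_piRNA_cluster = 0.02, genic_piRNA = 0.01,
                    miRNA_like = 0.45, rRNA_fragment = 0.20,
                    tRNA_fragment = 0.10, intron_fragment = 0.03,
                    exon_fragment = 0.04, random_background = 0.15),
                  depth = depth, ...)
}

# map read classes to feature categories
.class_category <- c(repeat_piRNA_cluster = "cluster", genic_piRNA = "genic",
                     miRNA_like = "miRNA", rRNA_fragment = "rRNA",
                     tRNA_fragment = "tRNA", intron_fragment = "intron",
                     exon_fragment = "exon", random_background = "background")

#' Simulate a small-RNA FASTQ library with truth labels
#'
#' Draws `profile$depth` reads from the planted features of `genome`
#' according to the class mixture, applies the 1U/10A edits and strand bias
#' to piRNA-class reads, appends adapter read-through, and assigns per-base
#' Phred qualities from a two-component model (high ~Q35, low ~Q8).  Every
#' read gets exactly one truth row.  Deterministic for a fixed
#' (genome, profile, seed).
#'
#' @param genome A `genome_model` from [build_genome()].
#' @param profile A [library_profile()].
#' @param seed Integer seed.
#' @param fastq Optional path; when given the library is written as
#'   Phred+33 FASTQ.
#' @param truth_tsv Optional path; when given the truth table is written as
#'   TSV with header.
#' @return An object of class `small_rna_library`: list with character
#'   vectors `id`, `seq`, `qual` and a data frame `truth` (columns read id,
#'   class, source feature id, chrom, insert start/end (1-based), strand,
#'   insert length, low_quality, adapter flags).
#' @export
simulate_library <- function(genome, profile, seed, fastq = NULL,
                             truth_tsv = NULL) {
  stopifnot(inherits(genome, "genome_model"),
            inherits(profile, "library_profile"))
  n <- profile$depth
  w <- profile$class_weights

  feat <- genome$features
  fcat <- if (length(feat)) feat$category else character()
  pools <- list(
    cluster = genome$clusters,
    genic = feat[fcat %in% c("exon", "intron")],
    miRNA = feat[fcat == "miRNA"],
    rRNA = feat[fcat == "rRNA"],
    tRNA = feat[fcat == "tRNA"],
    intron = feat[fcat == "intron"],
    exon = feat[fcat == "exon"])
  for (cl in read_classes()) {
    pool_name <- .class_category[[cl]]
    if (w[[cl]] > 0 && pool_name != "background" &&
        length(pools[[pool_name]]) == 0) {
      stop2("class '", cl, "' has weight ", w[[cl]],
            " but the genome contains no matching feature")
    }
  }

  empty <- function() {
    lib <- structure(list(id = character(), seq = character(),
                          qual = character(),
                          truth = data.frame(
                            read_id = character(), class = character(),
                            feature_id = character(), chrom = character(),
                            start = integer(), end = integer(),
                            strand = character(), length = integer(),
                            low_quality = logical(), adapter = logical(),
                            stringsAsFactors = FALSE)),
                     class = "small_rna_library")
    lib
  }
  if (n == 0) {
    lib <- empty()
    if (!is.null(fastq)) write_fastq(lib, fastq)
    if (!is.null(truth_tsv)) .write_tsv(lib$truth, truth_tsv)
    return(lib)
  }

  chrom_str <- as.character(genome$seqs)
  chrom_len <- setNames(Biostrings::width(genome$seqs), names(genome$seqs))

  with_seed(seed, {
    cls <- sample(read_classes(), n, replace = TRUE, prob = w)
    lens <- integer(n)
    for (cl in unique(cls)) {
      idx <- which(cls == cl)
      d <- profile$length_distributions[[cl]]
      lens[idx] <- sample(as.integer(names(d)), length(idx), replace = TRUE,
                          prob = d)
    }

    chrom <- character(n); start <- integer(n); strand <- character(n)
    feature_id <- rep(NA_character_, n)

    for (cl in unique(cls)) {
      idx <- which(cls == cl)
      pool_name <- .class_category[[cl]]
      if (pool_name == "background") {
        ci <- sample(seq_along(chrom_len), length(idx), replace = TRUE,
                     prob = chrom_len)
        chrom[idx] <- names(chrom_len)[ci]
        maxs <- pmax(1L, chrom_len[ci] - lens[idx] + 1L)
        start[idx] <- 1L + floor(runif(length(idx)) * maxs)
        strand[idx] <- sample(c("+", "-"), length(idx), replace = TRUE)
        next
      }
      pool <- pools[[pool_name]]
      fi <- sample(seq_along(pool), length(idx), replace = TRUE)
      g <- pool[fi]
      chrom[idx] <- as.character(GenomeInfoDb::seqnames(g))
      fs <- BiocGenerics::start(g); fe <- BiocGenerics::end(g)
      room <- pmax(0L, fe - fs + 1L - lens[idx])
      start[idx] <- fs + floor(runif(length(idx)) * (room + 1L))
      # keep reads on the chromosome when the feature is shorter than the read
      start[idx] <- pmin(start[idx],
                         chrom_len[chrom[idx]] - lens[idx] + 1L)
      feature_id[idx] <- g$id
      fstrand <- as.character(BiocGenerics::strand(g))
      if (pool_name == "cluster") {
        main <- runif(length(idx)) < profile$strand_main_fraction
        strand[idx] <- ifelse(main, fstrand,
                              ifelse(fstrand == "+", "-", "+"))
      } else if (pool_name == "genic") {
        strand[idx] <- sample(c("+", "-"), length(idx), replace = TRUE)
      } else {
        strand[idx] <- fstrand
      }
    }
    end <- start + lens - 1L

    # extract insert sequences
    seqs <- character(n)
    for (cn in unique(chrom)) {
      idx <- which(chrom == cn)
      seqs[idx] <- substring(chrom_str[[cn]], start[idx], end[idx])
    }
    neg <- strand == "-"
    if (any(neg)) seqs[neg] <- revcomp(seqs[neg])

    # ping-pong 1U/10A edits on piRNA-class reads
    pir <- cls %in% c("repeat_piRNA_cluster", "genic_piRNA")
    u1 <- pir & runif(n) < profile$one_u_fraction
    substr(seqs[u1], 1L, 1L) <- "T"
    a10 <- pir & runif(n) < profile$ten_a_fraction & lens >= 10L
    substr(seqs[a10], 10L, 10L) <- "A"

    # adapter read-through
    adp <- runif(n) < profile$adapter_rate
    out_seq <- seqs
    if (any(adp)) {
      full <- paste0(seqs[adp], profile$adapter)
      out_seq[adp] <- substr(full, 1L, profile$max_read_length)
    }
    out_len <- nchar(out_seq)

    # qualities: two-component per-read model
    lowq <- runif(n) < profile$low_quality_rate
    mu <- ifelse(lowq, 8, 35)
    total <- sum(out_len)
    q <- round(rnorm(total, rep(mu, out_len), 3))
    q <- pmin(pmax(q, 2L), 40L)
    qual_all <- intToUtf8(q + 33L)
    ends <- cumsum(out_len)
    qual <- substring(qual_all, ends - out_len + 1L, ends)

    ids <- sprintf("read_%07d", seq_len(n))
    truth <- data.frame(read_id = ids, class = cls, feature_id = feature_id,
                        chrom = chrom, start = start, end = end,
                        strand = strand, length = lens,
                        low_quality = lowq, adapter = adp,
                        stringsAsFactors = FALSE)
    lib <- structure(list(id = ids, seq = out_seq, qual = qual,
                          truth = truth),
                     class = "small_rna_library")
    if (!is.null(fastq)) write_fastq(lib, fastq)
    if (!is.null(truth_tsv)) .write_tsv(truth, truth_tsv)
    lib
  })
}

#' @export
print.small_rna_library <- function(x, ...) {
  cat("small_rna_library:", length(x$seq), "reads\n")
  if (length(x$seq)) {
    tab <- sort(table(x$truth$class), decreasing = TRUE)
    cat(paste(sprintf("  %s: %d", names(tab), tab), collapse = "\n"), "\n")
  }
  invisible(x)
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a simulated library as Phred+33 FASTQ
#'
#' @param lib A `small_rna_library` (or any list with `id`, `seq`, `qual`).
#' @param path Output FASTQ path.
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(lib, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(lib$seq)) {
    writeLines(paste0("@", lib$id, "\n", lib$seq, "\n+\n", lib$qual), con)
  }
  invisible(path)
}

#' Read a Phred+33 FASTQ file
#'
#' @param path FASTQ path (plain or gzip).
#' @return A list with character vectors `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L)
    stop2("malformed FASTQ: ", path, " has ", length(lines),
          " lines (not a multiple of 4)")
  n <- length(lines) / 4L
  if (n == 0) return(list(id = character(), seq = character(),
                          qual = character()))
  at <- lines[seq(1L, by = 4L, length.out = n)]
  bad <- which(!startsWith(at, "@"))
  if (length(bad))
    stop2("malformed FASTQ record ", bad[1], ": header does not start with @")
  list(id = sub("\\s.*$", "", sub("^@", "", at)),
       seq = toupper(lines[seq(2L, by = 4L, length.out = n)]),
       qual = lines[seq(4L, by = 4L, length.out = n)])
}
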