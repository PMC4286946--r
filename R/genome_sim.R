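#' Specification for a synthetic genome
#'
#' Describes a toy genome with planted, strand-aware features: diverged
#' LINE/CR1- and LTR/ERVL-like repeat copies, multi-exon gene models,
#' structural RNA loci (tRNA, rRNA, snRNA, snoRNA, scRNA, miRNA), and
#' repeat-annotated piRNA cluster intervals.  Clusters are modelled as old,
#' diverged repeat remnants whose sequence is unique in the genome, which is
#' what makes cluster-derived tags map uniquely, as piRNA cluster tags
#' typically do.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length Length of each chromosome in nt.
#' @param repeat_copies Number of dispersed repeat copies (outside clusters).
#' @param repeat_length Length of each repeat copy in nt.
#' @param gene_models Number of genes; each gene is exon(300)-intron(500)-
#'   exon(300)-intron(500)-exon(300).
#' @param structural_rna_loci Named counts for categories tRNA, rRNA, snRNA,
#'   snoRNA, scRNA, miRNA.
#' @param pirna_clusters Number of planted piRNA cluster intervals.
#' @param cluster_length Length of each planted cluster in nt.
#' @param gc GC content of the random background (0.5 = uniform).
#' @param seed Integer seed; the whole genome is a deterministic function of
#'   the spec including this seed.
#' @return An object of class `genome_spec`.
#' @export
genome_spec <- function(n_chromosomes = 1L,
                        chrom_length = 1e6,
                        repeat_copies = 30L,
                        repeat_length = 300L,
                        gene_models = 10L,
                        structural_rna_loci = c(tRNA = 8L, rRNA = 4L,
                                                snRNA = 4L, snoRNA = 4L,
                                                scRNA = 2L, miRNA = 20L),
                        pirna_clusters = 3L,
                        cluster_length = 2000L,
                        gc = 0.5,
                        seed = 1L) {
  cats <- c("tRNA", "rRNA", "snRNA", "snoRNA", "scRNA", "miRNA")
  full <- setNames(integer(6), cats)
  full[names(structural_rna_loci)] <- as.integer(structural_rna_loci)
  if (any(full < 0)) stop2("structural_rna_loci counts must be >= 0")
  stopifnot(n_chromosomes >= 1, chrom_length >= 1000, gc > 0, gc < 1)
  structure(list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length = as.integer(chrom_length),
    repeat_copies = as.integer(repeat_copies),
    repeat_length = as.integer(repeat_length),
    gene_models = as.integer(gene_models),
    structural_rna_loci = full,
    pirna_clusters = as.integer(pirna_clusters),
    cluster_length = as.integer(cluster_length),
    gc = gc,
    seed = as.integer(seed)
  ), class = "genome_spec")
}

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Lengths of the units a genome_spec plants, one row per unit.
.unit_table <- function(spec) {
  sl <- c(tRNA = 75L, rRNA = 800L, snRNA = 150L, snoRNA = 100L,
          scRNA = 300L, miRNA = 22L)
  units <- list()
  n <- spec$pirna_clusters
  if (n > 0) units$cluster <- data.frame(
    kind = "cluster", len = rep(spec$cluster_length, n))
  n <- spec$repeat_copies
  if (n > 0) units$rep <- data.frame(
    kind = "repeat", len = rep(spec$repeat_length, n))
  n <- spec$gene_models
  if (n > 0) units$gene <- data.frame(
    kind = "gene", len = rep(3L * 300L + 2L * 500L, n))
  for (cat in names(spec$structural_rna_loci)) {
    n <- spec$structural_rna_loci[[cat]]
    if (n > 0) units[[cat]] <- data.frame(kind = cat, len = rep(sl[[cat]], n))
  }
  if (length(units) == 0) {
    return(data.frame(kind = character(), len = integer()))
  }
  do.call(rbind, unname(units))
}

#' Build a synthetic genome with planted features
#'
#' Generates random chromosome sequences and places all planted units
#' (clusters, repeat copies, genes, structural RNA loci) at uniformly random
#' non-overlapping positions.  Dispersed repeat copies are drawn from one of
#' two family consensus sequences (LINE/CR1-like, LTR/ERVL-like) with 8%
#' per-base divergence, so that occasional multi-mapping and ambiguous
#' repeat subtypes arise naturally.  Deterministic for a fixed spec.
#'
#' @param spec A [genome_spec()].
#' @return An object of class `genome_model` with elements
#'   `seqs` (a [Biostrings::DNAStringSet-class]),
#'   `features` (a [GenomicRanges::GRanges-class] with metadata columns
#'   `id`, `category`, `subtype`, `gene_id`) and
#'   `clusters` (a `GRanges` of planted cluster truth intervals with a
#'   `main_strand` column).
#' @export
build_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  with_seed(spec$seed, {
    units <- .unit_table(spec)
    n_units <- nrow(units)
    chrom_names <- sprintf("chr%d", seq_len(spec$n_chromosomes))

    # feasibility: features may occupy at most 80% of the genome
    total_len <- sum(units$len)
    budget <- 0.8 * spec$n_chromosomes * spec$chrom_length
    if (total_len > budget) {
      by_kind <- tapply(units$len, units$kind, sum)
      worst <- names(by_kind)[which.max(by_kind)]
      stop2("infeasible packing: planted features exceed 80% of genome ",
            "length; largest contribution from category '", worst, "'")
    }

    # assign units to chromosomes, then place with uniform gap sampling
    if (n_units > 0) {
      units <- units[sample.int(n_units), , drop = FALSE]
      units$chrom <- sample(chrom_names, n_units, replace = TRUE)
    } else {
      units$chrom <- character()
    }
    units$start <- rep(NA_integer_, n_units)
    for (cn in chrom_names) {
      idx <- which(units$chrom == cn)
      if (length(idx) == 0) next
      lens <- units$len[idx]
      free <- spec$chrom_length - sum(lens)
      if (free < length(idx)) {
        by_kind <- tapply(lens, units$kind[idx], sum)
        stop2("infeasible packing on ", cn, ": category '",
              names(by_kind)[which.max(by_kind)], "' does not fit")
      }
      gaps <- sort(runif(length(idx), 0, free))
      starts <- floor(gaps) + cumsum(c(0, lens[-length(lens)])) + 1L
      units$start[idx] <- as.integer(starts)
    }
    units$end <- units$start + units$len - 1L
    units$strand <- sample(c("+", "-"), max(n_units, 1), replace = TRUE)[
      seq_len(n_units)]

    # chromosome sequences
    seqs <- Biostrings::DNAStringSet(
      vapply(chrom_names, function(x) random_dna(spec$chrom_length, spec$gc),
             character(1)))
    names(seqs) <- chrom_names

    # overwrite dispersed repeat copies with diverged family consensus
    rep_idx <- which(units$kind == "repeat")
    subtype <- rep(NA_character_, n_units)
    if (length(rep_idx) > 0) {
      fams <- c("LINE/CR1", "LTR/ERVL")
      consensus <- lapply(fams, function(f)
        strsplit(random_dna(spec$repeat_length, spec$gc), "")[[1]])
      names(consensus) <- fams
      fam_of <- sample(fams, length(rep_idx), replace = TRUE,
                       prob = c(0.7, 0.3))
      subtype[rep_idx] <- fam_of
      for (j in seq_along(rep_idx)) {
        i <- rep_idx[j]
        base <- consensus[[fam_of[j]]]
        mut <- runif(length(base)) < 0.08
        if (any(mut)) {
          base[mut] <- vapply(base[mut], function(b)
            sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
        }
        copy <- Biostrings::DNAString(paste(base, collapse = ""))
        Biostrings::subseq(seqs[[units$chrom[i]]],
                           units$start[i], units$end[i]) <- copy
      }
    }
    subtype[units$kind == "cluster"] <- "LINE/CR1"

    # expand units into feature records
    feats <- list()
    add <- function(chrom, start, end, strand, id, category, sub = NA,
                    gene = NA) {
      feats[[length(feats) + 1L]] <<- data.frame(
        chrom = chrom, start = start, end = end, strand = strand, id = id,
        category = category, subtype = sub, gene_id = gene,
        stringsAsFactors = FALSE)
    }
    cl_rows <- NULL
    counters <- new.env()
    nid <- function(prefix) {
      k <- get0(prefix, envir = counters, inherits = FALSE,
                ifnotfound = 0L) + 1L
      assign(prefix, k, envir = counters)
      sprintf("%s_%03d", prefix, k)
    }
    for (i in seq_len(n_units)) {
      kind <- units$kind[i]
      if (kind == "cluster") {
        id <- nid("cluster")
        add(units$chrom[i], units$start[i], units$end[i], units$strand[i],
            id, "repeat", sub = subtype[i])
        cl_rows <- rbind(cl_rows, data.frame(
          chrom = units$chrom[i], start = units$start[i], end = units$end[i],
          main_strand = units$strand[i], id = id, stringsAsFactors = FALSE))
      } else if (kind == "repeat") {
        add(units$chrom[i], units$start[i], units$end[i], units$strand[i],
            nid("repeat"), "repeat", sub = subtype[i])
      } else if (kind == "gene") {
        gid <- nid("gene")
        segs <- c(exon = 300L, intron = 500L, exon = 300L, intron = 500L,
                  exon = 300L)
        pos <- units$start[i]
        for (s in seq_along(segs)) {
          seg_cat <- names(segs)[s]
          add(units$chrom[i], pos, pos + segs[s] - 1L, units$strand[i],
              sprintf("%s_%s%d", gid, seg_cat, s), seg_cat, gene = gid)
          pos <- pos + segs[s]
        }
      } else {
        add(units$chrom[i], units$start[i], units$end[i], units$strand[i],
            nid(kind), kind)
      }
    }
    fdf <- if (length(feats)) do.call(rbind, feats) else
      data.frame(chrom = character(), start = integer(), end = integer(),
                 strand = character(), id = character(),
                 category = character(), subtype = character(),
                 gene_id = character())

    sl <- setNames(rep(spec$chrom_length, spec$n_chromosomes), chrom_names)
    features <- GenomicRanges::GRanges(
      seqnames = factor(fdf$chrom, levels = chrom_names),
      ranges = IRanges::IRanges(fdf$start, fdf$end),
      strand = if (nrow(fdf)) fdf$strand else character(),
      id = fdf$id, category = fdf$category, subtype = fdf$subtype,
      gene_id = fdf$gene_id, seqlengths = sl)
    clusters <- if (is.null(cl_rows)) {
      GenomicRanges::GRanges(seqlengths = sl)
    } else {
      GenomicRanges::GRanges(
        seqnames = factor(cl_rows$chrom, levels = chrom_names),
        ranges = IRanges::IRanges(cl_rows$start, cl_rows$end),
        strand = cl_rows$main_strand, id = cl_rows$id,
        main_strand = cl_rows$main_strand, seqlengths = sl)
    }
    features <- GenomicRanges::sort(features, ignore.strand = TRUE)

    structure(list(seqs = seqs, features = features, clusters = clusters,
                   spec = spec),
              class = "genome_model")
  })
}

#' @export
print.genome_model <- function(x, ...) {
  cat("genome_model:", length(x$seqs), "chromosome(s),",
      sum(Biostrings::width(x$seqs)), "nt;",
      length(x$features), "feature(s);",
      length(x$clusters), "planted cluster(s)\n")
  invisible(x)
}

#' Write a genome model to standard files
#'
#' Writes the chromosome sequences as FASTA, the features as GFF3 (1-based,
#' closed; `ID` and `category` attributes) and BED6 (0-based, half-open),
#' and the planted cluster truth intervals as a separate BED6 file.
#'
#' @param genome A `genome_model`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the file paths written.
#' @export
write_genome <- function(genome, dir) {
  stopifnot(inherits(genome, "genome_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(fasta = file.path(dir, "genome.fa"),
                gff3 = file.path(dir, "features.gff3"),
                bed = file.path(dir, "features.bed"),
                clusters = file.path(dir, "clusters_truth.bed"))
  Biostrings::writeXStringSet(genome$seqs, paths$fasta)
  gr <- genome$features
  if (length(gr)) {
    S4Vectors::mcols(gr)$ID <- S4Vectors::mcols(gr)$id
    S4Vectors::mcols(gr)$type <- S4Vectors::mcols(gr)$category
    rtracklayer::export(gr, paths$gff3, format = "gff3")
  } else {
    writeLines(c("##gff-version 3",
                 sprintf("##sequence-region %s 1 %d", names(genome$seqs),
                         Biostrings::width(genome$seqs))),
               paths$gff3)
  }
  bed <- genome$features
  if (length(bed)) {
    S4Vectors::mcols(bed) <- S4Vectors::DataFrame(
      name = genome$features$id, score = 0L)
    rtracklayer::export(bed, paths$bed, format = "bed")
  } else {
    writeLines(character(0), paths$bed)
  }
  cl <- genome$clusters
  if (length(cl)) {
    S4Vectors::mcols(cl) <- S4Vectors::DataFrame(
      name = genome$clusters$id, score = 0L)
    rtracklayer::export(cl, paths$clusters, format = "bed")
  } else {
    writeLines(character(0), paths$clusters)
  }
  invisible(paths)
}

#' Read a genome model from FASTA + GFF3
#'
#' Counterpart of [write_genome()].  The cluster truth BED is optional; when
#' absent the returned model has an empty cluster set.
#'
#' @param fasta Path to the genome FASTA.
#' @param gff3 Path to the features GFF3.
#' @param clusters_bed Optional path to the planted-cluster truth BED.
#' @return A `genome_model`.
#' @export
read_genome <- function(fasta, gff3, clusters_bed = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  sl <- setNames(Biostrings::width(seqs), names(seqs))
  gr <- rtracklayer::import(gff3, format = "gff3")
  GenomeInfoDb::seqlevels(gr) <- names(seqs)
  GenomeInfoDb::seqlengths(gr) <- sl
  mc <- S4Vectors::mcols(gr)
  feat <- GenomicRanges::GRanges(
    GenomeInfoDb::seqnames(gr), IRanges::ranges(gr),
    strand = BiocGenerics::strand(gr),
    id = if ("ID" %in% names(mc)) mc$ID else as.character(seq_along(gr)),
    category = if ("category" %in% names(mc)) mc$category else
      as.character(mc$type),
    subtype = if ("subtype" %in% names(mc)) mc$subtype else NA_character_,
    gene_id = if ("gene_id" %in% names(mc)) mc$gene_id else NA_character_,
    seqlengths = sl)
  clusters <- GenomicRanges::GRanges(seqlengths = sl)
  if (!is.null(clusters_bed) && file.exists(clusters_bed)) {
    cb <- rtracklayer::import(clusters_bed, format = "bed")
    GenomeInfoDb::seqlevels(cb) <- names(seqs)
    GenomeInfoDb::seqlengths(cb) <- sl
    clusters <- GenomicRanges::GRanges(
      GenomeInfoDb::seqnames(cb), IRanges::ranges(cb),
      strand = BiocGenerics::strand(cb),
      id = cb$name, main_strand = as.character(BiocGenerics::strand(cb)),
      seqlengths = sl)
  }
  structure(list(seqs = seqs, features = feat, clusters = clusters,
                 spec = NULL), class = "genome_model")
}
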