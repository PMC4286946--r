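# Hierarchical annotation of mapped tags and distribution summaries.

#' Annotate mapped tags by the hierarchical priority rule
#'
#' Every (locus, feature) pair with at least `overlap_frac` of the locus
#' inside the feature is collected, and each tag receives the single
#' highest-priority category over all of its pairs
#' (tRNA > rRNA > snRNA > snoRNA > scRNA > miRNA > repeat > exon > intron;
#' see [category_priority()]).  Exon and intron assignments are split into
#' sense/antisense by comparing the locus strand with the gene strand (when
#' both orientations support the winning category, sense wins).  Tags whose
#' loci overlap no feature are `unannotated`; tags with zero loci are
#' absent from the result.  For repeat tags the subtype is recorded, with
#' `Ambi` when loci overlap more than one repeat subtype.
#'
#' @param mapping A `tag_mapping` from [map_tags()].
#' @param genome A `genome_model` providing the feature set.
#' @param overlap_frac Minimum fraction of the locus covered by the
#'   feature (default 0.5).
#' @return A data frame of class `tag_annotation`: `tag` (index), `category`
#'   (one of [ncrna_categories()]), `n_loci`, `repeat_subtype`.
#' @export
annotate_tags <- function(mapping, genome, overlap_frac = 0.5) {
  stopifnot(inherits(mapping, "tag_mapping"),
            inherits(genome, "genome_model"))
  loci <- mapping$loci
  mapped <- sort(unique(loci$tag))
  out <- data.frame(tag = mapped,
                    category = rep("unannotated", length(mapped)),
                    n_loci = mapping$n_loci[mapped],
                    repeat_subtype = rep(NA_character_, length(mapped)),
                    stringsAsFactors = FALSE)
  if (nrow(loci) == 0 || length(genome$features) == 0) {
    class(out) <- c("tag_annotation", "data.frame")
    return(out)
  }
  gr <- GenomicRanges::GRanges(
    seqnames = loci$chrom,
    ranges = IRanges::IRanges(start = loci$start + 1L, end = loci$end),
    strand = loci$strand)
  feat <- genome$features
  hits <- GenomicRanges::findOverlaps(gr, feat, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  ovl <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(gr)[qh], IRanges::ranges(feat)[sh]))
  keep <- ovl >= overlap_frac * IRanges::width(gr)[qh]
  qh <- qh[keep]; sh <- sh[keep]
  if (length(qh)) {
    pair_tag <- loci$tag[qh]
    pair_cat <- feat$category[sh]
    pair_pri <- match(pair_cat, category_priority())
    pair_sense <- loci$strand[qh] ==
      as.character(BiocGenerics::strand(feat))[sh]
    pair_sub <- feat$subtype[sh]

    f <- factor(pair_tag, levels = mapped)
    best <- tapply(pair_pri, f, min)
    has <- !is.na(best)
    win <- best[has]
    win_tags <- mapped[has]
    win_cat <- category_priority()[win]

    # sense/antisense split for exon/intron winners
    split_needed <- win_cat %in% c("exon", "intron")
    if (any(split_needed)) {
      key <- paste(pair_tag, pair_pri)
      win_key <- paste(win_tags, win)[split_needed]
      sense_any <- tapply(pair_sense, key, any)[win_key]
      win_cat[split_needed] <- paste0(win_cat[split_needed],
                                      ifelse(sense_any, "_sense",
                                             "_antisense"))
    }
    out$category[has] <- win_cat

    # repeat subtype, Ambi when several subtypes are hit
    rep_win <- which(has)[win_cat == "repeat"]
    if (length(rep_win)) {
      rp <- pair_cat == "repeat"
      nsub <- tapply(pair_sub[rp], factor(pair_tag[rp], levels = mapped),
                     function(x) length(unique(x[!is.na(x)])))
      sub1 <- tapply(pair_sub[rp], factor(pair_tag[rp], levels = mapped),
                     function(x) unique(x[!is.na(x)])[1])
      out$repeat_subtype[rep_win] <-
        ifelse(nsub[rep_win] > 1, "Ambi", sub1[rep_win])
    }
  }
  class(out) <- c("tag_annotation", "data.frame")
  out
}

#' Category and length distribution summaries
#'
#' Composition summary: per category and per tag length, the
#' count-weighted ("total reads") and unweighted ("unique reads")
#' distributions of genome-mapped tags.  Unmapped tags are excluded (the
#' annotation input already contains only mapped tags); tags with zero
#' count in a sample contribute nothing to that sample's tables.
#'
#' @param annotation A `tag_annotation` from [annotate_tags()].
#' @param tags The `tag_set` the annotation refers to.
#' @param sample Name of the count column sample to summarize; `NULL` sums
#'   counts over all samples.
#' @return A list of class `distribution_summary`: `category` (data frame
#'   category/total/unique) and `length` (data frame length/total/unique
#'   over 18-44 nt).
#' @export
summarize_distributions <- function(annotation, tags, sample = NULL) {
  counts <- tag_count_matrix(tags)
  cnt <- if (is.null(sample)) rowSums(counts) else {
    if (!sample %in% colnames(counts))
      stop2("unknown sample '", sample, "'")
    counts[, sample]
  }
  cnt <- cnt[annotation$tag]
  lens <- tags$length[annotation$tag]
  present <- cnt > 0
  cats <- factor(annotation$category, levels = ncrna_categories())
  lenf <- factor(lens, levels = 18:44)
  category <- data.frame(
    category = ncrna_categories(),
    total = as.vector(tapply(cnt, cats, sum, default = 0)),
    unique = as.vector(tapply(present, cats, sum, default = 0)))
  length_df <- data.frame(
    length = 18:44,
    total = as.vector(tapply(cnt, lenf, sum, default = 0)),
    unique = as.vector(tapply(present, lenf, sum, default = 0)))
  structure(list(category = category, length = length_df),
            class = "distribution_summary")
}

#' @export
print.distribution_summary <- function(x, ...) {
  cat("distribution_summary\n")
  print(x$category)
  invisible(x)
}
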