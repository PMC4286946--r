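# proTRAC-style probabilistic piRNA cluster prediction.

#' Cluster scan parameters
#'
#' Thresholds for accepting a candidate piRNA cluster: a minimum number of
#' distinct loci, a Poisson upper-tail significance level on the local hit
#' density against the genome-wide uniform rate, a minimum main/minor
#' strand-bias score, and minimum fractions of loci with typical piRNA
#' length (26-32 nt) and with the 1U/10A ping-pong signature.  All
#' criteria must hold simultaneously for acceptance.
#'
#' @param min_loci Minimum distinct loci per cluster (default 6).
#' @param density_alpha Significance level for the density test
#'   (default 0.05).
#' @param min_strand_bias_score Minimum main/minor strand score
#'   (default 1.3).
#' @param pirna_length_range Typical piRNA length range in nt
#'   (default c(26, 32)).
#' @param min_length_fraction Minimum (weighted) fraction of loci with
#'   typical length (default 0.75).
#' @param min_1u10a_fraction Minimum (weighted) fraction of loci whose tag
#'   has T at position 1 or A at position 10 (default 0.75).
#' @param window Scan window in nt (default 5000; step is window/2).
#' @param locus_weighting `"one_over_nloci"` (each locus weighs one over
#'   its tag's genome-wide locus count, favouring infrequently mapped
#'   reads) or `"uniform"`.
#' @return An object of class `cluster_params`.
#' @export
cluster_params <- function(min_loci = 6L,
                           density_alpha = 0.05,
                           min_strand_bias_score = 1.3,
                           pirna_length_range = c(26L, 32L),
                           min_length_fraction = 0.75,
                           min_1u10a_fraction = 0.75,
                           window = 5000L,
                           locus_weighting = c("one_over_nloci",
                                               "uniform")) {
  locus_weighting <- match.arg(locus_weighting)
  stopifnot(min_loci >= 2, density_alpha > 0, density_alpha < 1,
            min_length_fraction >= 0, min_length_fraction <= 1,
            min_1u10a_fraction >= 0, min_1u10a_fraction <= 1,
            length(pirna_length_range) == 2,
            pirna_length_range[1] <= pirna_length_range[2],
            window >= 100)
  structure(list(min_loci = as.integer(min_loci),
                 density_alpha = density_alpha,
                 min_strand_bias_score = min_strand_bias_score,
                 pirna_length_range = as.integer(pirna_length_range),
                 min_length_fraction = min_length_fraction,
                 min_1u10a_fraction = min_1u10a_fraction,
                 window = as.integer(window),
                 locus_weighting = locus_weighting),
            class = "cluster_params")
}

#' 1U/10A ping-pong signature test
#'
#' `TRUE` when the tag starts with T (U on the RNA) or carries A at
#' position 10 (1-based, on the tag as sequenced).  Sequences shorter than
#' 10 nt return `FALSE` with a warning.
#'
#' @param seqs Character vector of tag sequences.
#' @return Logical vector.
#' @export
one_u_ten_a <- function(seqs) {
  short <- nchar(seqs) < 10L
  if (any(short))
    warning(sum(short), " sequence(s) shorter than 10 nt classified FALSE")
  res <- substr(seqs, 1L, 1L) == "T" | substr(seqs, 10L, 10L) == "A"
  res & !short
}

#' Strand-bias score of a set of loci
#'
#' The ratio of the (weighted) locus count on the heavier strand to that on
#' the lighter strand, with the minor-strand count floored at 1 so the
#' score is defined for single-stranded clusters (where it equals the
#' main-strand weight).
#'
#' @param strand Character vector of locus strands ("+" / "-").
#' @param weights Optional locus weights (default 1 each).
#' @return The strand-bias score (a single number >= weighted main count /
#'   max(weighted minor count, 1)).
#' @export
strand_bias_score <- function(strand, weights = rep(1, length(strand))) {
  stopifnot(length(strand) >= 1, length(weights) == length(strand))
  wp <- sum(weights[strand == "+"])
  wm <- sum(weights[strand == "-"])
  max(wp, wm) / max(min(wp, wm), 1)
}

#' Scan the genome for piRNA clusters
#'
#' Slides a window of `params$window` nt in steps of half a window; a
#' window is candidate-significant when the Poisson upper-tail probability
#' of observing at least its locus count under the genome-wide uniform
#' rate (total loci / total genome length) is at or below
#' `density_alpha`.  Overlapping significant windows are merged, merged
#' intervals are trimmed to their outermost loci, and per-cluster
#' statistics are computed with the configured locus weighting (the
#' distinct-locus count itself, used for `min_loci` and the density
#' p-value, is unweighted).  A cluster is accepted when all thresholds
#' hold.  Output is independent of input locus order.
#'
#' @param mapping A `tag_mapping` from [map_tags()] or [read_eland3()].
#' @param genome A `genome_model` (used for chromosome lengths).
#' @param params A [cluster_params()].
#' @return A data frame of class `pirna_clusters`: `chrom`, `start`, `end`
#'   (0-based half-open, trimmed to outermost loci), `n_loci`, `n_tags`,
#'   `main_strand`, `strand_bias_score`, `frac_1u10a`,
#'   `frac_typical_length`, `density_p`, `accepted`.
#' @export
scan_clusters <- function(mapping, genome, params = cluster_params()) {
  stopifnot(inherits(mapping, "tag_mapping"))
  chrom_len <- setNames(Biostrings::width(genome$seqs), names(genome$seqs))
  if (sum(chrom_len) == 0) stop2("genome length is zero")
  loci <- mapping$loci
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), n_loci = integer(),
                      n_tags = integer(), main_strand = character(),
                      strand_bias_score = numeric(), frac_1u10a = numeric(),
                      frac_typical_length = numeric(), density_p = numeric(),
                      accepted = logical(), stringsAsFactors = FALSE)
  class(empty) <- c("pirna_clusters", "data.frame")
  if (nrow(loci) == 0) return(empty)

  lambda <- nrow(loci) / sum(chrom_len)
  w <- params$window
  step <- w / 2
  tag_w <- if (params$locus_weighting == "one_over_nloci")
    1 / pmax(mapping$n_loci, 1L) else rep(1, length(mapping$n_loci))
  sig_1u10a <- suppressWarnings(one_u_ten_a(mapping$sequences))
  tag_len <- nchar(mapping$sequences)
  rng <- params$pirna_length_range

  rows <- list()
  for (cn in unique(loci$chrom)) {
    li <- loci[loci$chrom == cn, , drop = FALSE]
    li <- li[order(li$start, li$end, li$strand), , drop = FALSE]
    starts_sorted <- li$start
    clen <- chrom_len[[cn]]
    ws <- seq(0, max(0, clen - 1), by = step)
    n_in <- findInterval(ws + w - 0.5, starts_sorted) -
      findInterval(ws - 0.5, starts_sorted)
    pv <- ppois(n_in - 1, lambda * w, lower.tail = FALSE)
    sig <- which(pv <= params$density_alpha & n_in > 0)
    if (length(sig) == 0) next
    # merge overlapping significant windows
    ivs <- cbind(ws[sig], pmin(ws[sig] + w, clen))
    merged <- list()
    cur <- ivs[1, ]
    for (r in seq_len(nrow(ivs))[-1]) {
      if (ivs[r, 1] <= cur[2]) cur[2] <- max(cur[2], ivs[r, 2])
      else { merged[[length(merged) + 1L]] <- cur; cur <- ivs[r, ] }
    }
    merged[[length(merged) + 1L]] <- cur
    for (iv in merged) {
      inside <- li$start >= iv[1] & li$start < iv[2]
      if (!any(inside)) next
      sub <- li[inside, , drop = FALSE]
      cs <- min(sub$start); ce <- max(sub$end)
      wts <- tag_w[sub$tag]
      wp <- sum(wts[sub$strand == "+"])
      wm <- sum(wts[sub$strand == "-"])
      main <- if (wp >= wm) "+" else "-"
      n_loci <- nrow(sub)
      score <- max(wp, wm) / max(min(wp, wm), 1)
      f_sig <- sum(wts * sig_1u10a[sub$tag]) / sum(wts)
      f_len <- sum(wts * (tag_len[sub$tag] >= rng[1] &
                            tag_len[sub$tag] <= rng[2])) / sum(wts)
      dp <- ppois(n_loci - 1, lambda * (ce - cs), lower.tail = FALSE)
      acc <- n_loci >= params$min_loci &&
        dp <= params$density_alpha &&
        score >= params$min_strand_bias_score &&
        f_sig >= params$min_1u10a_fraction &&
        f_len >= params$min_length_fraction
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = cn, start = cs, end = ce, n_loci = n_loci,
        n_tags = length(unique(sub$tag)), main_strand = main,
        strand_bias_score = score, frac_1u10a = f_sig,
        frac_typical_length = f_len, density_p = dp, accepted = acc,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pirna_clusters", "data.frame")
  out
}

#' Call putative piRNAs from accepted clusters
#'
#' A tag is called a piRNA when at least one of its loci lies fully inside
#' an accepted cluster.  Each tag is counted once; its origin is the
#' category the annotation stage assigned.
#'
#' @param clusters A `pirna_clusters` data frame from [scan_clusters()].
#' @param mapping The `tag_mapping` the clusters were scanned from.
#' @param annotation A `tag_annotation` for the same tags.
#' @return A list of class `pirna_calls`: `calls` (data frame `tag`,
#'   `origin_category`) and `origin` (data frame `category`, `n` over
#'   [ncrna_categories()]).
#' @export
call_pirnas <- function(clusters, mapping, annotation) {
  acc <- clusters[clusters$accepted, , drop = FALSE]
  loci <- mapping$loci
  called <- integer(0)
  if (nrow(acc) > 0 && nrow(loci) > 0) {
    hit <- rep(FALSE, nrow(loci))
    for (r in seq_len(nrow(acc))) {
      hit <- hit | (loci$chrom == acc$chrom[r] &
                      loci$start >= acc$start[r] &
                      loci$end <= acc$end[r])
    }
    called <- sort(unique(loci$tag[hit]))
  }
  origin_cat <- annotation$category[match(called, annotation$tag)]
  origin_cat[is.na(origin_cat)] <- "unannotated"
  origin <- data.frame(
    category = ncrna_categories(),
    n = as.vector(table(factor(origin_cat, levels = ncrna_categories()))))
  structure(list(calls = data.frame(tag = called,
                                    origin_category = origin_cat,
                                    stringsAsFactors = FALSE),
                 origin = origin),
            class = "pirna_calls")
}

#' @export
print.pirna_calls <- function(x, ...) {
  cat("pirna_calls:", nrow(x$calls), "putative piRNAs\n")
  invisible(x)
}

#' Write clusters as BED6+ with statistics columns
#'
#' @param clusters A `pirna_clusters` data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_clusters_bed <- function(clusters, path) {
  df <- data.frame(clusters$chrom, clusters$start, clusters$end,
                   sprintf("cluster_%03d", seq_len(nrow(clusters))),
                   0L, clusters$main_strand,
                   clusters$n_loci, signif(clusters$density_p, 6),
                   round(clusters$strand_bias_score, 4),
                   round(clusters$frac_1u10a, 4),
                   round(clusters$frac_typical_length, 4),
                   clusters$accepted)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
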