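# RPKM, cross-sample fold change and upregulation tables.

#' RPKM of tags
#'
#' Reads per kilobase (of the tag's own length) per million clean reads:
#' `C * 1e9 / (L * N)` for count `C`, tag length `L` in nt and sample
#' clean-read total `N`.  The per-million basis is the sample's clean read
#' total, not its mapped total (configurable via `totals`).
#'
#' @param counts Integer vector (or matrix, samples in columns) of tag
#'   counts.
#' @param lengths Tag lengths in nt.
#' @param totals Clean-read totals per sample (recycled across columns for
#'   a matrix).  Must be positive.
#' @return Numeric vector or matrix of RPKM values.
#' @export
rpkm <- function(counts, lengths, totals) {
  if (any(totals <= 0)) stop2("sample clean-read total must be > 0")
  if (is.matrix(counts)) {
    if (length(totals) != ncol(counts))
      stop2("need one clean-read total per sample column")
    t(t(counts * 1e9 / lengths) / totals)
  } else {
    counts * 1e9 / (lengths * totals)
  }
}

#' Cross-sample fold change
#'
#' For a focal sample, the fold change of each tag is its focal RPKM over
#' the mean RPKM of the remaining samples, with a pseudocount guarding the
#' zero denominator: `FC = rpkm[focal] / max(mean(rpkm[others]), delta)`.
#' The default `delta = 0.01` reproduces published fold-change tables,
#' including rows where the tag is absent from every reference sample.
#'
#' @param rpkm_mat Numeric matrix of RPKM values, samples in columns.
#' @param focal Focal sample (column name or index).
#' @param delta Pseudocount floor for the reference mean (default 0.01).
#' @return Numeric vector of fold changes, one per row.
#' @export
fold_change <- function(rpkm_mat, focal, delta = 0.01) {
  rpkm_mat <- as.matrix(rpkm_mat)
  if (is.character(focal)) focal <- match(focal, colnames(rpkm_mat))
  if (is.na(focal) || focal < 1 || focal > ncol(rpkm_mat))
    stop2("unknown focal sample")
  others <- rpkm_mat[, -focal, drop = FALSE]
  denom <- pmax(rowMeans(others), delta)
  rpkm_mat[, focal] / denom
}

#' Expression records for a tag set
#'
#' Per-sample RPKM, per-sample fold change against the mean of the other
#' samples, and the 2-fold upregulation flag.
#'
#' @param tags A `tag_set` from [collapse_tags()].
#' @param totals Named clean-read totals, one per sample (order and names
#'   matching the count columns).
#' @param delta Pseudocount for [fold_change()].
#' @param fc_cutoff Upregulation threshold on the fold change (default 2).
#' @return A list of class `expression_set` with matrices `rpkm`, `fc`
#'   and logical `upregulated` (tags x samples), and `samples`.
#' @export
expression_records <- function(tags, totals, delta = 0.01, fc_cutoff = 2) {
  counts <- tag_count_matrix(tags)
  samples <- colnames(counts)
  if (!is.null(names(totals))) totals <- totals[samples]
  if (length(totals) != length(samples) || any(is.na(totals)))
    stop2("totals must provide one clean-read total per sample")
  r <- rpkm(counts, tags$length, as.numeric(totals))
  fc <- vapply(seq_along(samples), function(j) fold_change(r, j, delta),
               numeric(nrow(counts)))
  colnames(fc) <- samples
  structure(list(rpkm = r, fc = fc, upregulated = fc >= fc_cutoff,
                 samples = samples, fc_cutoff = fc_cutoff, delta = delta),
            class = "expression_set")
}

#' Upregulation-by-category table
#'
#' For each focal sample, counts the tags upregulated there (fold change at
#' or above the cutoff) by annotation category, with percentages of the
#' sample's upregulated total reported to two decimals (half-up).
#'
#' @param expr An `expression_set` from [expression_records()].
#' @param annotation A `tag_annotation`; tags absent from it (unmapped) are
#'   excluded.
#' @return A data frame of class `upregulation_table`: `category`, then per
#'   sample `n_<sample>` and `pct_<sample>` columns, with a final `Total`
#'   row.
#' @export
upregulation_table <- function(expr, annotation) {
  cats <- ncrna_categories()
  out <- data.frame(category = c(cats, "Total"))
  for (s in expr$samples) {
    up_tags <- which(expr$upregulated[, s])
    ann_idx <- match(up_tags, annotation$tag)
    cat_up <- annotation$category[ann_idx[!is.na(ann_idx)]]
    n <- as.vector(table(factor(cat_up, levels = cats)))
    total <- sum(n)
    pct <- if (total > 0) upregulation_percentages(n, total) else
      rep(NA_real_, length(n))
    out[[paste0("n_", s)]] <- c(n, total)
    out[[paste0("pct_", s)]] <- c(pct, if (total > 0) 100 else NA_real_)
  }
  class(out) <- c("upregulation_table", "data.frame")
  out
}

#' Report percentages for upregulation tables
#'
#' `100 * count / total`, rounded half-up to two decimals at report time
#' (internal values keep full precision).
#'
#' @param counts Category counts.
#' @param total Denominator (the sample's upregulated total).
#' @return Numeric vector of percentages.
#' @export
upregulation_percentages <- function(counts, total) {
  if (total <= 0) stop2("total must be positive")
  round_half_up(100 * counts / total, 2L)
}
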