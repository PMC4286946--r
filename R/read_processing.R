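# Read cleaning and unique-tag collapsing.

#' Cleaning configuration
#'
#' Thresholds for producing clean reads: 3' adapter trimming (best
#' suffix-prefix match with at least `min_adapter_overlap` bases and at most
#' 10% mismatches in the overlap), a mean per-base Phred filter (reads with
#' mean quality below `min_mean_quality` are discarded), and an insert
#' length window.  Filters are applied in the order trim, quality, length,
#' so it is the quality of the insert, not of the adapter, that decides
#' retention.  Reads containing N after trimming are discarded.
#'
#' @param min_mean_quality Minimum mean Phred score of the trimmed insert
#'   (default 13; reads with mean quality strictly below are removed).
#' @param min_length Minimum insert length in nt (default 18).
#' @param max_length Maximum insert length in nt (default 44).
#' @param adapter 3' adapter sequence to trim.
#' @param min_adapter_overlap Minimum read/adapter overlap to trim
#'   (default 6).
#' @param max_adapter_mismatch_frac Maximum mismatch fraction in the
#'   overlap (default 0.1).
#' @return An object of class `cleaning_config`.
#' @export
cleaning_config <- function(min_mean_quality = 13,
                            min_length = 18L,
                            max_length = 44L,
                            adapter = default_adapter(),
                            min_adapter_overlap = 6L,
                            max_adapter_mismatch_frac = 0.1) {
  if (min_length > max_length) stop2("min_length must be <= max_length")
  if (min_mean_quality < 0) stop2("min_mean_quality must be >= 0")
  structure(list(min_mean_quality = min_mean_quality,
                 min_length = as.integer(min_length),
                 max_length = as.integer(max_length),
                 adapter = adapter,
                 min_adapter_overlap = as.integer(min_adapter_overlap),
                 max_adapter_mismatch_frac = max_adapter_mismatch_frac),
            class = "cleaning_config")
}

#' Clean a small-RNA library
#'
#' Produces "clean reads": adapter-trimmed, mean Phred at or above the
#' quality threshold, insert length inside the configured window, no N.
#' Read order is preserved.
#'
#' @param reads A `small_rna_library`, a list with `id`, `seq`, `qual`
#'   character vectors, or a path to a FASTQ file.
#' @param config A [cleaning_config()].
#' @return A list of class `clean_library`: `id`, `seq`, `qual` of the
#'   retained (trimmed) reads, `stats` (a `library_stats` list with
#'   total_reads, total_bases, clean_reads, clean_bases, min_len, max_len,
#'   unique_tags), and `keep`, a logical vector over the input reads.
#' @export
clean_reads <- function(reads, config = cleaning_config()) {
  if (is.character(reads) && length(reads) == 1L) reads <- read_fastq(reads)
  seqs <- reads$seq
  quals <- reads$qual
  ids <- if (!is.null(reads$id)) reads$id else
    sprintf("read_%07d", seq_along(seqs))
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad))
    stop2("malformed FASTQ record ", bad[1],
          ": sequence and quality lengths differ")
  res <- cpp_clean_reads(seqs, quals, config$adapter,
                         config$min_adapter_overlap,
                         config$max_adapter_mismatch_frac,
                         config$min_mean_quality,
                         config$min_length, config$max_length)
  keep <- res$keep
  trimmed_seq <- substr(seqs, 1L, res$trim_len)[keep]
  trimmed_qual <- substr(quals, 1L, res$trim_len)[keep]
  lens <- nchar(trimmed_seq)
  stats <- list(
    total_reads = length(seqs),
    total_bases = sum(nchar(seqs)),
    clean_reads = sum(keep),
    clean_bases = sum(lens),
    min_len = if (length(lens)) min(lens) else NA_integer_,
    max_len = if (length(lens)) max(lens) else NA_integer_,
    unique_tags = length(unique(trimmed_seq)))
  class(stats) <- "library_stats"
  structure(list(id = ids[keep], seq = trimmed_seq, qual = trimmed_qual,
                 stats = stats, keep = keep,
                 trim_len = res$trim_len, reason = res$reason),
            class = "clean_library")
}

#' @export
print.library_stats <- function(x, ...) {
  cat(sprintf(paste0("library_stats: %d/%d reads retained ",
                     "(%d unique tags, lengths %s-%s)\n"),
              x$clean_reads, x$total_reads, x$unique_tags,
              x$min_len, x$max_len))
  invisible(x)
}

#' Collapse clean reads into unique tags
#'
#' One row per distinct sequence with one count column per sample.  The
#' conservation identity holds by construction: per sample, the counts sum
#' to that sample's number of clean reads.
#'
#' @param samples Named list; each element is a `clean_library` (or any
#'   list with a `seq` character vector of clean reads).
#' @return A data frame of class `tag_set`: `sequence`, `length`, then one
#'   integer column `count_<sample>` per sample.
#' @export
collapse_tags <- function(samples) {
  stopifnot(is.list(samples), length(samples) >= 1,
            !is.null(names(samples)), all(nzchar(names(samples))))
  all_seq <- sort(unique(unlist(lapply(samples, `[[`, "seq"),
                                use.names = FALSE)))
  out <- data.frame(sequence = all_seq, length = nchar(all_seq),
                    stringsAsFactors = FALSE)
  for (s in names(samples)) {
    tab <- table(factor(samples[[s]]$seq, levels = all_seq))
    out[[paste0("count_", s)]] <- as.integer(tab)
  }
  class(out) <- c("tag_set", "data.frame")
  out
}

tag_count_matrix <- function(tags) {
  cols <- grep("^count_", names(tags), value = TRUE)
  m <- as.matrix(tags[, cols, drop = FALSE])
  colnames(m) <- sub("^count_", "", cols)
  rownames(m) <- NULL
  m
}

#' Write a tag set as collapsed FASTA and TSV
#'
#' The FASTA uses the `tag<i>_x<count>` header dialect (count = total over
#' samples); the TSV has one row per tag with per-sample count columns.
#'
#' @param tags A `tag_set` from [collapse_tags()].
#' @param fasta,tsv Output paths (either may be `NULL` to skip).
#' @return Invisibly, `tags`.
#' @export
write_tags <- function(tags, fasta = NULL, tsv = NULL) {
  if (!is.null(fasta)) {
    total <- rowSums(tag_count_matrix(tags))
    writeLines(paste0(">tag", seq_len(nrow(tags)), "_x", total, "\n",
                      tags$sequence),
               fasta)
  }
  if (!is.null(tsv)) .write_tsv(as.data.frame(tags), tsv)
  invisible(tags)
}
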