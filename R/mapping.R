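# Genome placement of unique tags under the identity/coverage contract.

#' Mapping parameters
#'
#' A tag maps at a locus when an ungapped alignment of at least
#' `ceil(min_coverage * L)` consecutive tag bases (L = tag length) carries
#' at most `floor((1 - min_identity) * aligned_length)` mismatches.  At
#' 18-44 nt these thresholds admit at most 2-4 mismatches and no meaningful
#' gaps, so alignment is ungapped by design.  Candidate placements come
#' from an exact k-mer seed index; `seed_length = 12` finds every
#' qualifying alignment that contains an exact 12-mer run, and lowering it
#' to 6 makes the search provably exhaustive for the default thresholds
#' over 18-44-nt tags (pigeonhole on mismatch spacing).
#'
#' @param min_identity Minimum fraction of matching bases over aligned
#'   bases (default 0.90).
#' @param min_coverage Minimum fraction of the tag that must be aligned
#'   (default 0.95).
#' @param seed_length Exact seed length for candidate generation.
#' @param max_loci Cap on reported loci per tag; the full locus count is
#'   still returned and an overflow flag is set.
#' @return An object of class `mapping_params`.
#' @export
mapping_params <- function(min_identity = 0.90, min_coverage = 0.95,
                           seed_length = 12L, max_loci = 500L) {
  stopifnot(min_identity > 0, min_identity <= 1,
            min_coverage > 0, min_coverage <= 1,
            seed_length >= 4, seed_length <= 14, max_loci >= 1)
  structure(list(min_identity = min_identity, min_coverage = min_coverage,
                 seed_length = as.integer(seed_length),
                 max_loci = as.integer(max_loci)),
            class = "mapping_params")
}

#' Map unique tags onto a genome
#'
#' Reports all loci on both strands satisfying the identity/coverage
#' contract of [mapping_params()], ordered by (chrom, start, strand).
#'
#' @param tags A `tag_set` from [collapse_tags()], or a character vector of
#'   tag sequences (A/C/G/T only; tags containing other characters should
#'   have been removed by cleaning and raise an error here).
#' @param genome A `genome_model`.
#' @param params A [mapping_params()].
#' @return A list of class `tag_mapping`:
#'   * `loci`: data frame with `tag` (index into the tag set), `chrom`,
#'     `start` (0-based inclusive), `end` (0-based exclusive), `strand`,
#'     `identity`, `coverage`, `mismatches`;
#'   * `n_loci`: integer vector, total qualifying loci per tag (uncapped);
#'   * `overflow`: logical vector, `TRUE` where the locus list was
#'     truncated at `max_loci`;
#'   * `sequences`: the tag sequences, in input order.
#' @export
map_tags <- function(tags, genome, params = mapping_params()) {
  stopifnot(inherits(genome, "genome_model"))
  seqs <- if (is.character(tags)) tags else tags$sequence
  if (length(seqs) == 0) {
    return(structure(list(
      loci = data.frame(tag = integer(), chrom = character(),
                        start = integer(), end = integer(),
                        strand = character(), identity = numeric(),
                        coverage = numeric(), mismatches = integer()),
      n_loci = integer(), overflow = logical(), sequences = character()),
      class = "tag_mapping"))
  }
  chrom_names <- names(genome$seqs)
  res <- cpp_map_tags(seqs, as.character(genome$seqs),
                      params$seed_length, params$min_identity,
                      params$min_coverage, params$max_loci)
  loci <- data.frame(
    tag = res$tag,
    chrom = chrom_names[res$chrom],
    start = res$start,
    end = res$end,
    strand = res$strand,
    identity = (res$aligned - res$mismatches) / res$aligned,
    coverage = res$aligned / nchar(seqs)[res$tag],
    mismatches = res$mismatches,
    stringsAsFactors = FALSE)
  structure(list(loci = loci, n_loci = res$n_loci,
                 overflow = res$overflow, sequences = seqs),
            class = "tag_mapping")
}

#' @export
print.tag_mapping <- function(x, ...) {
  cat("tag_mapping:", length(x$sequences), "tags,",
      sum(x$n_loci > 0), "mapped,", nrow(x$loci), "loci\n")
  invisible(x)
}

#' Write mapped loci as BED6
#'
#' Score column carries `round(identity * 1000)`; the name column carries
#' the tag index.
#'
#' @param mapping A `tag_mapping`.
#' @param path Output BED path.
#' @return Invisibly, `path`.
#' @export
write_loci_bed <- function(mapping, path) {
  l <- mapping$loci
  bed <- data.frame(l$chrom, l$start, l$end,
                    paste0("tag", l$tag),
                    as.integer(round(l$identity * 1000)),
                    l$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write or read loci as ELAND3-like alignment records
#'
#' Tab-separated (tag sequence, chromosome, 0-based position, strand,
#' mismatches), one row per locus, for interoperability with external
#' cluster scanners.
#'
#' @param mapping A `tag_mapping`.
#' @param path TSV path.
#' @return `write_eland3()` invisibly returns `path`; `read_eland3()`
#'   returns a `tag_mapping` (with coverage/identity computed from the
#'   stored mismatch counts over full-length alignments).
#' @export
write_eland3 <- function(mapping, path) {
  l <- mapping$loci
  df <- data.frame(tag = mapping$sequences[l$tag], chrom = l$chrom,
                   pos = l$start, strand = l$strand,
                   mismatches = l$mismatches)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_eland3
#' @export
read_eland3 <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  seqs <- unique(df$tag)
  idx <- match(df$tag, seqs)
  L <- nchar(df$tag)
  loci <- data.frame(tag = idx, chrom = df$chrom, start = df$pos,
                     end = df$pos + L, strand = df$strand,
                     identity = (L - df$mismatches) / L,
                     coverage = 1, mismatches = df$mismatches,
                     stringsAsFactors = FALSE)
  o <- order(loci$tag, loci$chrom, loci$start, loci$strand)
  loci <- loci[o, , drop = FALSE]
  rownames(loci) <- NULL
  structure(list(loci = loci,
                 n_loci = as.integer(table(factor(idx,
                                                  seq_along(seqs)))),
                 overflow = rep(FALSE, length(seqs)),
                 sequences = seqs),
            class = "tag_mapping")
}
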