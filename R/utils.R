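# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random-number stream.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Round half away from zero, as report tables conventionally do (base round()
# uses banker's rounding).
round_half_up <- function(x, digits = 2L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Reverse complement for plain character vectors of A/C/G/T/N.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Annotation categories in reporting order.  Priority for the assignment rule
# is position in `category_priority()` (lower index = higher priority).
ncrna_categories <- function() {
  c("tRNA", "rRNA", "snRNA", "snoRNA", "scRNA", "miRNA", "repeat",
    "exon_sense", "exon_antisense", "intron_sense", "intron_antisense",
    "unannotated")
}

#' Annotation priority order
#'
#' The hierarchical rule that assigns each unique tag a single category:
#' structural RNAs (tRNA > rRNA > snRNA > snoRNA > scRNA) outrank miRNAs,
#' which outrank repeats, which outrank exons, which outrank introns.
#' Sense/antisense resolution for exons and introns happens after the
#' category is chosen and does not affect priority.
#'
#' @return Character vector of categories, highest priority first.
#' @export
category_priority <- function() {
  c("tRNA", "rRNA", "snRNA", "snoRNA", "scRNA", "miRNA", "repeat",
    "exon", "intron")
}

stop2 <- function(...) stop(..., call. = FALSE)
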