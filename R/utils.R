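stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

`%||%` <- function(x, y) if (is.null(x)) y else x

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x >= 0 && x == floor(x)

#' Construct a table of genomic intervals
#'
#' Intervals are plain data frames with 0-based half-open coordinates,
#' the universal currency of the package (peaks, marks, regions).
#'
#' @param chrom Chromosome names.
#' @param start 0-based inclusive start offsets.
#' @param end Exclusive end offsets; must satisfy `start < end`.
#' @param name Optional identifiers.
#' @param score Optional numeric scores (signal, fold enrichment).
#' @param strand Optional strand, one of `+`, `-`, `.`.
#' @return A `data.frame` with columns chrom/start/end/name/score/strand.
#' @export
genomic_intervals <- function(chrom, start, end, name = NA_character_,
                              score = NA_real_, strand = ".") {
  if (length(chrom) == 0) {
    name <- character(0); score <- numeric(0); strand <- character(0)
  }
  x <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                  end = as.numeric(end), name = as.character(name),
                  score = as.numeric(score), strand = as.character(strand),
                  stringsAsFactors = FALSE)
  validate_intervals(x)
  x
}

validate_intervals <- function(x, what = "interval") {
  if (!all(c("chrom", "start", "end") %in% names(x)))
    stopf("%s table must have chrom/start/end columns", what)
  if (nrow(x) == 0) return(invisible(x))
  if (any(is.na(x$start)) || any(is.na(x$end)))
    stopf("%s coordinates contain NA", what)
  bad <- which(x$start >= x$end | x$start < 0)
  if (length(bad))
    stopf("invalid %s: start >= end or start < 0 at row %d", what, bad[1])
  invisible(x)
}

empty_intervals <- function() {
  genomic_intervals(character(), numeric(), numeric(), character(),
                    numeric(), character())
}

# 0-based half-open data.frame -> GRanges (1-based closed)
as_granges <- function(x, layout = NULL) {
  seqlens <- NULL
  if (!is.null(layout)) seqlens <- setNames(layout$length, layout$chrom)
  GenomicRanges::GRanges(x$chrom,
                         IRanges::IRanges(x$start + 1, x$end),
                         seqlengths = seqlens)
}

# GRanges -> 0-based half-open data.frame
from_granges <- function(gr, score = NA_real_, name = NA_character_) {
  genomic_intervals(as.character(GenomicRanges::seqnames(gr)),
                    IRanges::start(gr) - 1, IRanges::end(gr),
                    name = name, score = score)
}
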