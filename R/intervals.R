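#' Genome layout: ordered chromosome names with lengths
#'
#' @param chrom Unique chromosome names.
#' @param length Chromosome lengths in bp (> 0).
#' @return A `data.frame` with columns `chrom` and `length`.
#' @export
genome_layout <- function(chrom, length) {
  chrom <- as.character(chrom); length <- as.numeric(length)
  if (anyDuplicated(chrom)) stopf("duplicate chromosome names in layout")
  if (any(length <= 0)) stopf("chromosome lengths must be > 0")
  data.frame(chrom = chrom, length = length, stringsAsFactors = FALSE)
}

#' Read a two-column chrom.sizes file
#'
#' @param path TSV with chromosome name and length.
#' @return A genome layout (see [genome_layout()]).
#' @export
read_chrom_sizes <- function(path) {
  x <- data.table::fread(path, header = FALSE, sep = "\t",
                         colClasses = list(character = 1))
  if (ncol(x) < 2) stopf("chrom.sizes file needs two columns: %s", path)
  genome_layout(x[[1]], as.numeric(x[[2]]))
}

#' Write a genome layout as a chrom.sizes file
#' @param layout Genome layout.
#' @param path Output path.
#' @export
write_chrom_sizes <- function(layout, path) {
  data.table::fwrite(layout, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Base pairs shared by two intervals
#'
#' Vectorized over rows; intervals on different chromosomes share 0 bp,
#' and half-open abutment counts as 0.
#'
#' @param a,b Interval tables (recycled row-wise to equal length).
#' @return Numeric vector of shared bp.
#' @export
overlap_bp <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  ai <- rep_len(seq_len(nrow(a)), n); bi <- rep_len(seq_len(nrow(b)), n)
  out <- pmax(0, pmin(a$end[ai], b$end[bi]) - pmax(a$start[ai], b$start[bi]))
  out[a$chrom[ai] != b$chrom[bi]] <- 0
  out
}

#' Merge intervals, joining neighbours within a gap
#'
#' Returns sorted, disjoint intervals; members within `gap` bp of each
#' other are joined. The merged score is the maximum member score (never
#' the sum); names are dropped.
#'
#' @param x Interval table.
#' @param gap Maximum joined gap in bp (default 0 = touching/overlapping).
#' @return Sorted disjoint interval table.
#' @export
merge_intervals <- function(x, gap = 0) {
  if (nrow(x) == 0) return(empty_intervals())
  validate_intervals(x)
  gr <- as_granges(x)
  red <- GenomicRanges::reduce(gr, min.gapwidth = gap + 1, with.revmap = TRUE)
  score <- if ("score" %in% names(x) && !all(is.na(x$score))) {
    vapply(S4Vectors::mcols(red)$revmap, function(i)
      suppressWarnings(max(x$score[i], na.rm = TRUE)), numeric(1))
  } else NA_real_
  score[is.infinite(score)] <- NA_real_
  out <- from_granges(red, score = score)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Length-matched random regions
#'
#' Draws one random region per template interval with identical length.
#' The chromosome is chosen with probability proportional to its length
#' (among chromosomes long enough to hold the region) and the start is
#' uniform over the valid range. Sampled regions may overlap each other
#' and the template; this is the null model for all observed-versus-random
#' enrichment comparisons.
#'
#' @param template Interval table whose lengths are matched.
#' @param layout Genome layout.
#' @param seed Integer seed; same seed, same draw.
#' @return Interval table, one row per template row.
#' @export
sample_matched_random_regions <- function(template, layout, seed) {
  validate_intervals(template)
  lens <- template$end - template$start
  if (nrow(template) == 0) return(empty_intervals())
  if (max(lens) > max(layout$length))
    stopf("template length %d exceeds the longest chromosome", max(lens))
  set.seed(seed)
  n <- length(lens)
  ci <- sample.int(nrow(layout), n, replace = TRUE, prob = layout$length)
  # re-draw any region that does not fit its chromosome, among those that fit
  for (attempt in seq_len(50)) {
    bad <- which(lens > layout$length[ci])
    if (!length(bad)) break
    for (i in bad) {
      ok <- which(layout$length >= lens[i])
      ci[i] <- if (length(ok) == 1) ok else
        sample(ok, 1, prob = layout$length[ok])
    }
  }
  start <- floor(runif(n, min = 0, max = layout$length[ci] - lens + 1))
  genomic_intervals(layout$chrom[ci], start, start + lens,
                    name = sprintf("random_%d", seq_len(n)))
}

# number of reference intervals overlapping each query by >= min_overlap_bp
count_interval_overlaps <- function(query, subject, min_overlap_bp = 1) {
  if (nrow(query) == 0) return(integer(0))
  if (nrow(subject) == 0) return(integer(nrow(query)))
  GenomicRanges::countOverlaps(as_granges(query), as_granges(subject),
                               minoverlap = min_overlap_bp)
}

# total bp of each query interval covered by the union of subject intervals
covered_bp <- function(query, subject) {
  if (nrow(query) == 0) return(numeric(0))
  if (nrow(subject) == 0) return(numeric(nrow(query)))
  qgr <- as_granges(query)
  sgr <- GenomicRanges::reduce(as_granges(subject))
  hits <- GenomicRanges::findOverlaps(qgr, sgr)
  if (!length(hits)) return(numeric(nrow(query)))
  w <- IRanges::width(GenomicRanges::pintersect(qgr[S4Vectors::queryHits(hits)],
                                                sgr[S4Vectors::subjectHits(hits)]))
  out <- numeric(nrow(query))
  agg <- rowsum(w, S4Vectors::queryHits(hits))
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}
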