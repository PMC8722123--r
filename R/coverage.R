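#' Construct a coverage track from signal steps
#'
#' A coverage track is a stepped, non-negative per-base signal (IP or
#' input coverage, or a derived level track). Steps are kept as given
#' (sorted, validated non-overlapping) and a run-length encoding per
#' chromosome is materialized for fast window arithmetic; bases not
#' covered by any step have signal 0.
#'
#' @param steps Data frame with chrom, start, end (0-based half-open),
#'   value columns.
#' @param library_size Total signal units; defaults to
#'   `sum(value * (end - start))`.
#' @param layout Optional genome layout; chromosomes are padded with
#'   zeros to their full length (needed for windows beyond the last step).
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(steps, library_size = NULL, layout = NULL) {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(steps)))
  validate_intervals(steps, what = "coverage step")
  if (any(steps$value < 0, na.rm = TRUE))
    stopf("coverage values must be >= 0")
  o <- order(steps$chrom, steps$start)
  steps <- steps[o, , drop = FALSE]
  rownames(steps) <- NULL
  for (ch in unique(steps$chrom)) {
    s <- steps[steps$chrom == ch, ]
    if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)]))
      stopf("overlapping coverage steps on %s", ch)
  }
  if (is.null(library_size))
    library_size <- sum(steps$value * (steps$end - steps$start))
  chroms <- if (!is.null(layout)) layout$chrom else unique(steps$chrom)
  rle <- setNames(lapply(chroms, function(ch) {
    s <- steps[steps$chrom == ch, ]
    len <- if (!is.null(layout)) {
      layout$length[layout$chrom == ch]
    } else if (nrow(s)) max(s$end) else 0
    build_rle(s, len)
  }), chroms)
  structure(list(steps = steps, rle = rle, library_size = library_size),
            class = "coverage_track")
}

# steps of one chromosome -> numeric Rle of the full chromosome length
build_rle <- function(s, len) {
  if (len == 0) return(S4Vectors::Rle(numeric(0)))
  if (!nrow(s)) return(S4Vectors::Rle(0, len))
  s <- s[s$start < len, , drop = FALSE]
  if (!nrow(s)) return(S4Vectors::Rle(0, len))
  s$end <- pmin(s$end, len)
  gap_before <- s$start - c(0, head(s$end, -1))
  # interleave (gap, step) runs, then the tail gap; drop zero-length runs
  vals <- as.vector(rbind(0, s$value))
  lens <- as.vector(rbind(gap_before, s$end - s$start))
  vals <- c(vals, 0); lens <- c(lens, len - max(s$end))
  keep <- lens > 0
  S4Vectors::Rle(vals[keep], lens[keep])
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track: %d steps on %d chromosome(s), library size %g\n",
              nrow(x$steps), length(x$rle), x$library_size))
  invisible(x)
}

#' Read a bedGraph coverage file
#'
#' Four tab- or space-separated columns: chrom, start, end, value
#' (0-based half-open). Steps may arrive unsorted; overlapping steps on
#' one chromosome are an error.
#'
#' @param path bedGraph path.
#' @param library_size Optional; computed from the data when missing.
#' @param layout Optional genome layout for zero-padding.
#' @return A `coverage_track`.
#' @export
read_bedgraph <- function(path, library_size = NULL, layout = NULL) {
  first <- readLines(path, n = 1)
  skip <- if (grepl("^(track|browser|#)", first)) 1L else 0L
  x <- data.table::fread(path, header = FALSE, skip = skip,
                         colClasses = list(character = 1))
  if (ncol(x) < 4) stopf("bedGraph needs 4 columns: %s", path)
  steps <- data.frame(chrom = x[[1]], start = as.numeric(x[[2]]),
                      end = as.numeric(x[[3]]), value = as.numeric(x[[4]]),
                      stringsAsFactors = FALSE)
  if (any(!complete.cases(steps)))
    stopf("malformed bedGraph line %d",
          which(!complete.cases(steps))[1] + skip)
  coverage_track(steps, library_size = library_size, layout = layout)
}

#' Write a coverage track as bedGraph
#'
#' Steps are written sorted with 6-decimal fixed-point values, mirroring
#' [read_bedgraph()].
#'
#' @param track A `coverage_track`.
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  s <- track$steps
  writeLines(sprintf("%s\t%d\t%d\t%.6f", s$chrom, as.integer(s$start),
                     as.integer(s$end), s$value), path)
  invisible(path)
}

track_chrom_rle <- function(track, chrom) {
  r <- track$rle[[chrom]]
  if (is.null(r)) S4Vectors::Rle(numeric(0)) else r
}

# Sums / means of the track signal over 0-based half-open windows on one
# chromosome. Windows are clipped to the chromosome; a window entirely
# outside yields NA (mean) / 0 (sum). NA signal values (level tracks) are
# ignored in means.
track_window_stat <- function(track, chrom, starts, ends,
                              stat = c("sum", "mean")) {
  stat <- match.arg(stat)
  r <- track_chrom_rle(track, chrom)
  len <- length(r)
  n <- length(starts)
  out <- rep(NA_real_, n)
  s <- pmax(starts, 0); e <- pmin(ends, len)
  ok <- which(s < e)
  if (!length(ok)) return(if (stat == "sum") rep(0, n) else out)
  v <- IRanges::Views(r, start = s[ok] + 1, end = e[ok])
  out[ok] <- if (stat == "sum") {
    IRanges::viewSums(v, na.rm = TRUE)
  } else IRanges::viewMeans(v, na.rm = TRUE)
  if (stat == "sum") out[is.na(out)] <- 0
  out[is.nan(out)] <- NA_real_
  out
}

# Signal sum over each interval of a table (vectorized across chromosomes).
# Intervals on chromosomes absent from the track count 0 with a warning.
track_region_sums <- function(track, regions) {
  out <- numeric(nrow(regions))
  missing <- setdiff(unique(regions$chrom), names(track$rle))
  if (length(missing))
    warnf("chromosome(s) absent from track count as 0: %s",
          paste(missing, collapse = ", "))
  for (ch in intersect(unique(regions$chrom), names(track$rle))) {
    i <- which(regions$chrom == ch)
    out[i] <- track_window_stat(track, ch, regions$start[i],
                                regions$end[i], "sum")
  }
  out
}
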