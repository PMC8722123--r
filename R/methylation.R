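#' Weighted methylation level of intervals
#'
#' For each interval, the weighted level `sum(n_meth) / sum(n_total)`
#' over sites of the requested context inside the interval with coverage
#' `n_total >= min_cov`. Intervals with no qualifying site get NA
#' (undefined, distinct from 0).
#'
#' @param calls Cytosine call table (see [read_cx_report()]).
#' @param intervals Interval table.
#' @param context One of `CG`, `CHG`, `CHH`.
#' @param min_cov Per-site coverage floor (0 keeps everything).
#' @return Numeric vector of levels in `[0, 1]`, one per interval.
#' @export
weighted_methylation_level <- function(calls, intervals, context,
                                       min_cov = 0) {
  context <- match.arg(context, CX_CONTEXTS)
  validate_intervals(intervals)
  s <- calls[calls$context == context & calls$n_total >= min_cov &
               calls$n_total > 0, , drop = FALSE]
  n <- nrow(intervals)
  if (!nrow(s) || !n) return(rep(NA_real_, n))
  sgr <- GenomicRanges::GRanges(s$chrom, IRanges::IRanges(s$pos + 1, s$pos + 1))
  hits <- GenomicRanges::findOverlaps(as_granges(intervals), sgr)
  out <- rep(NA_real_, n)
  if (!length(hits)) return(out)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  meth <- rowsum(s$n_meth[si], qi); tot <- rowsum(s$n_total[si], qi)
  out[as.integer(rownames(meth))] <- meth[, 1] / tot[, 1]
  out
}

#' Classify gene-body mCG levels as heavy / moderate / light
#'
#' Heavy: level >= 0.1; moderate: 0.01 <= level < 0.1; light:
#' level < 0.01. The three bands partition `[0, 1]`; undefined (NA)
#' levels are an error — exclude those genes first.
#'
#' @param level Numeric vector of defined weighted mCG levels.
#' @return Character vector: `heavy`, `moderate`, or `light`.
#' @export
classify_gene_mcg <- function(level) {
  if (anyNA(level))
    stopf("classify_gene_mcg: undefined level; exclude those genes first")
  if (any(level < 0 | level > 1)) stopf("levels must lie in [0, 1]")
  ifelse(level >= 0.1, "heavy", ifelse(level >= 0.01, "moderate", "light"))
}

#' Parameters for the differential methylation caller
#'
#' @param delta Minimum absolute mean level difference.
#' @param p_threshold Per-site significance threshold.
#' @param min_cg Minimum qualifying sites per region.
#' @param min_len Minimum region span in bp.
#' @param min_cov Per-site coverage floor in both samples.
#' @param max_gap Candidate sites within this many bp join one region.
#' @return A `dmr_params` list.
#' @export
dmr_params <- function(delta = 0.1, p_threshold = 0.05, min_cg = 4,
                       min_len = 100, min_cov = 5, max_gap = 300) {
  if (!(delta > 0 && delta <= 1)) stopf("need 0 < delta <= 1")
  if (min_cg < 1 || min_len < 1) stopf("min_cg and min_len must be >= 1")
  structure(list(delta = delta, p_threshold = p_threshold, min_cg = min_cg,
                 min_len = min_len, min_cov = min_cov, max_gap = max_gap),
            class = "dmr_params")
}

#' Call differentially methylated regions between two samples
#'
#' A region-threshold caller over shared cytosines: each site covered at
#' `min_cov` in both samples is tested by a two-sided Fisher exact test
#' on its (methylated, unmethylated) counts; candidate sites (p below
#' `p_threshold`, same-sign level difference with |diff| >= `delta`) are
#' joined into runs when consecutive candidates lie within `max_gap` bp,
#' and runs are reported as DMRs when they hold at least `min_cg` sites,
#' span at least `min_len` bp, and keep a region-wide weighted-level
#' difference of at least `delta`. Direction `hyper` means sample b is
#' higher than sample a.
#'
#' @param calls_a,calls_b Cytosine call tables on shared positions.
#' @param context One of `CG`, `CHG`, `CHH`.
#' @param params A [dmr_params()] list.
#' @return Data frame of DMRs: chrom, start, end, context, mean_level_a,
#'   mean_level_b, direction, n_sites.
#' @export
call_dmrs <- function(calls_a, calls_b, context, params = dmr_params()) {
  context <- match.arg(context, CX_CONTEXTS)
  a <- calls_a[calls_a$context == context, , drop = FALSE]
  b <- calls_b[calls_b$context == context, , drop = FALSE]
  m <- merge(
    data.frame(chrom = a$chrom, pos = a$pos, strand = a$strand,
               ma = a$n_meth, ta = a$n_total, stringsAsFactors = FALSE),
    data.frame(chrom = b$chrom, pos = b$pos, strand = b$strand,
               mb = b$n_meth, tb = b$n_total, stringsAsFactors = FALSE),
    by = c("chrom", "pos", "strand"))
  m <- m[m$ta >= params$min_cov & m$tb >= params$min_cov, , drop = FALSE]
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), context = character(),
                      mean_level_a = numeric(), mean_level_b = numeric(),
                      direction = character(), n_sites = integer(),
                      stringsAsFactors = FALSE)
  if (!nrow(m)) {
    warnf("call_dmrs: no shared %s sites at >= %dx coverage", context,
          params$min_cov)
    return(empty)
  }
  m <- m[order(m$chrom, m$pos), , drop = FALSE]
  m$p <- fisher_exact_p(m$ma, m$ta - m$ma, m$mb, m$tb - m$mb)
  m$diff <- m$mb / m$tb - m$ma / m$ta
  cand <- m[m$p < params$p_threshold & abs(m$diff) >= params$delta, ,
            drop = FALSE]
  if (!nrow(cand)) return(empty)
  sign_d <- sign(cand$diff)
  new_run <- c(TRUE, cand$chrom[-1] != cand$chrom[-nrow(cand)] |
                 sign_d[-1] != sign_d[-nrow(cand)] |
                 cand$pos[-1] - cand$pos[-nrow(cand)] > params$max_gap)
  run <- cumsum(new_run)
  regions <- lapply(split(seq_len(nrow(cand)), run), function(i) {
    r <- cand[i, , drop = FALSE]
    la <- sum(r$ma) / sum(r$ta); lb <- sum(r$mb) / sum(r$tb)
    data.frame(chrom = r$chrom[1], start = min(r$pos),
               end = max(r$pos) + 1, context = context,
               mean_level_a = la, mean_level_b = lb,
               direction = if (lb > la) "hyper" else "hypo",
               n_sites = nrow(r), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, regions)
  keep <- out$n_sites >= params$min_cg &
    (out$end - out$start) >= params$min_len &
    abs(out$mean_level_b - out$mean_level_a) >= params$delta
  rownames(out) <- NULL
  out[keep, , drop = FALSE]
}

#' Per-base methylation level track
#'
#' Builds a `coverage_track` whose value at each qualifying cytosine is
#' that site's methylation level and NA everywhere else, for use with
#' [metagene_matrix()] (bin means then average over cytosines only).
#'
#' @param calls Cytosine call table.
#' @param context One of `CG`, `CHG`, `CHH`.
#' @param layout Genome layout.
#' @param min_cov Per-site coverage floor.
#' @return A `coverage_track` with NA off-site values.
#' @export
methylation_level_track <- function(calls, context, layout, min_cov = 5) {
  context <- match.arg(context, CX_CONTEXTS)
  s <- calls[calls$context == context & calls$n_total >= min_cov &
               calls$n_total > 0, , drop = FALSE]
  # sites on both strands at the same position: pool the counts
  if (nrow(s)) {
    dt <- data.table::data.table(chrom = s$chrom, pos = s$pos,
                                 m = s$n_meth, t = s$n_total)
    dt <- dt[, list(m = sum(m), t = sum(t)), by = c("chrom", "pos")]
    s <- data.frame(chrom = dt$chrom, start = dt$pos, end = dt$pos + 1,
                    value = dt$m / dt$t, stringsAsFactors = FALSE)
  } else {
    s <- data.frame(chrom = character(), start = numeric(),
                    end = numeric(), value = numeric())
  }
  # off-site bases carry NA (not 0), so bin means average over cytosines only
  rle <- setNames(lapply(seq_len(nrow(layout)), function(ci) {
    ch <- layout$chrom[ci]; len <- layout$length[ci]
    ss <- s[s$chrom == ch & s$start < len, , drop = FALSE]
    if (!nrow(ss)) return(S4Vectors::Rle(NA_real_, len))
    ss <- ss[order(ss$start), , drop = FALSE]
    ss$end <- pmin(ss$end, len)
    gap_before <- ss$start - c(0, head(ss$end, -1))
    vals <- c(as.vector(rbind(NA_real_, ss$value)), NA_real_)
    lens <- c(as.vector(rbind(gap_before, ss$end - ss$start)),
              len - max(ss$end))
    keep <- lens > 0
    S4Vectors::Rle(vals[keep], lens[keep])
  }), layout$chrom)
  structure(list(steps = s, rle = rle, library_size = NA_real_),
            class = "coverage_track")
}
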