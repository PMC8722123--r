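#' Parameters for the windowed IP-vs-input peak caller
#'
#' @param window Sliding window size in bp.
#' @param step Window step in bp (0 < step <= window).
#' @param fdr Benjamini-Hochberg threshold on window p-values.
#' @param merge_gap Passing windows within this many bp are merged into
#'   one peak.
#' @param min_fold Minimum IP/expected fold enrichment for a window.
#' @param pseudocount Floor on the expected (input-derived) window count.
#' @param lambda_smooth_bp Span of the smoothed local input estimate; the
#'   expected window count is the maximum of the window-scale, smoothed
#'   and genome-wide input rates (stabilizes the expectation against
#'   input sampling noise, as local-lambda peak callers do).
#' @param signal_scale Divisor converting window coverage sums to
#'   approximate fragment counts before the Poisson test (use the mean
#'   fragment length for read-coverage tracks; 1 when the track already
#'   holds counts).
#' @return A `peak_call_params` list.
#' @export
peak_call_params <- function(window = 200, step = 50, fdr = 0.05,
                             merge_gap = 100, min_fold = 2.0,
                             pseudocount = 1.0, signal_scale = 1.0,
                             lambda_smooth_bp = 2000) {
  if (!(step > 0 && step <= window)) stopf("need 0 < step <= window")
  if (!(fdr > 0 && fdr < 1)) stopf("need 0 < fdr < 1")
  if (signal_scale <= 0) stopf("signal_scale must be > 0")
  structure(list(window = window, step = step, fdr = fdr,
                 merge_gap = merge_gap, min_fold = min_fold,
                 pseudocount = pseudocount, signal_scale = signal_scale,
                 lambda_smooth_bp = lambda_smooth_bp),
            class = "peak_call_params")
}

#' Call enrichment peaks from IP and input coverage
#'
#' A simplified IP-vs-input caller: sliding windows are scored by the
#' one-sided Poisson upper-tail p-value of the observed IP count against
#' an expectation taken from the input window count scaled by the
#' library-size ratio and floored at `pseudocount`. Benjamini-Hochberg
#' correction is applied over all windows genome-wide; windows passing
#' both the FDR cut and the fold gate are merged within `merge_gap` bp
#' into peaks. The peak score is the maximum -log10(p) of its member
#' windows (capped at 1000).
#'
#' @param ip,input `coverage_track` objects sharing a genome layout.
#' @param layout Genome layout.
#' @param params A [peak_call_params()] list.
#' @return Interval table of peaks (name = `peak_N`, score = -log10 p).
#' @export
call_enriched_windows <- function(ip, input, layout,
                                  params = peak_call_params()) {
  if (ip$library_size <= 0 || input$library_size <= 0)
    stopf("zero library size")
  lib_ratio <- ip$library_size / input$library_size
  win <- list()
  for (ci in seq_len(nrow(layout))) {
    ch <- layout$chrom[ci]; len <- layout$length[ci]
    if (len < params$window) next
    starts <- seq(0, len - params$window, by = params$step)
    ip_sum <- track_window_stat(ip, ch, starts, starts + params$window, "sum")
    in_sum <- track_window_stat(input, ch, starts, starts + params$window, "sum")
    # expected window signal: max of window-scale, smoothed local and
    # genome-wide input rates (local-lambda stabilization)
    sm <- params$lambda_smooth_bp
    sm_start <- starts + params$window / 2 - sm / 2
    in_smooth <- track_window_stat(input, ch, sm_start, sm_start + sm,
                                   "mean") * params$window
    in_smooth[is.na(in_smooth)] <- 0
    genome_rate <- input$library_size / sum(layout$length) * params$window
    in_exp <- pmax(in_sum, in_smooth, genome_rate)
    obs <- round(ip_sum / params$signal_scale)
    lambda <- pmax((in_exp / params$signal_scale) * lib_ratio,
                   params$pseudocount)
    win[[ch]] <- data.frame(chrom = ch, start = starts,
                            end = starts + params$window,
                            obs = obs, lambda = lambda,
                            stringsAsFactors = FALSE)
  }
  w <- do.call(rbind, win)
  if (is.null(w) || !nrow(w)) return(empty_intervals())
  w$p <- stats::ppois(w$obs - 1, w$lambda, lower.tail = FALSE)
  w$q <- stats::p.adjust(w$p, method = "BH")
  w$fold <- w$obs / w$lambda
  pass <- w$q < params$fdr & w$fold >= params$min_fold & w$obs > 0
  if (!any(pass)) return(empty_intervals())
  hits <- w[pass, , drop = FALSE]
  hits$score <- ifelse(hits$p <= 0, 1000, pmin(-log10(hits$p), 1000))
  peaks <- merge_intervals(
    genomic_intervals(hits$chrom, hits$start, hits$end, score = hits$score),
    gap = params$merge_gap)
  peaks$name <- sprintf("peak_%d", seq_len(nrow(peaks)))
  peaks
}

#' Replicate-consensus peaks
#'
#' Peaks from either replicate that overlap (>= 1 bp) a peak in the other
#' replicate are retained; retained peaks that overlap each other are
#' merged into union coordinates, so the output is disjoint. The score is
#' the maximum contributing score.
#'
#' @param rep1,rep2 Peak interval tables.
#' @return Disjoint consensus peak table.
#' @export
consensus_peaks <- function(rep1, rep2) {
  if (nrow(rep1) == 0 || nrow(rep2) == 0) return(empty_intervals())
  k1 <- rep1[count_interval_overlaps(rep1, rep2) > 0, , drop = FALSE]
  k2 <- rep2[count_interval_overlaps(rep2, rep1) > 0, , drop = FALSE]
  if (nrow(k1) + nrow(k2) == 0) return(empty_intervals())
  out <- merge_intervals(rbind(k1, k2), gap = 0)
  if (nrow(out)) out$name <- sprintf("peak_%d", seq_len(nrow(out)))
  out
}
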