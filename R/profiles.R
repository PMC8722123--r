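#' Metagene matrix of mean signal over scaled gene bodies with flanks
#'
#' Each gene body is split into `body_bins` equal-length bins (remainder
#' bp go to the last bin); each flank is split into fixed-width
#' `flank_bin` windows. Bin values are mean per-base signal; minus-strand
#' genes are reversed so columns always read upstream -> TSS -> body ->
#' TES -> downstream. Genes with a body shorter than `body_bins` are
#' skipped with a warning. Flank bins beyond the chromosome ends are NA
#' (partially out-of-range bins average over their in-range bases); NA
#' signal values (e.g. methylation level tracks) are ignored in bin means.
#'
#' @param track A `coverage_track`.
#' @param genes A `gene_models` object.
#' @param body_bins Number of gene-body bins.
#' @param flank Flank extent in bp on each side.
#' @param flank_bin Flank bin width in bp (flank must be a multiple).
#' @return List of class `metagene_matrix`: `values` (genes x bins),
#'   `gene_ids`, `bin_scheme`, `profile` (column means over genes),
#'   `tss_col`/`tes_col` (first/last body column indices).
#' @export
metagene_matrix <- function(track, genes, body_bins = 20, flank = 1000,
                            flank_bin = 50) {
  if (flank %% flank_bin != 0) stopf("flank must be a multiple of flank_bin")
  fbins <- flank / flank_bin
  g <- genes$genes
  short <- g$end - g$start < body_bins
  if (any(short))
    warnf("%d gene(s) with body shorter than %d bins skipped", sum(short),
          body_bins)
  g <- g[!short, , drop = FALSE]
  ncol_total <- 2 * fbins + body_bins
  values <- matrix(NA_real_, nrow(g), ncol_total)
  for (i in seq_len(nrow(g))) {
    L <- g$end[i] - g$start[i]
    w <- L %/% body_bins
    body_starts <- g$start[i] + w * (seq_len(body_bins) - 1)
    body_ends <- c(body_starts[-1], g$end[i])
    left_starts <- g$start[i] - flank + flank_bin * (seq_len(fbins) - 1)
    right_starts <- g$end[i] + flank_bin * (seq_len(fbins) - 1)
    starts <- c(left_starts, body_starts, right_starts)
    ends <- c(left_starts + flank_bin, body_ends, right_starts + flank_bin)
    row <- track_window_stat(track, g$chrom[i], starts, ends, "mean")
    if (g$strand[i] == "-") row <- rev(row)
    values[i, ] <- row
  }
  colnames(values) <- c(sprintf("up_%d", seq_len(fbins)),
                        sprintf("body_%d", seq_len(body_bins)),
                        sprintf("down_%d", seq_len(fbins)))
  rownames(values) <- g$gene_id
  structure(list(values = values, gene_ids = g$gene_id,
                 bin_scheme = list(flank = flank, flank_bin = flank_bin,
                                   body_bins = body_bins),
                 profile = colMeans(values, na.rm = TRUE),
                 tss_col = fbins + 1L, tes_col = fbins + body_bins),
            class = "metagene_matrix")
}

#' @export
print.metagene_matrix <- function(x, ...) {
  cat(sprintf("metagene_matrix: %d genes x %d bins (%d body bins, %d bp flanks)\n",
              nrow(x$values), ncol(x$values), x$bin_scheme$body_bins,
              x$bin_scheme$flank))
  invisible(x)
}

#' Write a metagene matrix and its mean profile as TSV
#' @param m A `metagene_matrix`.
#' @param matrix_path,profile_path Output paths (NULL to skip either).
#' @export
write_metagene_tsv <- function(m, matrix_path = NULL, profile_path = NULL) {
  if (!is.null(matrix_path)) {
    df <- data.frame(gene_id = m$gene_ids, m$values, check.names = FALSE)
    data.table::fwrite(df, matrix_path, sep = "\t")
  }
  if (!is.null(profile_path))
    data.table::fwrite(data.frame(bin = seq_along(m$profile),
                                  mean = m$profile),
                       profile_path, sep = "\t")
  invisible(NULL)
}

#' Classify genes by 4acC peak position relative to the TSS
#'
#' `tss_marked`: a peak overlaps the window of `window` bp centered on
#' the TSS (`[tss - floor(w/2), tss + ceiling(w/2))`). Otherwise
#' `nontss_marked` if a peak overlaps the gene body or promoter;
#' otherwise `unmarked`.
#'
#' @param peaks Peak interval table.
#' @param genes A `gene_models` object.
#' @param window TSS window size in bp.
#' @param promoter_bp Promoter extent for the non-TSS criterion.
#' @return Data frame: gene_id, label.
#' @export
tss_marked_classification <- function(peaks, genes, window = 250,
                                      promoter_bp = 1000) {
  g <- genes$genes
  ws <- pmax(g$tss - floor(window / 2), 0)
  we <- g$tss + ceiling(window / 2)
  tss_hit <- count_interval_overlaps(
    genomic_intervals(g$chrom, ws, we), peaks) > 0
  marked <- assign_peaks_to_genes(peaks, genes, promoter_bp,
                                  "body_or_promoter")$per_gene$marked
  label <- ifelse(tss_hit, "tss_marked",
                  ifelse(marked, "nontss_marked", "unmarked"))
  data.frame(gene_id = g$gene_id, label = label, stringsAsFactors = FALSE)
}

#' Chromosome-scale peak coverage profile
#'
#' Per fixed-size bin, the fraction of bin bp covered by the union of
#' the peaks (the final partial bin is normalized by its true length).
#'
#' @param peaks Peak interval table.
#' @param layout Genome layout.
#' @param bin Bin size in bp.
#' @return Data frame: chrom, bin_start, bin_end, level.
#' @export
chromosome_bin_profile <- function(peaks, layout, bin = 100000) {
  red <- merge_intervals(peaks)
  out <- lapply(seq_len(nrow(layout)), function(ci) {
    ch <- layout$chrom[ci]; len <- layout$length[ci]
    starts <- seq(0, len - 1, by = bin)
    ends <- pmin(starts + bin, len)
    p <- red[red$chrom == ch, , drop = FALSE]
    cov <- if (nrow(p)) {
      trk <- coverage_track(data.frame(chrom = ch, start = p$start,
                                       end = p$end, value = 1),
                            layout = layout[ci, , drop = FALSE])
      track_window_stat(trk, ch, starts, ends, "mean")
    } else rep(0, length(starts))
    data.frame(chrom = ch, bin_start = starts, bin_end = ends,
               level = cov, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
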