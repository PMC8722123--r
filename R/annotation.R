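PEAK_CATEGORIES <- c("promoter", "utr5", "exon", "intron", "utr3",
                     "intergenic")
# priority used for per-base labelling and tie-breaking: gene-body
# subfeatures beat the promoter, and within the body utr5 > exon
# (excluding UTRs) > intron > utr3
CATEGORY_PRIORITY <- c("utr5", "exon", "intron", "utr3", "promoter")

# Per-gene disjoint subfeature segments (0-based half-open data frames
# with gene_id), plus the strand-aware promoter clipped at chromosome
# bounds. "exon" excludes UTR bases; "intron" is the gene span minus
# exons.
gene_feature_segments <- function(genes, promoter_bp = 1000, layout = NULL) {
  g <- genes$genes
  per_gene_setdiff <- function(a, b) {
    # a, b: data frames with gene_id/chrom/start/end; a minus b per gene
    if (!nrow(a)) return(a)
    agr <- GenomicRanges::GRanges(paste0(a$gene_id, "\r", a$chrom),
                                  IRanges::IRanges(a$start + 1, a$end))
    bgr <- if (nrow(b)) {
      GenomicRanges::GRanges(paste0(b$gene_id, "\r", b$chrom),
                             IRanges::IRanges(b$start + 1, b$end))
    } else GenomicRanges::GRanges()
    d <- GenomicRanges::setdiff(agr, bgr)
    if (!length(d)) return(a[0, , drop = FALSE])
    key <- as.character(GenomicRanges::seqnames(d))
    parts <- do.call(rbind, strsplit(key, "\r", fixed = TRUE))
    data.frame(gene_id = parts[, 1], chrom = parts[, 2],
               start = IRanges::start(d) - 1, end = IRanges::end(d),
               stringsAsFactors = FALSE)
  }
  utr <- rbind(genes$utr5, genes$utr3)
  span <- data.frame(gene_id = g$gene_id, chrom = g$chrom,
                     start = g$start, end = g$end, stringsAsFactors = FALSE)
  exon_core <- per_gene_setdiff(genes$exons, utr)
  intron <- per_gene_setdiff(span, genes$exons)
  prom_start <- ifelse(g$strand == "+", g$start - promoter_bp, g$end)
  prom_end <- ifelse(g$strand == "+", g$start, g$end + promoter_bp)
  prom_start <- pmax(prom_start, 0)
  if (!is.null(layout)) {
    maxlen <- setNames(layout$length, layout$chrom)[g$chrom]
    prom_end <- pmin(prom_end, maxlen)
  }
  keep <- prom_start < prom_end
  promoter <- data.frame(gene_id = g$gene_id[keep], chrom = g$chrom[keep],
                         start = prom_start[keep], end = prom_end[keep],
                         stringsAsFactors = FALSE)
  list(utr5 = genes$utr5, exon = exon_core, intron = intron,
       utr3 = genes$utr3, promoter = promoter)
}

# Genome-wide disjoint prioritized segment sets: each base belongs to at
# most one category, chosen by CATEGORY_PRIORITY across all genes.
prioritized_segments <- function(segments) {
  taken <- GenomicRanges::GRanges()
  out <- list()
  for (cat in CATEGORY_PRIORITY) {
    s <- segments[[cat]]
    gr <- if (nrow(s)) {
      GenomicRanges::reduce(
        as_granges(genomic_intervals(s$chrom, s$start, s$end)))
    } else GenomicRanges::GRanges()
    gr <- GenomicRanges::setdiff(gr, taken)
    out[[cat]] <- gr
    taken <- GenomicRanges::union(taken, gr)
  }
  out
}

#' Assign each peak a single genomic category
#'
#' Categories are promoter (1 kb upstream of the TSS, strand-aware),
#' 5'UTR, exon (excluding UTRs), intron, 3'UTR, and intergenic. Each
#' peak gets the single category with maximal bp overlap, computed on
#' genome-wide per-base-prioritized segments: gene-body subfeatures beat
#' the promoter on ties, and within the body the tie order is
#' utr5 > exon > intron > utr3. A peak overlapping nothing is intergenic.
#' `gene_id` is the gene contributing the most bp of the winning
#' category (ties by gene order).
#'
#' @param peaks Peak interval table.
#' @param genes A `gene_models` object.
#' @param layout Optional genome layout (clips promoters).
#' @param promoter_bp Promoter extent upstream of the TSS.
#' @return The peak table with `category` and `gene_id` columns added.
#' @export
classify_peaks <- function(peaks, genes, layout = NULL, promoter_bp = 1000) {
  validate_intervals(peaks)
  segs <- gene_feature_segments(genes, promoter_bp, layout)
  prio <- prioritized_segments(segs)
  n <- nrow(peaks)
  ov <- matrix(0, n, length(CATEGORY_PRIORITY),
               dimnames = list(NULL, CATEGORY_PRIORITY))
  if (n) {
    pgr <- as_granges(peaks)
    for (cat in CATEGORY_PRIORITY) {
      gr <- prio[[cat]]
      if (!length(gr)) next
      hits <- GenomicRanges::findOverlaps(pgr, gr)
      if (!length(hits)) next
      w <- IRanges::width(GenomicRanges::pintersect(
        pgr[S4Vectors::queryHits(hits)], gr[S4Vectors::subjectHits(hits)]))
      agg <- rowsum(w, S4Vectors::queryHits(hits))
      ov[as.integer(rownames(agg)), cat] <- agg[, 1]
    }
  }
  # argmax with ties resolved by CATEGORY_PRIORITY column order
  best <- apply(ov, 1, function(r)
    if (all(r == 0)) NA_integer_ else which.max(r))
  category <- ifelse(is.na(best), "intergenic", CATEGORY_PRIORITY[best])
  gene_id <- rep(NA_character_, n)
  for (cat in CATEGORY_PRIORITY) {
    idx <- which(category == cat)
    if (!length(idx)) next
    s <- segs[[cat]]
    if (!nrow(s)) next
    sgr <- as_granges(genomic_intervals(s$chrom, s$start, s$end))
    hits <- GenomicRanges::findOverlaps(as_granges(peaks[idx, , drop = FALSE]),
                                        sgr)
    if (!length(hits)) next
    w <- IRanges::width(GenomicRanges::pintersect(
      as_granges(peaks[idx, , drop = FALSE])[S4Vectors::queryHits(hits)],
      sgr[S4Vectors::subjectHits(hits)]))
    dt <- data.table::data.table(q = S4Vectors::queryHits(hits),
                                 g = s$gene_id[S4Vectors::subjectHits(hits)],
                                 w = w)
    bygene <- dt[, list(w = sum(w)), by = c("q", "g")]
    data.table::setorderv(bygene, c("q", "w"), order = c(1L, -1L))
    top <- bygene[!duplicated(bygene$q), ]
    gene_id[idx[top$q]] <- top$g
  }
  out <- peaks
  out$category <- category
  out$gene_id <- gene_id
  out
}

#' Genomic category distribution of peaks with enrichment tests
#'
#' Counts and percentages of peaks per category (summing to 100), and a
#' per-category two-sided Fisher exact test of the observed in/out split
#' against the expected genomic composition. The expected composition is
#' the per-category bp fraction of the genome under the same per-base
#' priority rules; the expected column of the 2x2 table is the rounded
#' expected count among the same number of peaks.
#'
#' @param peaks Peak interval table (>= 1 peak).
#' @param genes A `gene_models` object.
#' @param layout Genome layout (defines total genome size).
#' @param promoter_bp Promoter extent in bp.
#' @return Data frame: category, count, pct, expected_frac, p.
#' @export
annotation_distribution <- function(peaks, genes, layout,
                                    promoter_bp = 1000) {
  if (nrow(peaks) == 0) stopf("annotation_distribution: empty peak list")
  ann <- classify_peaks(peaks, genes, layout, promoter_bp)
  counts <- table(factor(ann$category, levels = PEAK_CATEGORIES))
  comp <- genome_composition(genes, layout, promoter_bp)
  n <- nrow(peaks)
  p <- vapply(PEAK_CATEGORIES, function(cat) {
    obs_in <- as.integer(counts[[cat]])
    exp_in <- round(comp[[cat]] * n)
    fisher_p_2x2(matrix(c(obs_in, n - obs_in, exp_in, n - exp_in), 2,
                        byrow = TRUE))
  }, numeric(1))
  data.frame(category = PEAK_CATEGORIES,
             count = as.integer(counts),
             pct = 100 * as.integer(counts) / n,
             expected_frac = unname(comp[PEAK_CATEGORIES]),
             p = unname(p),
             stringsAsFactors = FALSE)
}

# per-category bp fraction of the genome under the priority rules
genome_composition <- function(genes, layout, promoter_bp = 1000) {
  prio <- prioritized_segments(
    gene_feature_segments(genes, promoter_bp, layout))
  total <- sum(layout$length)
  bp <- vapply(prio, function(gr) sum(as.numeric(IRanges::width(gr))),
               numeric(1))
  c(bp, intergenic = total - sum(bp)) / total
}

#' Per-gene peak assignment and marked-gene tallies
#'
#' A gene is 4acC-marked iff at least one peak overlaps its gene body
#' (or, in the default mode, its 1-kb promoter as well). Returns per-gene
#' body/promoter peak counts, the marked fraction per biotype, and the
#' {1, 2, >2} histogram of gene-body peak counts for protein-coding genes.
#'
#' @param peaks Peak interval table.
#' @param genes A `gene_models` object.
#' @param promoter_bp Promoter extent in bp.
#' @param mode `body_or_promoter` (default) or `body_only`.
#' @return List with `per_gene`, `biotype_summary`, and `body_histogram`.
#' @export
assign_peaks_to_genes <- function(peaks, genes, promoter_bp = 1000,
                                  mode = c("body_or_promoter", "body_only")) {
  mode <- match.arg(mode)
  g <- genes$genes
  body <- genomic_intervals(g$chrom, g$start, g$end)
  n_body <- count_interval_overlaps(body, peaks)
  prom_start <- pmax(ifelse(g$strand == "+", g$start - promoter_bp, g$end), 0)
  prom_end <- ifelse(g$strand == "+", g$start, g$end + promoter_bp)
  ok <- prom_start < prom_end
  n_prom <- integer(nrow(g))
  if (any(ok))
    n_prom[ok] <- count_interval_overlaps(
      genomic_intervals(g$chrom[ok], prom_start[ok], prom_end[ok]), peaks)
  marked <- if (mode == "body_only") n_body > 0 else n_body + n_prom > 0
  per_gene <- data.frame(gene_id = g$gene_id, biotype = g$biotype,
                         n_body_peaks = n_body, n_promoter_peaks = n_prom,
                         marked = marked, stringsAsFactors = FALSE)
  bio <- split(per_gene$marked, per_gene$biotype)
  biotype_summary <- data.frame(
    biotype = names(bio),
    n_genes = lengths(bio),
    n_marked = vapply(bio, sum, numeric(1)),
    pct_marked = 100 * vapply(bio, mean, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  pc <- per_gene$n_body_peaks[per_gene$biotype == "protein_coding" &
                                per_gene$n_body_peaks > 0]
  body_histogram <- c(`1` = sum(pc == 1), `2` = sum(pc == 2),
                      `>2` = sum(pc > 2))
  list(per_gene = per_gene, biotype_summary = biotype_summary,
       body_histogram = body_histogram)
}
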