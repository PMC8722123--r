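#' Per-gene joined table of expression and chromatin marks
#'
#' One row per gene: FPKM, 4acC status (tss_marked / nontss_marked /
#' unmarked), gene-body mCG class, and one logical column per histone
#' mark / DHS / TF set. "Marked by" a reference set means >= 1 bp overlap
#' of its intervals with the gene body (promoter inclusion is optional).
#'
#' @param genes A `gene_models` object.
#' @param expression Data frame gene_id/fpkm; genes absent get NA fpkm.
#' @param acetylation_labels Data frame gene_id/label from
#'   [tss_marked_classification()].
#' @param mcg_class Optional data frame gene_id/mcg_class
#'   (heavy/moderate/light/undefined).
#' @param reference_sets Optional named list of interval tables (histone
#'   marks, DHS, TFs); each contributes a logical column.
#' @param include_promoter Count promoter overlap as marked (default
#'   FALSE: gene-body only).
#' @param promoter_bp Promoter extent when included.
#' @return Data frame, one row per gene, class `marked_gene_table`.
#' @export
build_marked_gene_table <- function(genes, expression, acetylation_labels,
                                    mcg_class = NULL, reference_sets = NULL,
                                    include_promoter = FALSE,
                                    promoter_bp = 1000) {
  g <- genes$genes
  out <- data.frame(gene_id = g$gene_id, biotype = g$biotype,
                    fpkm = expression$fpkm[match(g$gene_id,
                                                 expression$gene_id)],
                    acetylation = acetylation_labels$label[
                      match(g$gene_id, acetylation_labels$gene_id)],
                    stringsAsFactors = FALSE)
  out$mcg_class <- if (!is.null(mcg_class)) {
    mcg_class$mcg_class[match(g$gene_id, mcg_class$gene_id)]
  } else NA_character_
  out$mcg_class[is.na(out$mcg_class)] <- "undefined"
  if (!is.null(reference_sets)) {
    body <- genomic_intervals(g$chrom, g$start, g$end)
    query <- body
    if (include_promoter) {
      s <- pmax(ifelse(g$strand == "+", g$start - promoter_bp, g$start), 0)
      e <- ifelse(g$strand == "+", g$end, g$end + promoter_bp)
      query <- genomic_intervals(g$chrom, s, e)
    }
    for (nm in names(reference_sets))
      out[[nm]] <- count_interval_overlaps(query,
                                           reference_sets[[nm]]) > 0
  }
  class(out) <- c("marked_gene_table", "data.frame")
  out
}

#' Expressed-gene / 4acC-marked-gene overlap
#'
#' The 2x2 table of genes by (expressed at `fpkm > fpkm_cut`) x
#' (4acC-marked, i.e. acetylation label other than `unmarked`), with the
#' two-sided Fisher exact p, the percentage of expressed genes that are
#' marked, and the percentage of marked genes that are expressed.
#'
#' @param table A `marked_gene_table`.
#' @param fpkm_cut Expression threshold (strict inequality).
#' @return List: table, p, pct_expressed_marked, pct_marked_expressed.
#' @export
expressed_gene_overlap <- function(table, fpkm_cut = 0) {
  if (nrow(table) == 0) stopf("empty gene table")
  t2 <- table[!is.na(table$fpkm), , drop = FALSE]
  expressed <- t2$fpkm > fpkm_cut
  marked <- t2$acetylation != "unmarked"
  tab <- base::table(factor(expressed, c(TRUE, FALSE)),
                     factor(marked, c(TRUE, FALSE)),
                     dnn = c("expressed", "marked"))
  list(table = tab, p = fisher_p_2x2(tab),
       pct_expressed_marked = 100 * mean(marked[expressed]),
       pct_marked_expressed = 100 * mean(expressed[marked]))
}

#' Expression quartile groups
#'
#' Genes ranked by FPKM descending (ties broken by gene_id for
#' determinism) and split into four equal-size groups; remainders are
#' distributed one each to the top groups, so n = 10 gives sizes
#' (3, 3, 2, 2). Q1 is the top 25%.
#'
#' @param expr Data frame gene_id/fpkm with >= 4 genes.
#' @return Data frame gene_id/quartile (`Q1`..`Q4`).
#' @export
expression_quartile_groups <- function(expr) {
  n <- nrow(expr)
  if (n < 4) stopf("need >= 4 genes for quartile grouping")
  o <- order(-expr$fpkm, expr$gene_id)
  sizes <- rep(n %/% 4, 4) + (seq_len(4) <= n %% 4)
  q <- rep(sprintf("Q%d", 1:4), times = sizes)
  out <- data.frame(gene_id = expr$gene_id[o], quartile = q,
                    stringsAsFactors = FALSE)
  out <- out[match(expr$gene_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Group-wise expression statistics with pairwise rank-sum tests
#'
#' For any grouping of the genes (a column name of the table or a factor
#' aligned with its rows), reports group sizes, medians and IQRs of
#' FPKM, and two-sided Mann-Whitney U p-values for the requested pairs
#' (all pairs by default). The exact null is used when the smaller group
#' has <= 8 tie-free observations; otherwise the normal approximation
#' with tie correction.
#'
#' @param table A `marked_gene_table` (or any data frame with `fpkm`).
#' @param grouping Column name or vector of group labels.
#' @param pairs Optional list of 2-vectors of group labels to compare.
#' @param value_col Value column (default `fpkm`).
#' @return List: `stats` (per-group) and `pairwise` (group_a, group_b, p).
#' @export
compare_marked_expression <- function(table, grouping, pairs = NULL,
                                      value_col = "fpkm") {
  values <- table[[value_col]]
  groups <- if (length(grouping) == 1 && is.character(grouping) &&
                  grouping %in% names(table)) {
    table[[grouping]]
  } else grouping
  if (length(groups) != nrow(table))
    stopf("grouping length does not match the table")
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- as.character(groups)[keep]
  levs <- unique(groups)
  split_vals <- split(values, factor(groups, levs))
  if (any(lengths(split_vals) == 0))
    stopf("empty group: %s", names(split_vals)[lengths(split_vals) == 0][1])
  stats_df <- data.frame(
    group = levs, n = lengths(split_vals),
    median = vapply(split_vals, median, numeric(1)),
    q25 = vapply(split_vals, quantile, numeric(1), probs = 0.25,
                 names = FALSE),
    q75 = vapply(split_vals, quantile, numeric(1), probs = 0.75,
                 names = FALSE),
    stringsAsFactors = FALSE, row.names = NULL)
  if (is.null(pairs)) {
    pairs <- if (length(levs) > 1) {
      utils::combn(levs, 2, simplify = FALSE)
    } else list()
  }
  pw <- lapply(pairs, function(pr) {
    if (!all(pr %in% levs)) stopf("empty group: %s", setdiff(pr, levs)[1])
    data.frame(group_a = pr[1], group_b = pr[2],
               p = mann_whitney_p(split_vals[[pr[1]]], split_vals[[pr[2]]]),
               stringsAsFactors = FALSE)
  })
  list(stats = stats_df,
       pairwise = if (length(pw)) do.call(rbind, pw) else
         data.frame(group_a = character(), group_b = character(),
                    p = numeric()))
}

#' Colocalization of peaks with named reference interval sets
#'
#' For each reference set, the percentage of peaks overlapping at least
#' one reference interval, the expected percentage from a seeded
#' length-matched random draw of the peaks, the two-sided Fisher exact
#' p on the 2x2 overlap table, and its BH adjustment across rows. Empty
#' reference sets report 0% with p = 1 and a warning.
#'
#' @param peaks Peak interval table (>= 1 peak).
#' @param reference_sets Named list of interval tables.
#' @param layout Genome layout.
#' @param seed Seed for the random draws (one draw per set).
#' @param min_overlap_bp Minimum shared bp to count an overlap.
#' @return Data frame: set, n_reference, observed_pct, expected_pct, p,
#'   q.
#' @export
colocalization_table <- function(peaks, reference_sets, layout, seed = 1,
                                 min_overlap_bp = 1) {
  if (nrow(peaks) == 0) stopf("empty peak list")
  n <- nrow(peaks)
  rows <- lapply(seq_along(reference_sets), function(k) {
    ref <- reference_sets[[k]]
    if (is.null(ref) || nrow(ref) == 0) {
      warnf("empty reference set '%s'", names(reference_sets)[k])
      return(data.frame(set = names(reference_sets)[k], n_reference = 0L,
                        observed_pct = 0, expected_pct = 0, p = 1,
                        stringsAsFactors = FALSE))
    }
    obs <- sum(count_interval_overlaps(peaks, ref, min_overlap_bp) > 0)
    rnd <- sample_matched_random_regions(peaks, layout, seed + k - 1)
    exp_hit <- sum(count_interval_overlaps(rnd, ref, min_overlap_bp) > 0)
    tab <- matrix(c(obs, n - obs, exp_hit, n - exp_hit), 2, byrow = TRUE)
    data.frame(set = names(reference_sets)[k], n_reference = nrow(ref),
               observed_pct = 100 * obs / n,
               expected_pct = 100 * exp_hit / n,
               p = fisher_p_2x2(tab), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}
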