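#' Region-by-sample signal matrix from coverage tracks
#'
#' Each cell is the total signal bp of one track within one (pre-merged,
#' disjoint) region. Library sizes travel as an attribute for
#' normalization downstream.
#'
#' @param regions Disjoint interval table (merge first with
#'   [merge_intervals()]).
#' @param tracks Named list of `coverage_track` objects.
#' @return Numeric matrix regions x samples with attribute
#'   `library_sizes`.
#' @export
build_count_matrix <- function(regions, tracks) {
  validate_intervals(regions)
  if (nrow(regions) > 1) {
    o <- order(regions$chrom, regions$start)
    r <- regions[o, ]
    if (any(r$chrom[-1] == r$chrom[-nrow(r)] &
              r$start[-1] < r$end[-nrow(r)]))
      stopf("regions overlap; merge them first with merge_intervals()")
  }
  stopifnot(length(tracks) >= 1)
  m <- vapply(tracks, function(t) track_region_sums(t, regions),
              numeric(nrow(regions)))
  if (nrow(regions) == 1) m <- matrix(m, nrow = 1,
                                      dimnames = list(NULL, names(tracks)))
  if (nrow(regions) == 0) m <- matrix(numeric(0), 0, length(tracks),
                                      dimnames = list(NULL, names(tracks)))
  rownames(m) <- sprintf("%s:%d-%d", regions$chrom,
                         as.integer(regions$start), as.integer(regions$end))
  attr(m, "library_sizes") <- vapply(tracks, function(t) t$library_size,
                                     numeric(1))
  m
}

#' Call differentially acetylated regions between two genotypes
#'
#' A simplified two-group test over a merged peak universe: per region,
#' counts (signal sums divided by `signal_scale`) are scaled to the mean
#' library size; `log2fc = log2((mean_mut + 0.5) / (mean_wt + 0.5))`; the
#' p-value is a two-sided binomial test of the pooled mutant count
#' against the pooled total under the library-size-ratio null, BH-adjusted
#' across regions. DARs are regions with `|log2fc| > lfc_cut` and
#' `q < fdr`. All-zero regions are excluded with a warning.
#'
#' @param counts Region x sample matrix from [build_count_matrix()].
#' @param groups Character vector (`wt`/`mut`) naming each column's group.
#' @param regions The interval table the matrix was built from.
#' @param lfc_cut Absolute log2 fold-change gate.
#' @param fdr BH threshold.
#' @param signal_scale Divisor converting signal sums to approximate
#'   fragment counts (mean fragment length for coverage tracks).
#' @return Data frame: region coordinates, mean_norm_wt, mean_norm_mut,
#'   log2fc, p, q, is_dar.
#' @export
call_dars <- function(counts, groups, regions, lfc_cut = 1, fdr = 0.05,
                      signal_scale = 1) {
  stopifnot(ncol(counts) == length(groups))
  groups <- match.arg(groups, c("wt", "mut"), several.ok = TRUE)
  if (!any(groups == "wt") || !any(groups == "mut"))
    stopf("need at least one sample per group")
  lib <- attr(counts, "library_sizes")
  cnt <- counts / signal_scale
  lib <- lib / signal_scale
  norm <- sweep(cnt, 2, mean(lib) / lib, `*`)
  mean_wt <- rowMeans(norm[, groups == "wt", drop = FALSE])
  mean_mut <- rowMeans(norm[, groups == "mut", drop = FALSE])
  keep <- rowSums(cnt) > 0
  if (any(!keep)) warnf("%d all-zero region(s) excluded", sum(!keep))
  pooled_mut <- round(rowSums(cnt[, groups == "mut", drop = FALSE]))
  pooled_wt <- round(rowSums(cnt[, groups == "wt", drop = FALSE]))
  p0 <- sum(lib[groups == "mut"]) / sum(lib)
  p <- rep(NA_real_, nrow(cnt))
  for (i in which(keep))
    p[i] <- stats::binom.test(pooled_mut[i], pooled_mut[i] + pooled_wt[i],
                              p = p0)$p.value
  q <- rep(NA_real_, nrow(cnt))
  q[keep] <- stats::p.adjust(p[keep], method = "BH")
  log2fc <- log2((mean_mut + 0.5) / (mean_wt + 0.5))
  out <- data.frame(chrom = regions$chrom, start = regions$start,
                    end = regions$end, mean_norm_wt = mean_wt,
                    mean_norm_mut = mean_mut, log2fc = log2fc, p = p, q = q,
                    stringsAsFactors = FALSE)
  out$is_dar <- keep & abs(out$log2fc) > lfc_cut & !is.na(out$q) &
    out$q < fdr
  out[keep, , drop = FALSE]
}

#' Genes overlapped by differentially acetylated regions
#'
#' A DAG is a gene whose body or strand-aware promoter overlaps at least
#' one DAR.
#'
#' @param dars DAR interval table.
#' @param genes A `gene_models` object.
#' @param promoter_bp Promoter extent in bp.
#' @return Character vector of gene ids.
#' @export
dag_genes <- function(dars, genes, promoter_bp = 1000) {
  g <- genes$genes
  body_hit <- count_interval_overlaps(
    genomic_intervals(g$chrom, g$start, g$end), dars) > 0
  ps <- pmax(ifelse(g$strand == "+", g$start - promoter_bp, g$end), 0)
  pe <- ifelse(g$strand == "+", g$start, g$end + promoter_bp)
  prom_hit <- rep(FALSE, nrow(g))
  ok <- ps < pe
  prom_hit[ok] <- count_interval_overlaps(
    genomic_intervals(g$chrom[ok], ps[ok], pe[ok]), dars) > 0
  g$gene_id[body_hit | prom_hit]
}

#' Identify uDAGs: differentially acetylated genes clear of DMRs
#'
#' Keeps the DAGs whose gene body and strand-aware 1-kb upstream region
#' overlap no DMR of any context.
#'
#' @param dags Character vector of DAG gene ids (subset of the models).
#' @param genes A `gene_models` object.
#' @param dmrs DMR table (any context; interval columns suffice).
#' @param upstream_bp Upstream extent checked along with the body.
#' @return Character vector of uDAG gene ids.
#' @export
identify_udags <- function(dags, genes, dmrs, upstream_bp = 1000) {
  g <- genes$genes
  unknown <- setdiff(dags, g$gene_id)
  if (length(unknown)) stopf("unknown gene_id: %s", unknown[1])
  gi <- match(dags, g$gene_id)
  s <- pmax(ifelse(g$strand[gi] == "+", g$start[gi] - upstream_bp,
                   g$start[gi]), 0)
  e <- ifelse(g$strand[gi] == "+", g$end[gi], g$end[gi] + upstream_bp)
  if (is.null(dmrs) || nrow(dmrs) == 0) return(dags)
  hit <- count_interval_overlaps(
    genomic_intervals(g$chrom[gi], s, e), dmrs) > 0
  dags[!hit]
}

#' DAR-versus-DMR overlap compared with a random-region null
#'
#' Observed: percentage of DARs overlapping at least one DMR. Null: the
#' same statistic over `n_null` seeded length-matched random draws.
#' Fisher exact test on the pooled 2x2 table
#' (overlapping / non-overlapping x DAR / random).
#'
#' @param dars DAR interval table (>= 1 region).
#' @param dmrs DMR interval table.
#' @param layout Genome layout.
#' @param n_null Number of matched random draws pooled into the null.
#' @param seed Seed for the random draws.
#' @return List: observed_pct, null_pct, p, table.
#' @export
dar_dmr_overlap_comparison <- function(dars, dmrs, layout, n_null = 1,
                                       seed = 1) {
  if (nrow(dars) == 0) stopf("empty DAR list")
  if (n_null < 1) stopf("n_null must be >= 1")
  obs_hit <- sum(count_interval_overlaps(dars, dmrs) > 0)
  rand_hit <- 0L; rand_n <- 0L
  for (k in seq_len(n_null)) {
    rnd <- sample_matched_random_regions(dars, layout, seed + k - 1)
    rand_hit <- rand_hit + sum(count_interval_overlaps(rnd, dmrs) > 0)
    rand_n <- rand_n + nrow(rnd)
  }
  tab <- matrix(c(obs_hit, nrow(dars) - obs_hit,
                  rand_hit, rand_n - rand_hit), 2, byrow = TRUE,
                dimnames = list(c("dar", "random"),
                                c("overlap", "no_overlap")))
  list(observed_pct = 100 * obs_hit / nrow(dars),
       null_pct = 100 * rand_hit / rand_n,
       p = fisher_p_2x2(tab), table = tab)
}

#' Methylation fold changes in DARs versus random regions
#'
#' Per DAR (and per length-matched random region), the fold change of
#' the weighted methylation level between two samples,
#' `(level_b + pseudo) / (level_a + pseudo)`; regions without qualifying
#' sites in either sample are dropped. The two fold-change distributions
#' are compared by a two-sided rank-sum test.
#'
#' @param dars DAR interval table.
#' @param calls_a,calls_b Cytosine call tables (e.g. WT and mutant).
#' @param context One of `CG`, `CHG`, `CHH`.
#' @param layout Genome layout.
#' @param seed Seed for the matched random draw.
#' @param pseudo Pseudo-level guarding near-zero ratios.
#' @param min_cov Per-site coverage floor.
#' @return List: dar_fc, random_fc, p.
#' @export
dar_methylation_fold_changes <- function(dars, calls_a, calls_b, context,
                                         layout, seed = 1, pseudo = 0.01,
                                         min_cov = 5) {
  rnd <- sample_matched_random_regions(dars, layout, seed)
  fc <- function(regions) {
    la <- weighted_methylation_level(calls_a, regions, context, min_cov)
    lb <- weighted_methylation_level(calls_b, regions, context, min_cov)
    v <- (lb + pseudo) / (la + pseudo)
    v[!is.na(v)]
  }
  dar_fc <- fc(dars); random_fc <- fc(rnd)
  p <- if (length(dar_fc) && length(random_fc))
    mann_whitney_p(dar_fc, random_fc) else NA_real_
  list(dar_fc = dar_fc, random_fc = random_fc, p = p)
}
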