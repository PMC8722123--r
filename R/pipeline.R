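SUMMARY_SCHEMA_VERSION <- "1.0"

#' Assemble a pipeline configuration
#'
#' Collects every input path and tunable threshold of the pipeline in
#' one validated list. `inputs` may name either pre-called peaks
#' (`peaks_bed`) or IP/input bedGraph pairs (two replicates each);
#' methylation, mutant and reference-set inputs are optional and their
#' stages are skipped when absent.
#'
#' @param inputs Named list of paths: `chrom_sizes`, `genes_gff`, and
#'   either `peaks_bed` or `ip_bedgraphs`/`input_bedgraphs` (character
#'   vectors of length 2); optional `expression_tsv`, `cx_report`,
#'   `mutant_cx_report`, `mutant_ip_bedgraphs`, `mutant_input_bedgraphs`,
#'   `reference_beds` (named character vector).
#' @param out_dir Output directory.
#' @param seed Seed for every stochastic step (random-region nulls).
#' @param peak_params A [peak_call_params()] list.
#' @param dmr_parameters A [dmr_params()] list.
#' @param thresholds Overrides for the scalar thresholds: promoter_bp
#'   (1000), tss_window (250), body_bins (20), flank (1000), flank_bin
#'   (50), chrom_bin (1e5), lfc_cut (1), fdr (0.05), fpkm_cut (0),
#'   min_cov (5), signal_scale (300), n_null (1).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(inputs, out_dir, seed = 1,
                            peak_params = peak_call_params(signal_scale = 300),
                            dmr_parameters = dmr_params(),
                            thresholds = list()) {
  th <- list(promoter_bp = 1000, tss_window = 250, body_bins = 20,
             flank = 1000, flank_bin = 50, chrom_bin = 1e5, lfc_cut = 1,
             fdr = 0.05, fpkm_cut = 0, min_cov = 5, signal_scale = 300,
             n_null = 1)
  unknown <- setdiff(names(thresholds), names(th))
  if (length(unknown)) stopf("unknown threshold: %s", unknown[1])
  th[names(thresholds)] <- thresholds
  if (any(vapply(th[c("promoter_bp", "tss_window", "body_bins", "flank",
                      "chrom_bin")], function(v) v <= 0, logical(1))))
    stopf("thresholds must be positive")
  need <- c("chrom_sizes", "genes_gff")
  miss <- setdiff(need, names(inputs))
  if (length(miss)) stopf("missing required input: %s", miss[1])
  if (is.null(inputs$peaks_bed) &&
        (is.null(inputs$ip_bedgraphs) || is.null(inputs$input_bedgraphs)))
    stopf("supply either peaks_bed or ip_bedgraphs + input_bedgraphs")
  structure(list(inputs = inputs, out_dir = out_dir, seed = seed,
                 peak_params = peak_params, dmr_parameters = dmr_parameters,
                 thresholds = th),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror [pipeline_config()] arguments: `inputs`,
#' `out_dir`, `seed`, `peak_params`, `dmr_params`, `thresholds`.
#'
#' @param path YAML file path.
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  pipeline_config(
    inputs = y$inputs, out_dir = y$out_dir, seed = y$seed %||% 1,
    peak_params = do.call(peak_call_params, y$peak_params %||% list()),
    dmr_parameters = do.call(dmr_params, y$dmr_params %||% list()),
    thresholds = y$thresholds %||% list())
}

call_consensus_from_tracks <- function(ip_paths, input_paths, layout,
                                       params) {
  reps <- lapply(seq_along(ip_paths), function(i) {
    ip <- read_bedgraph(ip_paths[i], layout = layout)
    inp <- read_bedgraph(input_paths[min(i, length(input_paths))],
                         layout = layout)
    call_enriched_windows(ip, inp, layout, params)
  })
  if (length(reps) == 1) return(reps[[1]])
  consensus_peaks(reps[[1]], reps[[2]])
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes, in order and as inputs permit: (1) peak calling with
#' replicate consensus (skipped when peaks are supplied), (2) genomic
#' category annotation with enrichment tests, (3) metagene/TSS/chromosome
#' profiles, (4) methylation levels and classes plus DMRs when a mutant
#' cytosine report is present, (5) DARs and uDAGs when mutant tracks are
#' present, and (6) integration statistics. Writes per-stage TSV/BED
#' outputs and a machine-readable `summary.json` under `out_dir`;
#' identical config + inputs give byte-identical outputs.
#'
#' @param config A `pipeline_config` (or YAML path).
#' @return The summary list, invisibly-written to `summary.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  inp <- config$inputs; th <- config$thresholds
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  op <- function(...) file.path(config$out_dir, paste0(...))
  summary <- list(schema_version = SUMMARY_SCHEMA_VERSION,
                  seed = config$seed)

  layout <- read_chrom_sizes(inp$chrom_sizes)
  genes <- read_gene_models(inp$genes_gff)

  # -- stage 1: peaks ------------------------------------------------
  ip_rep1 <- NULL
  if (!is.null(inp$peaks_bed)) {
    peaks <- read_bed(inp$peaks_bed)
    summary$peaks <- list(source = "supplied", n_peaks = nrow(peaks))
  } else {
    peaks <- call_consensus_from_tracks(inp$ip_bedgraphs,
                                        inp$input_bedgraphs, layout,
                                        config$peak_params)
    ip_rep1 <- read_bedgraph(inp$ip_bedgraphs[1], layout = layout)
    summary$peaks <- list(source = "called", n_peaks = nrow(peaks))
  }
  write_bed(peaks, op("consensus_peaks.bed"))

  # -- stage 2: annotation -------------------------------------------
  ann_dist <- annotation_distribution(peaks, genes, layout, th$promoter_bp)
  data.table::fwrite(ann_dist, op("annotation_distribution.tsv"),
                     sep = "\t")
  assign <- assign_peaks_to_genes(peaks, genes, th$promoter_bp)
  data.table::fwrite(assign$biotype_summary, op("biotype_summary.tsv"),
                     sep = "\t")
  pc <- assign$biotype_summary[assign$biotype_summary$biotype ==
                                 "protein_coding", ]
  summary$annotation <- list(
    pct = setNames(as.list(ann_dist$pct), ann_dist$category),
    pct_gene_body = sum(ann_dist$pct[ann_dist$category %in%
                                       c("utr5", "exon", "intron", "utr3")]),
    pct_protein_coding_marked = if (nrow(pc)) pc$pct_marked else NA,
    body_histogram = as.list(assign$body_histogram))

  # -- stage 3: profiles ---------------------------------------------
  tssc <- tss_marked_classification(peaks, genes, th$tss_window,
                                    th$promoter_bp)
  data.table::fwrite(tssc, op("tss_classification.tsv"), sep = "\t")
  chrprof <- chromosome_bin_profile(peaks, layout, th$chrom_bin)
  data.table::fwrite(chrprof, op("chromosome_profile.tsv"), sep = "\t")
  summary$profiles <- list(
    n_tss_marked = sum(tssc$label == "tss_marked"),
    n_nontss_marked = sum(tssc$label == "nontss_marked"),
    n_unmarked = sum(tssc$label == "unmarked"))
  if (!is.null(ip_rep1)) {
    mg <- metagene_matrix(ip_rep1, genes, th$body_bins, th$flank,
                          th$flank_bin)
    write_metagene_tsv(mg, op("metagene_matrix.tsv"),
                       op("metagene_profile.tsv"))
    summary$profiles$metagene_argmax_bin <-
      unname(which.max(mg$profile))
    summary$profiles$metagene_tss_bin <- mg$tss_col
  }

  # -- stage 4: methylation ------------------------------------------
  mcg_tab <- NULL
  dmrs_all <- NULL
  if (!is.null(inp$cx_report)) {
    calls <- read_cx_report(inp$cx_report)
    g <- genes$genes
    lvl <- weighted_methylation_level(
      calls, genomic_intervals(g$chrom, g$start, g$end), "CG", th$min_cov)
    def <- !is.na(lvl)
    mcg_tab <- data.frame(gene_id = g$gene_id, mcg_level = lvl,
                          mcg_class = "undefined",
                          stringsAsFactors = FALSE)
    mcg_tab$mcg_class[def] <- classify_gene_mcg(lvl[def])
    data.table::fwrite(mcg_tab, op("gene_mcg.tsv"), sep = "\t")
    summary$methylation <- list(
      n_genes_with_mcg = sum(def),
      mcg_class_counts = as.list(table(mcg_tab$mcg_class[def])))
    if (!is.null(inp$mutant_cx_report)) {
      mcalls <- read_cx_report(inp$mutant_cx_report)
      dmrs_all <- do.call(rbind, lapply(CX_CONTEXTS, function(ctx)
        call_dmrs(calls, mcalls, ctx, config$dmr_parameters)))
      data.table::fwrite(dmrs_all, op("dmrs.tsv"), sep = "\t")
      summary$methylation$n_dmrs <-
        as.list(table(factor(dmrs_all$context, CX_CONTEXTS)))
    }
  } else summary$methylation <- "skipped"

  # -- stage 5: differential -----------------------------------------
  if (!is.null(inp$mutant_ip_bedgraphs)) {
    mut_peaks <- call_consensus_from_tracks(inp$mutant_ip_bedgraphs,
                                            inp$mutant_input_bedgraphs,
                                            layout, config$peak_params)
    write_bed(mut_peaks, op("mutant_consensus_peaks.bed"))
    universe <- merge_intervals(rbind(peaks[, 1:6], mut_peaks[, 1:6]))
    tracks <- list(
      wt1 = read_bedgraph(inp$ip_bedgraphs[1], layout = layout),
      wt2 = read_bedgraph(inp$ip_bedgraphs[2], layout = layout),
      mut1 = read_bedgraph(inp$mutant_ip_bedgraphs[1], layout = layout),
      mut2 = read_bedgraph(inp$mutant_ip_bedgraphs[2], layout = layout))
    cm <- build_count_matrix(universe, tracks)
    dar_tab <- call_dars(cm, c("wt", "wt", "mut", "mut"), universe,
                         th$lfc_cut, th$fdr, th$signal_scale)
    data.table::fwrite(dar_tab, op("dars.tsv"), sep = "\t")
    dars <- genomic_intervals(dar_tab$chrom[dar_tab$is_dar],
                              dar_tab$start[dar_tab$is_dar],
                              dar_tab$end[dar_tab$is_dar])
    summary$differential <- list(
      n_mutant_peaks = nrow(mut_peaks), n_regions = nrow(dar_tab),
      n_dars = nrow(dars),
      pct_mutant_peaks_shared = if (nrow(mut_peaks)) {
        100 * mean(count_interval_overlaps(mut_peaks, peaks) > 0)
      } else NA)
    if (nrow(dars)) {
      dags <- dag_genes(dars, genes, th$promoter_bp)
      udags <- identify_udags(dags, genes, dmrs_all, th$promoter_bp)
      writeLines(udags, op("udags.tsv"))
      summary$differential$n_dags <- length(dags)
      summary$differential$n_udags <- length(udags)
      if (!is.null(dmrs_all) && nrow(dmrs_all)) {
        cmp <- dar_dmr_overlap_comparison(
          dars, genomic_intervals(dmrs_all$chrom, dmrs_all$start,
                                  dmrs_all$end),
          layout, th$n_null, config$seed)
        summary$differential$dar_dmr <- list(
          observed_pct = cmp$observed_pct, null_pct = cmp$null_pct,
          p = cmp$p)
      }
    }
  } else summary$differential <- "skipped"

  # -- stage 6: integration ------------------------------------------
  if (!is.null(inp$expression_tsv)) {
    expr <- read_expression_tsv(inp$expression_tsv)
    refs <- NULL
    if (!is.null(inp$reference_beds)) {
      paths <- inp$reference_beds
      nm <- names(paths)
      if (is.null(nm) || any(!nzchar(nm)))   # e.g. YAML drops vector names
        names(paths) <- sub("\\.bed$", "", basename(unlist(paths)),
                            ignore.case = TRUE)
      refs <- lapply(paths, read_bed)
    }
    tbl <- build_marked_gene_table(genes, expr, tssc,
                                   mcg_class = mcg_tab,
                                   reference_sets = refs)
    data.table::fwrite(tbl, op("marked_gene_table.tsv"), sep = "\t")
    ov <- expressed_gene_overlap(tbl, th$fpkm_cut)
    marked_grp <- ifelse(tbl$acetylation == "unmarked", "non4acC", "4acC")
    cmp <- compare_marked_expression(tbl, marked_grp,
                                     pairs = list(c("4acC", "non4acC")))
    summary$integration <- list(
      pct_expressed_marked = ov$pct_expressed_marked,
      pct_marked_expressed = ov$pct_marked_expressed,
      expressed_overlap_p = ov$p,
      marked_vs_unmarked_p = cmp$pairwise$p[1],
      median_fpkm = setNames(as.list(cmp$stats$median), cmp$stats$group))
    if (!is.null(refs) && length(refs)) {
      coloc <- colocalization_table(peaks, refs, layout, config$seed)
      data.table::fwrite(coloc, op("colocalization.tsv"), sep = "\t")
      summary$integration$colocalization_pct <-
        setNames(as.list(coloc$observed_pct), coloc$set)
    }
  } else summary$integration <- "skipped"

  jsonlite::write_json(summary, op("summary.json"), auto_unbox = TRUE,
                       digits = 10, pretty = TRUE, null = "null")
  invisible(summary)
}
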