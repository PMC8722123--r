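#!/usr/bin/env Rscript
# Stage 6: differential acetylation between wild type and the rdd mutant
# over the merged peak universe, uDAG derivation, and the DAR-vs-DMR
# overlap and methylation fold-change comparisons.

suppressMessages(library(acetylseq))
sim <- "results/simdata"
layout <- read_chrom_sizes(file.path(sim, "chrom.sizes"))
genes <- read_gene_models(file.path(sim, "genes.gff3"))
wt_peaks <- read_bed("results/wt_consensus_peaks.bed")
rdd_peaks <- read_bed("results/rdd_consensus_peaks.bed")

universe <- merge_intervals(rbind(wt_peaks, rdd_peaks))
tracks <- list(
  wt1 = read_bedgraph(file.path(sim, "wt_ip_rep1.bedgraph"), layout = layout),
  wt2 = read_bedgraph(file.path(sim, "wt_ip_rep2.bedgraph"), layout = layout),
  mut1 = read_bedgraph(file.path(sim, "rdd_ip_rep1.bedgraph"), layout = layout),
  mut2 = read_bedgraph(file.path(sim, "rdd_ip_rep2.bedgraph"), layout = layout))
cm <- build_count_matrix(universe, tracks)
dtab <- call_dars(cm, c("wt", "wt", "mut", "mut"), universe,
                  signal_scale = 300)
data.table::fwrite(dtab, "results/dars_rdd.tsv", sep = "\t")
dars <- genomic_intervals(dtab$chrom[dtab$is_dar], dtab$start[dtab$is_dar],
                          dtab$end[dtab$is_dar])
cat(sprintf("%d of %d merged regions are DARs (|log2FC| > 1, FDR < 0.05)\n",
            nrow(dars), nrow(dtab)))

wt_cx <- read_cx_report(file.path(sim, "wt_cx_report.txt"))
rdd_cx <- read_cx_report(file.path(sim, "rdd_cx_report.txt"))
dmrs <- do.call(rbind, lapply(c("CG", "CHG", "CHH"), function(ctx)
  call_dmrs(wt_cx, rdd_cx, ctx)))
dmr_iv <- genomic_intervals(dmrs$chrom, dmrs$start, dmrs$end)

if (nrow(dars)) {
  cmp <- dar_dmr_overlap_comparison(dars, dmr_iv, layout, n_null = 1,
                                    seed = 1)
  cat(sprintf("DAR-DMR overlap: %.1f%% observed vs %.1f%% in matched random regions (Fisher p = %.3g)\n",
              cmp$observed_pct, cmp$null_pct, cmp$p))
  fc <- dar_methylation_fold_changes(dars, wt_cx, rdd_cx, "CG", layout,
                                     seed = 1)
  cat(sprintf("mCG fold change in DARs: median %.2f vs %.2f in random regions (rank-sum p = %.3g)\n",
              median(fc$dar_fc), median(fc$random_fc), fc$p))
  dags <- dag_genes(dars, genes)
  udags <- identify_udags(dags, genes, dmrs)
  writeLines(udags, "results/udags_rdd.tsv")
  cat(sprintf("%d DAGs, of which %d are uDAGs (no DMR in body or 1-kb upstream)\n",
              length(dags), length(udags)))
}
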