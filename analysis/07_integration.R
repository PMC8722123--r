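#!/usr/bin/env Rscript
# Stage 7: combinatorial mark x expression statistics — expressed/marked
# overlap, expression quartiles, mCG-class x 4acC expression, histone
# colocalization, and combined-mark group comparisons.

suppressMessages(library(acetylseq))
sim <- "results/simdata"
layout <- read_chrom_sizes(file.path(sim, "chrom.sizes"))
genes <- read_gene_models(file.path(sim, "genes.gff3"))
peaks <- read_bed("results/wt_consensus_peaks.bed")
expr <- read_expression_tsv(file.path(sim, "expression.tsv"))
lab <- read.delim("results/tss_classification.tsv")
mcg <- read.delim("results/gene_mcg.tsv")

marks <- c("H3K4me2", "H3K4me3", "H3K36me3", "H3K9ac", "H3K14ac",
           "H3K9me2", "H3K9me3", "H3K27me3", "DHS",
           "TF_A", "TF_B", "TF_C", "TF_D")
refs <- setNames(lapply(marks, function(m)
  read_bed(file.path(sim, paste0(m, ".bed")))), marks)

tbl <- build_marked_gene_table(genes, expr, lab, mcg_class = mcg,
                               reference_sets = refs)
data.table::fwrite(tbl, "results/marked_gene_table.tsv", sep = "\t")

for (cut in c(0, 1)) {
  ov <- expressed_gene_overlap(tbl, fpkm_cut = cut)
  cat(sprintf("FPKM > %d: %.0f%% of expressed genes marked, %.0f%% of marked genes expressed (Fisher p = %.3g)\n",
              cut, ov$pct_expressed_marked, ov$pct_marked_expressed, ov$p))
}

q <- expression_quartile_groups(expr)
pct_marked <- tapply(tbl$acetylation != "unmarked",
                     q$quartile[match(tbl$gene_id, q$gene_id)], mean)
cat("fraction of genes 4acC-marked by expression quartile (Q1 = top):\n")
print(round(pct_marked, 2))

cmp <- compare_marked_expression(tbl, "acetylation")
data.table::fwrite(cmp$stats, "results/expression_by_acetylation.tsv",
                   sep = "\t")
cat("median FPKM by 4acC status:\n")
print(cmp$stats[, c("group", "n", "median")], row.names = FALSE)

# mCG class x 4acC combined groups
grp <- paste(ifelse(tbl$acetylation == "unmarked", "non4acC", "4acC"),
             tbl$mcg_class, sep = "_")
ok <- tbl$mcg_class != "undefined"
cmp_mcg <- compare_marked_expression(tbl[ok, ], grp[ok], pairs = list())
data.table::fwrite(cmp_mcg$stats, "results/expression_by_mcg_class.tsv",
                   sep = "\t")

# H3K27me3 x 4acC: both / 4acC / H3K27me3 / neither
a <- tbl$acetylation != "unmarked"; h <- tbl$H3K27me3
grp2 <- ifelse(a & h, "both", ifelse(a, "4acC",
                                     ifelse(h, "H3K27me3", "neither")))
cmp2 <- compare_marked_expression(tbl, grp2)
cat("median FPKM for 4acC x H3K27me3 groups:\n")
print(cmp2$stats[, c("group", "n", "median")], row.names = FALSE)

coloc <- colocalization_table(peaks, refs, layout, seed = 1)
data.table::fwrite(coloc, "results/colocalization.tsv", sep = "\t")
cat("peak colocalization (observed vs expected %):\n")
print(coloc[, c("set", "observed_pct", "expected_pct", "p")],
      row.names = FALSE)
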