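#!/usr/bin/env Rscript
# Stage 2: window-Poisson IP-vs-input peak calling per replicate, then
# replicate consensus, for the wild type and the rdd mutant.

suppressMessages(library(acetylseq))
sim <- "results/simdata"
layout <- read_chrom_sizes(file.path(sim, "chrom.sizes"))
prm <- peak_call_params(signal_scale = 300)   # 200-400 bp fragments

call_genotype <- function(prefix) {
  reps <- lapply(1:2, function(i) call_enriched_windows(
    read_bedgraph(file.path(sim, sprintf("%s_ip_rep%d.bedgraph", prefix, i)),
                  layout = layout),
    read_bedgraph(file.path(sim, sprintf("%s_input_rep%d.bedgraph", prefix, i)),
                  layout = layout),
    layout, prm))
  cons <- consensus_peaks(reps[[1]], reps[[2]])
  cat(sprintf("%s: %d / %d peaks per replicate, %d consensus peaks\n",
              prefix, nrow(reps[[1]]), nrow(reps[[2]]), nrow(cons)))
  write_bed(cons, file.path("results", sprintf("%s_consensus_peaks.bed",
                                               prefix)))
  cons
}
dir.create("results", showWarnings = FALSE)
wt_cons <- call_genotype("wt")
rdd_cons <- call_genotype("rdd")
cat(sprintf("%.1f%% of rdd consensus peaks overlap a wild-type peak\n",
            100 * mean(sapply(seq_len(nrow(rdd_cons)), function(i)
              any(overlap_bp(rdd_cons[i, ], wt_cons) > 0)))))
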