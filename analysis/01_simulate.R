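#!/usr/bin/env Rscript
# Stage 1: build the synthetic study system — a 5-Mb two-chromosome
# genome with 500 genes, wild-type 4acC IP/input coverage (2 replicates),
# a three-context bisulfite sample, histone/DHS/TF interval sets, and two
# methylation mutants (met1-like CG erasure, rdd-like regional
# hypermethylation with attenuated 4acC peaks). All later stages read
# from results/simdata.

suppressMessages(library(acetylseq))
seed <- 1
out <- "results/simdata"

cfg <- simulation_config(seed = seed)
gen <- generate_genome(cfg)
cat(sprintf("genome: %d chromosomes x %g bp, %d genes\n",
            nrow(gen$layout), gen$layout$length[1],
            nrow(gen$genes$genes)))

wt <- generate_epigenome(gen, cfg, out_dir = out)
cat(sprintf("wild type: %d genes carry a planted 4acC peak (%.0f%%), %d cytosine sites\n",
            sum(wt$truth$genes$has_peak),
            100 * mean(wt$truth$genes$has_peak), nrow(wt$calls)))

met1 <- generate_mutant_epigenome(gen, wt, cfg, "met1", out_dir = out)
rdd <- generate_mutant_epigenome(gen, wt, cfg, "rdd", out_dir = out)
cat(sprintf("mutants: met1 (CG erased), rdd (%d planted hyper regions, %d attenuated peaks)\n",
            nrow(rdd$truth$planted_dmrs), nrow(rdd$truth$planted_dars)))
cat("files written under", out, "\n")
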