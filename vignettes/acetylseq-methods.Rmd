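---
title: "Models and methods behind acetylseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind acetylseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis problem

N4-acetyldeoxycytosine (4acC) is a DNA modification detectable by
antibody enrichment of denatured, sonicated genomic DNA followed by
sequencing (IP-seq). In Arabidopsis it concentrates in euchromatin
around transcription start sites and tracks gene expression, in sharp
contrast to 5-methyldeoxycytosine (5mC), which accumulates in
pericentromeric heterochromatin. Interpreting a 4acC profile therefore
means joining several data types around a common gene table: IP and
input coverage, gene models, bisulfite cytosine reports in the CG, CHG
and CHH contexts, an expression table (FPKM), and interval sets for
histone marks, DNase I hypersensitive sites (DHS) and transcription
factor binding.

`acetylseq` implements that full analysis as composable functions, plus
a synthetic-epigenome generator with a ground-truth manifest so every
stage can be validated quantitatively without any external download.
The `analysis/` scripts in the repository run the stages in order over
the default synthetic study system.

# Coordinate conventions

All intervals inside the package are **0-based, half-open**
(BED-native). GFF3 (1-based inclusive) and CX-report positions are
converted once, at the file boundary. When a gene has several mRNAs the
representative transcript is the longest one, with ties broken by file
order; the TSS is the first transcribed base (`start` on `+`,
`end - 1` on `-`).

# Peak calling

The caller is a deliberately simple IP-versus-input scan, not a
reimplementation of a fragment-model caller. Sliding windows (200 bp,
step 50 bp, matched to 200–400 bp sonication fragments) are scored by a
one-sided Poisson upper tail:

* the observed count is the window's IP coverage sum divided by
  `signal_scale`. Coverage sums are not counts — each fragment
  contributes its full length in coverage units — so `signal_scale`
  should be the mean fragment length (300 by default in the pipeline
  configuration) to put the statistic on an approximate fragment-count
  scale. With `signal_scale = 1` the caller treats the track as raw
  counts.
* the expectation is the **maximum** of the window-scale, 2-kb-smoothed
  (`lambda_smooth_bp`) and genome-wide input rates, scaled by the
  IP/input library-size ratio and floored at `pseudocount`. Taking the
  maximum of nested local rates stabilizes the expectation against
  input sampling noise, the same device local-lambda callers use;
  without it, window-scale input fluctuations alone generate spurious
  two-fold windows and the caller is not quiet on label-permuted data.

Windows pass if they survive Benjamini–Hochberg control at FDR < 0.05
**and** show at least `min_fold = 2` enrichment; passing windows within
`merge_gap = 100` bp merge into peaks scored by the best member window
(−log10 p, capped at 1000). Only the FDR threshold is inherited from
the study design; window, step, fold and gap are this package's own
defaults. Replicate consensus retains peaks overlapping (≥ 1 bp) a peak
in the other replicate and merges retained peaks into union
coordinates, which is conservative for downstream overlap statistics.

Because fragments overlap windows coherently, the rescaled counts are
under-dispersed relative to Poisson, so the p-values are conservative;
the fold gate, not the p-value, is the effective specificity control at
high depth.

# Genomic annotation

Each peak receives exactly one category among promoter (1 kb upstream
of the TSS, strand-aware, clipped at chromosome ends), 5'UTR, exon
(excluding UTRs), intron, 3'UTR and intergenic. Assignment is by
maximal base-pair overlap computed on genome-wide *per-base-prioritized*
segments: where genes overlap, a base belongs to the highest-priority
feature covering it (utr5 > exon > intron > utr3 > promoter), and a
peak tied between gene body and promoter goes to the body. The same
per-base labeling yields the expected genomic composition for the
per-category Fisher tests, so observed and expected are measured with
identical rules. The test compares the observed in/out split against
the rounded expected count among the same number of peaks; under a
uniform null this construction is conservative (for rare categories the
table often collapses and p sticks at 1), which is the direction one
wants for enrichment claims.

# Profiles

Metagene matrices rescale each gene body to 20 equal bins (remainder
base pairs to the last bin) with 1-kb flanks in fixed 50-bp bins — 20
body bins and the flank extent follow the study design; the 50-bp flank
bin width is this package's choice. Bin values are mean per-base
signal; minus-strand rows are reversed so columns always read
upstream → TSS → body → TES → downstream. Bin means times bin lengths
exactly conserve the per-base signal sum, which the tests assert at
1e-9. Genes shorter than the bin count are skipped with a warning.
Methylation metagenes reuse the same machinery on a level track that is
NA everywhere except at qualifying cytosines, so bin means average over
cytosines only.

The chromosome-scale profile reports, per 100-kb bin, the fraction of
the bin covered by the merged peak set (the trailing partial bin is
normalized by its true length). Peak *coverage* rather than read
coverage is the default because it is insensitive to library size; the
read-coverage variant is a one-liner through the same window machinery.

The TSS classification labels a gene `tss_marked` when any peak
overlaps the 250-bp window centered on the TSS
(`[tss − 125, tss + 125)`), `nontss_marked` when peaks touch only the
body or promoter, and `unmarked` otherwise.

# Methylation statistics

The weighted methylation level of an interval is
`sum(n_meth) / sum(n_total)` over in-interval sites of one context with
coverage at least `min_cov` (5 by default, matching the study's ≥ 5×
site filter); an interval without qualifying sites is *undefined* (NA),
never 0. Gene-body mCG classes are heavy (≥ 0.1), moderate
(0.01–0.1) and light. The published class boundaries overlap at the
light/moderate edge ("≤ 0.1" for light); the only reading that yields
three disjoint classes is light < 0.01, which is what
`classify_gene_mcg()` implements.

`call_dmrs()` is a region-threshold caller standing in for a
beta-binomial package: per shared site (coverage ≥ 5 in both samples) a
two-sided Fisher exact test on the methylated/unmethylated counts;
candidate sites (p < 0.05, same-sign difference ≥ delta = 0.1) join
into runs when consecutive candidates lie within `max_gap = 300` bp;
runs become DMRs when they hold ≥ 4 sites, span ≥ 100 bp and keep a
region-wide weighted difference ≥ delta. Delta, the per-site threshold,
the site minimum and the length minimum are the study's parameters; the
300-bp join gap is this package's choice (roughly the scale over which
neighbouring cytosines share methylation state in plant genomes). The
per-site scan uses a vectorized hypergeometric implementation
(`fisher_exact_p()`), cross-checked in the tests against
`stats::fisher.test` and a direct binomial-coefficient enumeration over
every table with margins up to 30. No dispersion shrinkage or smoothing
is attempted: with that omission the caller is exact, symmetric
(swapping samples flips direction only) and silent on identical inputs.

# Differential acetylation

DARs are called over the merged WT+mutant peak universe. Region signal
sums are converted to approximate fragment counts (`signal_scale`),
scaled to the mean library size, and tested by a two-sided binomial
test of the pooled mutant count against the pooled total under the
library-size-ratio null, with BH control. The effect size is
`log2((mean_mut + 0.5) / (mean_wt + 0.5))`; a region is a DAR iff
|log2FC| > 1 and FDR < 0.05 — those two thresholds are the study's
contract, the pooled binomial with pseudocount 0.5 is the package's
stand-in for a negative-binomial model. With two replicates per group
and ~30× depth the binomial p is anticonservative in principle
(replicate variability is ignored) but the log2FC gate dominates in
practice; the synthetic-truth tests measure ≤ 5% false DARs.

A DAG is a gene whose body or promoter overlaps a DAR; a uDAG is a DAG
whose body *and* 1-kb upstream region overlap no DMR of any context.
Methylation fold changes over DARs use `(level_b + 0.01) /
(level_a + 0.01)`; the 0.01 pseudo-level guards near-zero euchromatic
levels and is exposed as an argument.

# Random-region nulls

Every observed-versus-chance comparison (DAR–DMR overlap, histone/DHS/
TF colocalization) uses the same null: one region per query with
identical length, chromosome drawn proportional to chromosome length
among chromosomes that can hold it, start uniform, overlaps allowed,
seeded. The null does not exclude the query's own positions and is not
GC- or feature-matched; both would shrink expected overlaps further and
are out of scope. Fisher tests on the resulting 2×2 tables are reported
per row with a BH-adjusted column alongside.

# The synthetic epigenome

The generator emulates the structural features the analysis is meant to
detect, each behind one `simulation_config()` field:

* **Genome**: two 2.5-Mb chromosomes, 500 non-overlapping genes with
  log-normal lengths (median 2 kb), 1–5 exons, terminal UTRs, Bernoulli
  strands, and the biotype mix of a compact plant genome.
* **Expression**: zero-inflated log-normal FPKM (20% silent genes).
* **Acetylation**: peaks of 400 bp planted near TSSs. One logistic
  slope, `expression_coupling`, drives *presence* (more expressed genes
  are more often marked), *placement* (more expressed marked genes are
  more often TSS-proximal, offset N(150, 100) bp downstream of the TSS;
  the rest sit in the gene body) and *height* (fold scales mildly with
  expression rank around the default 8-fold enrichment). Setting the
  slope to 0 severs all three links at once, which is what makes the
  null-behavior tests meaningful.
* **Sequencing**: Poisson-distributed 200–400-bp fragments at 30×
  background depth; IP adds fold-enriched fragments over planted peaks
  (fragment-length convolution arises naturally); input is background
  only; replicates are independent draws from the same truth. Coverage
  is emitted at 10-bp resolution to keep bedGraphs compact.
* **Methylation**: per-site mean levels by compartment (one centered
  pericentromeric block per chromosome with high mCG/mCHG and moderate
  mCHH; low euchromatic background; gene-body mCG classes sampled per
  gene), then beta-binomial site draws (precision 50, depth
  Poisson(30)). Methylation is planted *independent* of acetylation, so
  any mark × methylation association measured downstream is null by
  construction — a feature, used by the DAR–DMR tests.
* **Mutants**: `met1` resamples CG site means from Beta(0.5, 50)
  (near-complete erasure), leaving CHG/CHH untouched; `rdd` plants 20
  2-kb hypermethylated regions gaining +0.4 in all contexts, placed in
  euchromatin (inside the heterochromatin block the level ceiling
  leaves no room for the advertised gain, and demethylase-target
  regions are euchromatic in the real system). Both modes attenuate
  20% of the planted peaks 4-fold in the mutant IP, creating true DARs
  recorded in the manifest.

Every component runs on its own seed stream derived from the master
seed, so a configuration reproduces byte-identical files regardless of
which components are switched on.

What the generator does **not** model: sequence composition and
mappability, PCR duplicates, bisulfite conversion failure, overlapping
genes and alternative isoforms, chromatin-state autocorrelation beyond
the single heterochromatin block, and any causal coupling between
acetylation and methylation or histone marks beyond the configured
conditional probabilities. Passing tests therefore demonstrate that the
statistics recover planted structure at realistic depth and noise — not
that they are robust to alignment artifacts or covariate-driven
confounding in real data.

# Problem sizes and numerical choices

The test suite exercises: the full 5-Mb default system for end-to-end
checks; 10-seed sweeps at 5 Mb (50 planted peaks) for caller
sensitivity/FDR and at 1 Mb for DAR recovery; a 0.8-Mb system for DMR
recovery; 100 seeded 0.3-Mb label permutations for the caller null; 50
random ≤ 100-kb toy genomes against the per-base annotation oracle; and
the complete enumeration of 2×2 tables with margins ≤ 30 against the
closed-form hypergeometric sum (tolerance 1e-10). Metagene
conservation is asserted to 1e-9. Peak scores cap at 1000 where p
underflows. Ties: annotation ties follow the fixed priority order;
expression ranks break ties by gene id so every grouping is
deterministic; the Mann–Whitney wrapper uses the exact null when the
smaller group has ≤ 8 tie-free observations and the tie-corrected
normal approximation otherwise, returning p = 1 when all observations
are identical.

# Known limitations

The Poisson window test ignores fragment-level autocorrelation (its
p-values are conservative at depth, honest only at `signal_scale` ≈
fragment length); the DMR caller ignores biological dispersion beyond
what the per-site counts carry; the DAR test pools replicates; the
random-region null is length-matched only. These are the places where a
production analysis of real data would substitute a fragment-model
caller, a beta-binomial DMR model and a count model with dispersion —
the surrounding interfaces are designed so each can be swapped without
touching the statistics that consume their output.
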