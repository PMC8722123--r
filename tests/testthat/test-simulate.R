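small_cfg <- function(seed = 1, ...) {
  simulation_config(seed = seed, n_chroms = 2, chrom_length = 3e5,
                    n_genes = 40,
                    site_density_per_kb = c(CG = 6, CHG = 4, CHH = 8),
                    rdd_n_hyper = 8, ...)
}

test_that("generated genomes place non-overlapping genes deterministically", {
  cfg <- small_cfg(3)
  gen <- generate_genome(cfg)
  g <- gen$genes$genes
  expect_equal(nrow(g), 40)
  for (ch in unique(g$chrom)) {
    s <- g[g$chrom == ch, ]; s <- s[order(s$start), ]
    expect_true(all(s$start[-1] >= s$end[-nrow(s)]))
  }
  # exons inside spans; UTRs inside exon space
  expect_true(all(gen$genes$exons$start >= g$start[
    match(gen$genes$exons$gene_id, g$gene_id)]))
  expect_true(all(gen$genes$exons$end <= g$end[
    match(gen$genes$exons$gene_id, g$gene_id)]))
  # deterministic
  expect_identical(generate_genome(cfg), gen)
  # degenerate and impossible configurations
  empty <- generate_genome(small_cfg(1, n_genes = 0))
  expect_equal(nrow(empty$genes$genes), 0)
  expect_error(generate_genome(simulation_config(
    1, n_chroms = 1, chrom_length = 1e4, n_genes = 50)), "density")
})

test_that("same config gives byte-identical emitted files", {
  cfg <- small_cfg(5)
  gen <- generate_genome(cfg)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  wt1 <- generate_epigenome(gen, cfg, out_dir = d1)
  mut1 <- generate_mutant_epigenome(gen, wt1, cfg, "rdd", out_dir = d1)
  wt2 <- generate_epigenome(gen, cfg, out_dir = d2)
  mut2 <- generate_mutant_epigenome(gen, wt2, cfg, "rdd", out_dir = d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  for (f in f1)
    expect_identical(readBin(file.path(d1, f), "raw", 1e8),
                     readBin(file.path(d2, f), "raw", 1e8))
})

test_that("emitted files round-trip through the readers without warnings", {
  cfg <- small_cfg(6)
  gen <- generate_genome(cfg)
  d <- withr::local_tempdir()
  wt <- generate_epigenome(gen, cfg, out_dir = d)
  expect_no_warning({
    layout <- read_chrom_sizes(file.path(d, "chrom.sizes"))
    gm <- read_gene_models(file.path(d, "genes.gff3"))
    expr <- read_expression_tsv(file.path(d, "expression.tsv"))
    trk <- read_bedgraph(file.path(d, "wt_ip_rep1.bedgraph"),
                         layout = layout)
    calls <- read_cx_report(file.path(d, "wt_cx_report.txt"))
    bed <- read_bed(file.path(d, "H3K4me3.bed"))
  })
  expect_equal(layout, gen$layout)
  expect_equal(gm$genes$start, gen$genes$genes$start)
  expect_equal(expr$fpkm, round(wt$expression$fpkm, 6))
  expect_equal(trk$steps, wt$tracks$ip$rep1$steps)
  expect_equal(nrow(calls), nrow(wt$calls))
})

test_that("planted peaks sit near their TSSs and couple to expression", {
  cfg <- simulation_config(seed = 8)
  gen <- generate_genome(cfg)
  wt <- generate_epigenome(gen, cfg, tracks = FALSE, methylation = FALSE,
                           marks = FALSE)
  t <- wt$truth$genes
  g <- gen$genes$genes
  prox <- t$has_peak & t$tss_proximal
  center <- (t$peak_start + t$peak_end) / 2
  d <- abs(center - g$tss)
  expect_true(all(d[prox] <= cfg$peak_offset_mean +
                    4 * cfg$peak_offset_sd + cfg$peak_width))
  # distal peaks stay within their gene body (plus half a peak width)
  distal <- t$has_peak & !t$tss_proximal
  expect_true(all(t$peak_start[distal] >= g$start[distal] -
                    cfg$peak_width &
                    t$peak_end[distal] <= g$end[distal] + cfg$peak_width))
  # expression coupling: planted-peak indicator correlates with FPKM
  expect_gt(cor(rank(t$fpkm), t$has_peak, method = "spearman"), 0.3)
  # slope 0 severs the link
  cfg0 <- simulation_config(seed = 8, expression_coupling = 0)
  wt0 <- generate_epigenome(generate_genome(cfg0), cfg0, tracks = FALSE,
                            methylation = FALSE, marks = FALSE)
  expect_lt(abs(cor(rank(wt0$truth$genes$fpkm),
                    wt0$truth$genes$has_peak)), 0.15)
})

test_that("unit enrichment fold leaves the caller almost nothing to find", {
  cfg <- small_cfg(9, enrichment_fold = 1)
  gen <- generate_genome(cfg)
  wt <- generate_epigenome(gen, cfg, methylation = FALSE, marks = FALSE)
  pk <- call_enriched_windows(wt$tracks$ip$rep1, wt$tracks$input$rep1,
                              gen$layout,
                              peak_call_params(signal_scale = 300))
  expect_lte(nrow(pk), 2)
})

test_that("met1 erases CG genome-wide; rdd hyper regions carry all contexts", {
  cfg <- small_cfg(10)
  gen <- generate_genome(cfg)
  wt <- generate_epigenome(gen, cfg, tracks = FALSE, marks = FALSE)
  m1 <- generate_mutant_epigenome(gen, wt, cfg, "met1", tracks = FALSE)
  lvl <- function(calls, ctx) {
    s <- calls[calls$context == ctx & calls$n_total >= 5, ]
    sum(s$n_meth) / sum(s$n_total)
  }
  expect_lt(lvl(m1$calls, "CG"), 0.02)
  expect_lt(abs(lvl(m1$calls, "CHG") - lvl(wt$calls, "CHG")), 0.02)
  rdd <- generate_mutant_epigenome(gen, wt, cfg, "rdd", tracks = FALSE)
  pd <- rdd$truth$planted_dmrs
  expect_equal(nrow(pd), 8)
  for (ctx in c("CG", "CHG", "CHH")) {
    wt_l <- weighted_methylation_level(wt$calls, pd, ctx, 5)
    mu_l <- weighted_methylation_level(rdd$calls, pd, ctx, 5)
    expect_gt(median(mu_l - wt_l, na.rm = TRUE), 0.2)
  }
  expect_error(generate_mutant_epigenome(gen, wt, cfg, "xyz"))
})
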