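const_track <- function(value, len = 1000, chrom = "chr1") {
  coverage_track(data.frame(chrom = chrom, start = 0, end = len,
                            value = value),
                 layout = genome_layout(chrom, len))
}

test_that("count matrix sums signal per region and validates disjointness", {
  regions <- genomic_intervals("chr1", c(0, 500), c(100, 700))
  cm <- build_count_matrix(regions, list(s1 = const_track(2)))
  expect_equal(unname(cm[, 1]), c(200, 400))
  expect_equal(unname(attr(cm, "library_sizes")), 2000)
  expect_equal(nrow(build_count_matrix(
    genomic_intervals(character(), numeric(), numeric()),
    list(s1 = const_track(2)))), 0)
  expect_error(build_count_matrix(
    genomic_intervals("chr1", c(0, 50), c(100, 150)),
    list(s1 = const_track(2))), "merge_intervals")
  expect_warning(cm2 <- build_count_matrix(
    genomic_intervals("chr9", 0, 100), list(s1 = const_track(2))),
    "absent")
  expect_equal(unname(cm2[, 1]), 0)
})

two_group_matrix <- function(wt, mut, lib = c(1000, 1000, 1000, 1000)) {
  m <- cbind(wt1 = wt, wt2 = wt, mut1 = mut, mut2 = mut)
  attr(m, "library_sizes") <- lib
  m
}

test_that("DAR calls follow the pooled binomial test and the log2FC gate", {
  regions <- genomic_intervals("chr1", c(0, 1000), c(500, 1500))
  # identical groups: zero DARs
  d0 <- call_dars(two_group_matrix(c(100, 200), c(100, 200)),
                  c("wt", "wt", "mut", "mut"), regions)
  expect_false(any(d0$is_dar))
  # 200 (wt) vs 20 (mut) pooled with equal libraries
  m <- cbind(wt1 = c(100, 50), mut1 = c(10, 50))
  attr(m, "library_sizes") <- c(1000, 1000)
  d <- call_dars(m, c("wt", "mut"), regions)
  expect_equal(d$log2fc[1], log2(10.5 / 100.5))
  ref_p <- stats::binom.test(10, 110, 0.5)$p.value
  expect_equal(d$p[1], ref_p)
  expect_true(d$is_dar[1])
  expect_false(d$is_dar[2])
  # a 1.5-fold change never becomes a DAR (log2fc ~ 0.58 < 1)
  m15 <- cbind(wt1 = 300, mut1 = 200)
  attr(m15, "library_sizes") <- c(1000, 1000)
  d15 <- call_dars(m15, c("wt", "mut"),
                   genomic_intervals("chr1", 0, 500))
  expect_false(any(d15$is_dar))
  expect_lt(abs(abs(d15$log2fc) - log2(1.5)), 0.01)
  # all-zero regions are excluded with a warning
  expect_warning(dz <- call_dars(two_group_matrix(c(0, 50), c(0, 60)),
                                 c("wt", "wt", "mut", "mut"), regions),
                 "all-zero")
  expect_equal(nrow(dz), 1)
})

test_that("swapping group labels negates log2fc and preserves q", {
  set.seed(41)
  n <- 40
  regions <- genomic_intervals("chr1", seq(0, by = 1000, length.out = n),
                               seq(500, by = 1000, length.out = n))
  m <- cbind(a1 = rpois(n, 100), a2 = rpois(n, 100),
             b1 = rpois(n, 150), b2 = rpois(n, 60))
  attr(m, "library_sizes") <- c(900, 1100, 1000, 950)
  fwd <- call_dars(m, c("wt", "wt", "mut", "mut"), regions)
  rev <- call_dars(m, c("mut", "mut", "wt", "wt"), regions)
  expect_equal(rev$log2fc, -fwd$log2fc)
  expect_equal(rev$q, fwd$q)
})

test_that("uDAGs exclude DAGs with DMRs in body or 1-kb upstream", {
  genes <- rbind(one_gene("gA", start = 5000, end = 7000),
                 one_gene("gB", strand = "-", start = 10000, end = 12000),
                 one_gene("gC", start = 20000, end = 22000))
  gm <- make_gm(genes)
  dmr_body <- genomic_intervals("chr1", 5100, 5200)
  dmr_upstream_b <- genomic_intervals("chr1", 12100, 12300)  # gB upstream (-)
  dags <- c("gA", "gB", "gC")
  expect_equal(identify_udags(dags, gm, rbind(dmr_body, dmr_upstream_b)),
               "gC")
  expect_equal(identify_udags(dags, gm, dmr_body), c("gB", "gC"))
  expect_equal(identify_udags(dags, gm, NULL), dags)
  expect_error(identify_udags("nope", gm, dmr_body), "unknown gene_id")
  # DAG definition: body or promoter overlap with a DAR
  expect_equal(dag_genes(genomic_intervals("chr1", 4200, 4300), gm), "gA")
  expect_equal(dag_genes(genomic_intervals("chr1", 12500, 12600), gm), "gB")
})

test_that("DAR/DMR overlap comparison against matched random regions", {
  layout <- genome_layout("chr1", 1e6)
  dars <- genomic_intervals("chr1", seq(0, by = 50000, length.out = 10),
                            seq(500, by = 50000, length.out = 10))
  # every DAR inside a DMR, random regions nearly never overlapping
  cmp <- dar_dmr_overlap_comparison(dars, dars, layout, n_null = 1,
                                    seed = 3)
  expect_equal(cmp$observed_pct, 100)
  ref <- stats::fisher.test(cmp$table)$p.value
  expect_equal(cmp$p, ref)
  expect_lt(cmp$p, 0.01)
  # no DMRs at all
  cmp0 <- dar_dmr_overlap_comparison(
    dars, genomic_intervals(character(), numeric(), numeric()), layout,
    seed = 3)
  expect_equal(cmp0$observed_pct, 0)
  expect_equal(cmp0$null_pct, 0)
  expect_equal(cmp0$p, 1)
  expect_error(dar_dmr_overlap_comparison(
    genomic_intervals(character(), numeric(), numeric()), dars, layout),
    "empty")
})

test_that("methylation fold changes in DARs match random regions under
          independence", {
  layout <- genome_layout("chr1", 2e5)
  set.seed(51)
  pos <- sort(sample.int(2e5, 4000))
  calls_a <- mk_calls(pos, rbinom(4000, 30, 0.3), 30)
  calls_b <- mk_calls(pos, rbinom(4000, 30, 0.3), 30)
  st <- seq(0, by = 10000, length.out = 15)
  dars <- genomic_intervals("chr1", st, st + 2000)
  ps <- vapply(1:10, function(s)
    dar_methylation_fold_changes(dars, calls_a, calls_b, "CG", layout,
                                 seed = s)$p, numeric(1))
  expect_gt(median(ps), 0.05)
  expect_gt(max(ps), 0.2)
})
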