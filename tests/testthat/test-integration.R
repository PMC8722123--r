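simple_table <- function(fpkm, acet, ...) {
  n <- length(fpkm)
  out <- data.frame(gene_id = sprintf("g%03d", seq_len(n)),
                    biotype = "protein_coding", fpkm = fpkm,
                    acetylation = acet, mcg_class = "undefined",
                    stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) out[[nm]] <- extra[[nm]]
  class(out) <- c("marked_gene_table", "data.frame")
  out
}

test_that("expressed/marked overlap reports the 2x2 and both percentages", {
  # all genes marked and expressed: off-diagonals zero, p = 1
  t1 <- simple_table(rep(5, 10), rep("tss_marked", 10))
  ov <- expressed_gene_overlap(t1)
  expect_equal(ov$p, 1)
  expect_equal(unname(ov$table[1, ]), c(10, 0))
  expect_equal(ov$pct_expressed_marked, 100)
  expect_equal(ov$pct_marked_expressed, 100)
  # 2x2 = (30,10,10,30) equals the closed-form hypergeometric sum
  t2 <- simple_table(c(rep(1, 40), rep(0, 40)),
                     c(rep("tss_marked", 30), rep("unmarked", 10),
                       rep("tss_marked", 10), rep("unmarked", 30)))
  ov2 <- expressed_gene_overlap(t2)
  expect_equal(unname(as.vector(ov2$table)), c(30, 10, 10, 30))
  expect_equal(ov2$p, fisher_oracle_p(30, 10, 10, 30), tolerance = 1e-12)
  expect_error(expressed_gene_overlap(t1[0, ]), "empty")
})

test_that("independent marks give uniform-ish overlap p-values", {
  ps <- vapply(1:20, function(seed) {
    set.seed(seed)
    tab <- simple_table(ifelse(runif(2000) < 0.7, 1, 0),
                        ifelse(runif(2000) < 0.4, "tss_marked", "unmarked"))
    expressed_gene_overlap(tab)$p
  }, numeric(1))
  expect_gte(median(ps), 0.25)
  expect_lte(median(ps), 0.75)
})

test_that("expression quartiles split by rank with deterministic ties", {
  e8 <- data.frame(gene_id = sprintf("g%d", 1:8), fpkm = 8:1)
  q8 <- expression_quartile_groups(e8)
  expect_equal(q8$quartile, rep(c("Q1", "Q2", "Q3", "Q4"), each = 2))
  # n = 10: group sizes (3,3,2,2) from the top
  e10 <- data.frame(gene_id = sprintf("g%02d", 1:10), fpkm = 10:1)
  q10 <- expression_quartile_groups(e10)
  expect_equal(unname(table(q10$quartile)[c("Q1", "Q2", "Q3", "Q4")]),
               c(3, 3, 2, 2), ignore_attr = TRUE)
  # all equal: deterministic grouping by gene_id order
  eq <- data.frame(gene_id = sprintf("g%d", c(3, 1, 4, 2)), fpkm = 1)
  qq <- expression_quartile_groups(eq)
  expect_equal(qq$quartile[order(qq$gene_id)], c("Q1", "Q2", "Q3", "Q4"))
  expect_equal(expression_quartile_groups(eq), qq)  # reproducible
  expect_error(expression_quartile_groups(e8[1:3, ]), ">= 4")
})

test_that("grouped expression comparisons report medians and rank-sum p", {
  tab <- simple_table(c(1, 2, 3, 10, 11, 12),
                      rep(c("nontss_marked", "tss_marked"), each = 3))
  cmp <- compare_marked_expression(tab, "acetylation")
  expect_equal(sort(cmp$stats$median), c(2, 11))
  expect_equal(cmp$pairwise$p, 0.1)
  # identical groups -> p = 1 under the tie-corrected approximation
  tid <- simple_table(rep(4, 10), rep(c("a", "b"), 5))
  expect_equal(compare_marked_expression(tid, "acetylation")$pairwise$p, 1)
  expect_error(compare_marked_expression(tab, "acetylation",
                                         pairs = list(c("tss_marked",
                                                        "absent"))),
               "empty group")
  # arbitrary grouping vector, e.g. 4acC x histone combination labels
  grp <- c("both", "both", "4acC", "4acC", "neither", "neither")
  cmp2 <- compare_marked_expression(tab, grp,
                                    pairs = list(c("both", "neither")))
  expect_equal(nrow(cmp2$pairwise), 1)
  expect_equal(cmp2$stats$n, c(2, 2, 2))
})

test_that("colocalization percentages and Fisher tests behave at the edges", {
  layout <- genome_layout("chr1", 1e6)
  st <- seq(0, by = 50000, length.out = 20)
  peaks <- genomic_intervals("chr1", st, st + 400)
  whole <- genomic_intervals("chr1", 0, 1e6)
  tab <- colocalization_table(peaks, list(all = whole), layout, seed = 2)
  expect_equal(tab$observed_pct, 100)
  expect_equal(tab$expected_pct, 100)
  expect_equal(tab$p, 1)
  # reference equal to the sparse peak set: observed 100%, expected ~ 0
  tab2 <- colocalization_table(peaks, list(self = peaks), layout, seed = 2)
  expect_equal(tab2$observed_pct, 100)
  expect_lt(tab2$expected_pct, 30)
  expect_lt(tab2$p, 1e-4)
  # disjoint reference
  far <- genomic_intervals("chr1", st + 10000, st + 10400)
  tab3 <- colocalization_table(peaks, list(far = far), layout, seed = 2)
  expect_equal(tab3$observed_pct, 0)
  expect_warning(tab4 <- colocalization_table(
    peaks, list(none = genomic_intervals(character(), numeric(),
                                         numeric())), layout, seed = 2),
    "empty reference")
  expect_equal(tab4$p, 1)
  expect_true(all(tab2$observed_pct >= 0 & tab2$observed_pct <= 100))
  expect_error(colocalization_table(peaks[0, ], list(all = whole), layout),
               "empty peak")
})

test_that("marked-gene tables join expression, labels, classes and marks", {
  genes <- rbind(one_gene("gA", start = 1000, end = 3000),
                 one_gene("gB", start = 10000, end = 12000))
  gm <- make_gm(genes)
  expr <- data.frame(gene_id = c("gA", "gB"), fpkm = c(5, 0))
  lab <- data.frame(gene_id = c("gA", "gB"),
                    label = c("tss_marked", "unmarked"))
  refs <- list(H3K4me3 = genomic_intervals("chr1", 1500, 1600),
               H3K27me3 = genomic_intervals("chr1", 50000, 50100))
  tab <- build_marked_gene_table(gm, expr, lab, reference_sets = refs)
  expect_equal(tab$H3K4me3, c(TRUE, FALSE))
  expect_equal(tab$H3K27me3, c(FALSE, FALSE))
  expect_equal(tab$acetylation, c("tss_marked", "unmarked"))
  expect_equal(tab$mcg_class, c("undefined", "undefined"))
  # a mark upstream of the body counts only when promoters are included
  refs2 <- list(mk = genomic_intervals("chr1", 400, 600))
  expect_false(build_marked_gene_table(gm, expr, lab,
                                       reference_sets = refs2)$mk[1])
  expect_true(build_marked_gene_table(gm, expr, lab,
                                      reference_sets = refs2,
                                      include_promoter = TRUE)$mk[1])
})
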