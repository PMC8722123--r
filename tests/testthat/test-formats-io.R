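test_that("read_bed maps BED3/BED6 fields and reports malformed lines", {
  f <- withr::local_tempfile()
  writeLines(c("chr1\t100\t200",
               "chr1\t100\t200\tpk1\t7.5\t+"), f)
  x <- read_bed(f)
  expect_equal(x$chrom, c("chr1", "chr1"))
  expect_equal(x$start, c(100, 100))
  expect_equal(x$end, c(200, 200))
  expect_equal(x$name, c(NA, "pk1"))
  expect_equal(x$score, c(NA, 7.5))
  expect_equal(x$strand, c(".", "+"))

  writeLines("chr1\t200\t100", f)
  expect_error(read_bed(f), "start >= end at line 1")
  writeLines(c("chr1\t10\t20", "chr1\tx\t100"), f)
  expect_error(read_bed(f), "non-integer coordinates at line 2")
})

test_that("BED round-trips field-for-field through write_bed", {
  set.seed(7)
  s <- sort(sample.int(1e6, 20))
  x <- genomic_intervals("chr1", s, s + sample.int(500, 20),
                         name = sprintf("pk%d", 1:20),
                         score = round(runif(20, 0, 50), 4),
                         strand = sample(c("+", "-", "."), 20, TRUE))
  f <- withr::local_tempfile()
  write_bed(x, f)
  expect_equal(read_bed(f), x)
})

gff_lines <- function(...) c("##gff-version 3", ...)

test_that("GFF3 gene models convert coordinates and pick the longest mRNA", {
  f <- withr::local_tempfile()
  writeLines(gff_lines(
    "chr1\tsrc\tgene\t1001\t2000\t.\t+\t.\tID=gA",
    "chr1\tsrc\tmRNA\t1001\t2000\t.\t+\t.\tID=gA.1;Parent=gA",
    "chr1\tsrc\texon\t1001\t2000\t.\t+\t.\tParent=gA.1",
    "chr1\tsrc\tgene\t3001\t4000\t.\t-\t.\tID=gB",
    "chr1\tsrc\tmRNA\t3001\t4000\t.\t-\t.\tID=gB.1;Parent=gB",
    "chr1\tsrc\texon\t3001\t4000\t.\t-\t.\tParent=gB.1"), f)
  gm <- read_gene_models(f)
  expect_equal(gm$genes$start, c(1000, 3000))
  expect_equal(gm$genes$end, c(2000, 4000))
  expect_equal(gm$genes$tss, c(1000, 3999))
  expect_equal(gm$genes$tes, c(1999, 3000))
  expect_equal(gm$genes$biotype, c("protein_coding", "protein_coding"))

  # two transcripts: exons of the longest mRNA; span tie -> first in file
  writeLines(gff_lines(
    "chr1\tsrc\tgene\t1001\t5000\t.\t+\t.\tID=gC",
    "chr1\tsrc\tmRNA\t1001\t3000\t.\t+\t.\tID=gC.1;Parent=gC",
    "chr1\tsrc\texon\t1001\t3000\t.\t+\t.\tParent=gC.1",
    "chr1\tsrc\tmRNA\t1001\t5000\t.\t+\t.\tID=gC.2;Parent=gC",
    "chr1\tsrc\texon\t1001\t2000\t.\t+\t.\tParent=gC.2",
    "chr1\tsrc\texon\t4001\t5000\t.\t+\t.\tParent=gC.2"), f)
  gm <- read_gene_models(f)
  expect_equal(nrow(gm$exons), 2)          # gC.2 is longer
  expect_equal(gm$exons$start, c(1000, 4000))

  writeLines(gff_lines(
    "chr1\tsrc\tgene\t1001\t5000\t.\t+\t.\tID=gD",
    "chr1\tsrc\tmRNA\t1001\t5000\t.\t+\t.\tID=gD.1;Parent=gD",
    "chr1\tsrc\tmRNA\t1001\t5000\t.\t+\t.\tID=gD.2;Parent=gD",
    "chr1\tsrc\texon\t1001\t5000\t.\t+\t.\tParent=gD.1",
    "chr1\tsrc\texon\t1001\t1500\t.\t+\t.\tParent=gD.2"), f)
  gm <- read_gene_models(f)
  expect_equal(gm$exons$end, 5000)         # tie -> gD.1 (first in file)
})

test_that("GFF3 parsing enforces the hierarchy and strand contract", {
  f <- withr::local_tempfile()
  writeLines(gff_lines(
    "chr1\tsrc\tgene\t1001\t2000\t.\t+\t.\tID=gA",
    "chr1\tsrc\tmRNA\t1001\t2500\t.\t+\t.\tID=gA.1;Parent=gA"), f)
  expect_error(read_gene_models(f), "outside its parent")
  writeLines(gff_lines(
    "chr1\tsrc\tgene\t1001\t2000\t.\t?\t.\tID=gA"), f)
  expect_error(read_gene_models(f), "unknown strand")
  writeLines(gff_lines(
    "chr1\tsrc\tgene\t1001\t2000\t.\t+\t.\tID=gA;gene_biotype=lncRNA_weird"),
    f)
  expect_warning(gm <- read_gene_models(f), "other_ncrna")
  expect_equal(gm$genes$biotype, "other_ncrna")
})

test_that("GFF coordinate conversion is its own inverse on random intervals", {
  set.seed(42)
  n <- 1000
  s <- sample.int(1e6, n)
  genes <- data.frame(gene_id = sprintf("g%04d", 1:n), chrom = "chr1",
                      strand = sample(c("+", "-"), n, TRUE),
                      start = s, end = s + sample.int(5000, n) + 10,
                      stringsAsFactors = FALSE)
  gm <- make_gm(genes)
  f <- withr::local_tempfile()
  write_gff3(gm, f)
  back <- read_gene_models(f)
  o <- match(gm$genes$gene_id, back$genes$gene_id)
  expect_equal(back$genes$start[o], gm$genes$start)
  expect_equal(back$genes$end[o], gm$genes$end)
  expect_equal(back$genes$tss[o], gm$genes$tss)
})

test_that("CX report positions, totals and contexts are normalized", {
  f <- withr::local_tempfile()
  writeLines(c("chr1\t101\t+\t3\t7\tCG\tCGA",
               "chr1\t50\t-\t0\t0\tCHH\tCTT"), f)
  x <- read_cx_report(f)
  expect_equal(x$pos, c(100, 49))
  expect_equal(x$n_meth, c(3, 0))
  expect_equal(x$n_total, c(10, 0))        # zero-coverage site kept
  expect_equal(x$context, c("CG", "CHH"))

  writeLines("chr1\t101\t+\t3\t7\tCXG\tCXG", f)
  expect_error(read_cx_report(f), "unknown context")
  writeLines("chr1\t101\t+\t-3\t7\tCG\tCGA", f)
  expect_error(read_cx_report(f), "negative")
  # round trip
  calls <- data.frame(chrom = "chr1", pos = c(10, 20), strand = c("+", "-"),
                      context = c("CG", "CHG"), n_meth = c(2, 5),
                      n_total = c(9, 5), stringsAsFactors = FALSE)
  write_cx_report(calls, f)
  expect_equal(read_cx_report(f), calls)
})

test_that("bedGraph reading computes the brute-force library size", {
  f <- withr::local_tempfile()
  writeLines("chr1\t0\t100\t2.0", f)
  tr <- read_bedgraph(f)
  expect_equal(tr$library_size, 200)
  expect_equal(nrow(tr$steps), 1)
  # brute-force per-base sum on a random toy track
  set.seed(3)
  starts <- seq(0, 900, by = 100)
  keep <- sample(c(TRUE, FALSE), 10, TRUE)
  steps <- data.frame(chrom = "chr1", start = starts[keep],
                      end = starts[keep] + sample.int(100, sum(keep)),
                      value = round(runif(sum(keep), 0, 5), 3))
  writeLines(sprintf("chr1\t%d\t%d\t%s", steps$start, steps$end,
                     steps$value), f)
  tr <- read_bedgraph(f)
  expect_equal(tr$library_size,
               sum(oracle_base_vector(steps, "chr1", 1000)))
})

test_that("bedGraph abutting equal steps are preserved; overlaps error", {
  f <- withr::local_tempfile()
  writeLines(c("chr1\t0\t100\t1.5", "chr1\t100\t200\t1.5"), f)
  tr <- read_bedgraph(f)
  expect_equal(nrow(tr$steps), 2)          # no merging
  writeLines(c("chr1\t0\t100\t1.0", "chr1\t50\t150\t2.0"), f)
  expect_error(read_bedgraph(f), "overlapping coverage")
  # write/read round trip preserves steps and values
  writeLines(c("chr2\t10\t30\t0.25", "chr2\t40\t50\t3"), f)
  tr <- read_bedgraph(f)
  f2 <- withr::local_tempfile()
  write_bedgraph(tr, f2)
  expect_equal(read_bedgraph(f2)$steps, tr$steps)
})

test_that("expression tables demand the gene_id/fpkm header", {
  f <- withr::local_tempfile()
  writeLines(c("gene_id\tfpkm", "g1\t2.5", "g2\t0"), f)
  x <- read_expression_tsv(f)
  expect_equal(x$fpkm, c(2.5, 0))
  writeLines(c("id\tvalue", "g1\t2.5"), f)
  expect_error(read_expression_tsv(f), "gene_id")
  writeLines(c("gene_id\tfpkm", "g1\t-2"), f)
  expect_error(read_expression_tsv(f), "non-negative")
})
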