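test_that("metagene bins reproduce per-base means, strand-aware", {
  layout <- genome_layout("chr1", 2e4)
  flat <- coverage_track(data.frame(chrom = "chr1", start = 0, end = 2e4,
                                    value = 1), layout = layout)
  gm <- make_gm(one_gene(start = 5000, end = 7000))
  m <- metagene_matrix(flat, gm)
  expect_true(all(m$values == 1))
  expect_true(all(m$profile == 1))
  expect_equal(ncol(m$values), 60)
  # coverage 1 on the first 1000 bp of a 2-kb + gene: body bins 1-10 = 1
  half <- coverage_track(data.frame(chrom = "chr1", start = 5000,
                                    end = 6000, value = 1),
                         layout = layout)
  m <- metagene_matrix(half, gm)
  body <- m$values[1, m$tss_col:m$tes_col]
  expect_equal(unname(body), c(rep(1, 10), rep(0, 10)))
  # same gene on -: coverage on its transcriptional 5' half mirrors exactly
  gm_minus <- make_gm(one_gene(strand = "-", start = 5000, end = 7000))
  half_minus <- coverage_track(data.frame(chrom = "chr1", start = 6000,
                                          end = 7000, value = 1),
                               layout = layout)
  m2 <- metagene_matrix(half_minus, gm_minus)
  expect_equal(m2$values[1, ], m$values[1, ])
})

test_that("bin sums conserve the per-base signal and mirror under strand flip", {
  set.seed(21)
  layout <- genome_layout("chr1", 3e4)
  starts <- seq(0, 3e4 - 10, by = 10)
  steps <- data.frame(chrom = "chr1", start = starts, end = starts + 10,
                      value = rpois(length(starts), 4))
  trk <- coverage_track(steps, layout = layout)
  base <- oracle_base_vector(steps, "chr1", 3e4)
  for (strand in c("+", "-")) {
    g <- one_gene(strand = strand, start = 8000, end = 8000 + 2117)
    m <- metagene_matrix(trk, make_gm(g))
    body <- m$values[1, m$tss_col:m$tes_col]
    if (strand == "-") body <- rev(body)
    L <- 2117; w <- L %/% 20
    lens <- c(rep(w, 19), L - 19 * w)
    expect_equal(sum(body * lens), sum(base[8001:(8000 + L)]),
                 tolerance = 1e-9)
  }
  # mirroring the coverage across the gene midpoint equals a strand flip
  g <- one_gene(start = 10000, end = 12000)
  mirror_steps <- steps
  lo <- 10000 - 1000; hi <- 12000 + 1000   # mirror within gene +/- flank
  keep <- steps$start >= lo & steps$end <= hi
  ms <- steps[keep, ]
  new_start <- lo + (hi - ms$end)
  mirror_steps[keep, "start"] <- new_start
  mirror_steps[keep, "end"] <- new_start + 10
  mirror_trk <- coverage_track(mirror_steps[keep, ], layout = layout)
  m_fwd <- metagene_matrix(coverage_track(steps[keep, ], layout = layout),
                           make_gm(g))
  m_rev <- metagene_matrix(mirror_trk, make_gm(one_gene(strand = "-",
                                                        start = 10000,
                                                        end = 12000)))
  expect_equal(m_rev$values[1, ], m_fwd$values[1, ], tolerance = 1e-12)
})

test_that("short gene bodies are skipped with a warning", {
  layout <- genome_layout("chr1", 1e4)
  trk <- coverage_track(data.frame(chrom = "chr1", start = 0, end = 1e4,
                                   value = 1), layout = layout)
  gm <- make_gm(rbind(one_gene("tiny", start = 100, end = 110),
                      one_gene("ok", start = 3000, end = 6000)))
  expect_warning(m <- metagene_matrix(trk, gm), "skipped")
  expect_equal(m$gene_ids, "ok")
})

test_that("TSS-window classification follows the 250-bp centered window", {
  gm <- make_gm(one_gene(start = 5000, end = 8000))   # tss = 5000
  lab <- function(pk) tss_marked_classification(pk, gm)$label
  expect_equal(lab(genomic_intervals("chr1", 4950, 5050)), "tss_marked")
  # window is [tss - 125, tss + 125): peak touching 5124 is TSS-marked
  expect_equal(lab(genomic_intervals("chr1", 5124, 5400)), "tss_marked")
  expect_equal(lab(genomic_intervals("chr1", 5125, 5400)), "nontss_marked")
  # peak 500 bp into the body only
  expect_equal(lab(genomic_intervals("chr1", 5500, 5600)), "nontss_marked")
  expect_equal(lab(genomic_intervals("chr1", 20000, 20100)), "unmarked")
  expect_equal(lab(genomic_intervals(character(), numeric(), numeric())),
               "unmarked")
})

test_that("chromosome bins report covered fraction with per-base accuracy", {
  layout <- genome_layout("chr1", 250000)
  # one 1,000-bp peak in an otherwise empty 100-kb bin
  prof <- chromosome_bin_profile(genomic_intervals("chr1", 10000, 11000),
                                 layout)
  expect_equal(prof$level, c(0.01, 0, 0))
  expect_equal(prof$bin_end, c(1e5, 2e5, 2.5e5))
  # straddling peak splits bp across bins (200 left, 300 right)
  prof2 <- chromosome_bin_profile(genomic_intervals("chr1", 99800, 100300),
                                  layout)
  expect_equal(prof2$level, c(200 / 1e5, 300 / 1e5, 0))
  # partial final bin normalized by its true length
  prof3 <- chromosome_bin_profile(genomic_intervals("chr1", 2.4e5, 245000),
                                  layout)
  expect_equal(prof3$level[3], 5000 / 50000)
  # no peaks -> zeros
  expect_true(all(chromosome_bin_profile(
    genomic_intervals(character(), numeric(), numeric()),
    layout)$level == 0))
  # overlapping peaks are not double counted
  prof4 <- chromosome_bin_profile(
    genomic_intervals("chr1", c(0, 500), c(1000, 1500)), layout)
  expect_equal(prof4$level[1], 1500 / 1e5)
})
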