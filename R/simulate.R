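HISTONE_MARKS <- c("H3K4me2", "H3K4me3", "H3K36me3", "H3K9ac", "H3K14ac",
                   "H3K9me2", "H3K9me3", "H3K27me3")

#' Configuration for the synthetic epigenome generator
#'
#' Defaults describe a compact Arabidopsis-like study system: a 5-Mb
#' genome (2 chromosomes) with 500 genes, ~30x IP/input coverage from
#' 200-400 bp fragments, acetylation peaks planted near TSSs with
#' presence/placement/height all coupled to expression through one
#' logistic slope (`expression_coupling`; 0 severs every link), a
#' pericentromeric heterochromatin block per chromosome carrying
#' hyper-mCHG/mCHH, gene-body mCG classes, histone marks co-occurring
#' with 4acC, and met1-like / rdd-like mutant modes.
#'
#' @param seed Master seed; every component derives its own stream from
#'   fixed offsets, so outputs are byte-identical per seed.
#' @param ... Overrides for any default field (unknown names error).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    # genome
    n_chroms = 2, chrom_length = 2.5e6, n_genes = 500,
    gene_length_meanlog = log(2000), gene_length_sdlog = 0.35,
    min_gene_length = 700, min_gene_gap = 300,
    biotype_probs = c(protein_coding = 0.82, te_gene = 0.08,
                      pseudogene = 0.04, mirna = 0.015, trna = 0.015,
                      snrna = 0.01, snorna = 0.01, other_ncrna = 0.01),
    # expression
    expr_zero_prob = 0.2, expr_meanlog = 1, expr_sdlog = 1.5,
    # acetylation peaks and their expression coupling
    expression_coupling = 4, peak_prob_intercept = -1.5,
    tss_placement_intercept = 0.5, tss_placement_scale = 0.6,
    height_coupling = 0.5,
    peak_width = 400, peak_offset_mean = 150, peak_offset_sd = 100,
    enrichment_fold = 8,
    # sequencing model
    depth = 30, frag_len_range = c(200, 400), resolution = 10,
    # methylation
    het_fraction = 0.2,
    meth_levels = list(het = c(CG = 0.85, CHG = 0.55, CHH = 0.12),
                       eu = c(CG = 0.02, CHG = 0.015, CHH = 0.01)),
    gene_body_mcg_probs = c(heavy = 0.25, moderate = 0.35, light = 0.40),
    gene_body_mcg_levels = c(heavy = 0.30, moderate = 0.04, light = 0.003),
    beta_precision = 50, meth_depth = 30,
    site_density_per_kb = c(CG = 8, CHG = 6, CHH = 16),
    # companion marks: P(mark | 4acC gene), P(mark | non-4acC gene)
    histone_probs = list(
      H3K4me2 = c(0.65, 0.25), H3K4me3 = c(0.70, 0.20),
      H3K36me3 = c(0.60, 0.25), H3K9ac = c(0.60, 0.20),
      H3K14ac = c(0.55, 0.20), H3K9me2 = c(0.05, 0.25),
      H3K9me3 = c(0.07, 0.20), H3K27me3 = c(0.15, 0.30)),
    dhs_probs = c(0.70, 0.25),
    tf_names = c("TF_A", "TF_B", "TF_C", "TF_D"),
    tf_probs = c(0.30, 0.05),
    # mutants
    met1_beta = c(0.5, 50),
    rdd_n_hyper = 20, rdd_delta = 0.4, rdd_region_length = 2000,
    dar_fraction = 0.2, dar_attenuation = 4)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stopf("unknown config field: %s", unknown[1])
  cfg[names(dots)] <- dots
  stopifnot(cfg$enrichment_fold >= 1, cfg$depth >= 1,
            cfg$het_fraction >= 0, cfg$het_fraction < 1)
  class(cfg) <- "simulation_config"
  cfg
}

#' Generate a synthetic genome: layout plus gene models
#'
#' Places non-overlapping genes (log-normal lengths, Bernoulli(0.5)
#' strand, 1-5 exons with terminal UTRs) on equal-length chromosomes.
#' Deterministic given the config seed.
#'
#' @param config A [simulation_config()].
#' @return List with `layout` (genome layout) and `genes`
#'   (`gene_models`).
#' @export
generate_genome <- function(config) {
  set.seed(config$seed)
  layout <- genome_layout(sprintf("chr%d", seq_len(config$n_chroms)),
                          rep(config$chrom_length, config$n_chroms))
  n <- config$n_genes
  per_chrom <- diff(round(seq(0, n, length.out = config$n_chroms + 1)))
  genes_l <- list(); exons_l <- list(); utr5_l <- list(); utr3_l <- list()
  gid <- 0
  for (ci in seq_len(config$n_chroms)) {
    nc <- per_chrom[ci]
    if (nc == 0) next
    len <- pmax(round(rlnorm(nc, config$gene_length_meanlog,
                             config$gene_length_sdlog)),
                config$min_gene_length)
    L <- layout$length[ci]
    free <- L - sum(len) - (nc + 1) * config$min_gene_gap
    if (free < 0)
      stopf("cannot place %d genes on a %g bp chromosome; lower the density",
            nc, L)
    u <- runif(nc + 1)
    gaps <- config$min_gene_gap + free * u / sum(u)
    starts <- floor(cumsum(gaps)[seq_len(nc)] +
                      cumsum(c(0, head(len, -1))))
    ends <- starts + len
    strand <- ifelse(runif(nc) < 0.5, "+", "-")
    for (i in seq_len(nc)) {
      gid <- gid + 1
      id <- sprintf("gene_%04d", gid)
      s <- starts[i]; e <- ends[i]; li <- len[i]
      n_ex <- sample.int(5, 1)
      # exon/intron structure: split the span at 2*(n_ex-1) sorted cuts
      if (n_ex > 1) {
        cuts <- sort(sample.int(li - 2, 2 * (n_ex - 1)) )
        bounds <- c(0, cuts, li)
        ex_s <- s + bounds[seq(1, 2 * n_ex - 1, by = 2)]
        ex_e <- s + bounds[seq(2, 2 * n_ex, by = 2)]
        keep <- ex_e > ex_s
        ex_s <- ex_s[keep]; ex_e <- ex_e[keep]
        ex_e[length(ex_e)] <- e; ex_s[1] <- s
      } else {
        ex_s <- s; ex_e <- e
      }
      first_len <- ex_e[1] - ex_s[1]
      last_len <- ex_e[length(ex_e)] - ex_s[length(ex_s)]
      u_left <- min(round(runif(1, 50, 300)), floor(first_len / 2))
      u_right <- min(round(runif(1, 50, 300)), floor(last_len / 2))
      left_utr <- if (u_left > 0)
        data.frame(gene_id = id, chrom = layout$chrom[ci], start = ex_s[1],
                   end = ex_s[1] + u_left, stringsAsFactors = FALSE)
      right_utr <- if (u_right > 0)
        data.frame(gene_id = id, chrom = layout$chrom[ci],
                   start = ex_e[length(ex_e)] - u_right,
                   end = ex_e[length(ex_e)], stringsAsFactors = FALSE)
      if (strand[i] == "+") {
        utr5_l[[id]] <- left_utr; utr3_l[[id]] <- right_utr
      } else {
        utr5_l[[id]] <- right_utr; utr3_l[[id]] <- left_utr
      }
      genes_l[[id]] <- data.frame(
        gene_id = id, chrom = layout$chrom[ci], strand = strand[i],
        start = s, end = e,
        tss = if (strand[i] == "+") s else e - 1,
        tes = if (strand[i] == "+") e - 1 else s,
        biotype = sample(names(config$biotype_probs), 1,
                         prob = config$biotype_probs),
        stringsAsFactors = FALSE)
      exons_l[[id]] <- data.frame(gene_id = id, chrom = layout$chrom[ci],
                                  start = ex_s, end = ex_e,
                                  stringsAsFactors = FALSE)
    }
  }
  bindr <- function(l) if (length(l)) do.call(rbind, unname(l)) else
    data.frame(gene_id = character(), chrom = character(),
               start = numeric(), end = numeric(), stringsAsFactors = FALSE)
  gm <- list(genes = bindr(genes_l), exons = bindr(exons_l),
             utr5 = bindr(utr5_l), utr3 = bindr(utr3_l))
  if (nrow(gm$genes)) rownames(gm$genes) <- NULL
  class(gm) <- "gene_models"
  list(layout = layout, genes = gm)
}

# pericentromeric heterochromatin blocks, one centered block per chromosome
het_blocks <- function(layout, het_fraction) {
  if (het_fraction <= 0) return(empty_intervals())
  half <- layout$length * het_fraction / 2
  genomic_intervals(layout$chrom, floor(layout$length / 2 - half),
                    floor(layout$length / 2 + half),
                    name = sprintf("het_%s", layout$chrom))
}

# expression, peak presence/placement/height truth for every gene
sample_expression_truth <- function(genome, config) {
  set.seed(config$seed + 1)
  g <- genome$genes$genes
  n <- nrow(g)
  fpkm <- ifelse(runif(n) < config$expr_zero_prob, 0,
                 rlnorm(n, config$expr_meanlog, config$expr_sdlog))
  r <- (rank(fpkm, ties.method = "first") - 1) / max(n - 1, 1)
  slope <- config$expression_coupling
  has_peak <- runif(n) < plogis(config$peak_prob_intercept + slope * r)
  p_tss <- plogis(config$tss_placement_intercept +
                    config$tss_placement_scale * slope * r)
  tss_proximal <- runif(n) < p_tss
  w <- config$peak_width
  L <- g$end - g$start
  dir <- ifelse(g$strand == "+", 1, -1)
  # TSS-proximal: normal offset around the TSS; distal: uniform within
  # the gene body, at least 400 bp downstream of the TSS (short genes
  # fall back to TSS-proximal placement)
  too_short <- L < 400 + w + 100
  tss_proximal <- tss_proximal | too_short
  offset <- ifelse(tss_proximal,
                   round(rnorm(n, config$peak_offset_mean,
                               config$peak_offset_sd)),
                   round(runif(n, 400 + w / 2, pmax(L - w / 2, 401 + w / 2))))
  center <- g$tss + dir * offset
  chrom_len <- setNames(genome$layout$length, genome$layout$chrom)[g$chrom]
  peak_start <- pmax(pmin(center - w / 2, chrom_len - w), 0)
  peak_end <- peak_start + w
  slope_norm <- slope / 4
  fold <- config$enrichment_fold *
    2^(config$height_coupling * slope_norm * (r - 0.5))
  fold <- pmax(fold, 1)
  truth <- data.frame(
    gene_id = g$gene_id, chrom = g$chrom, fpkm = fpkm, expr_rank = r,
    has_peak = has_peak, tss_proximal = tss_proximal,
    peak_start = ifelse(has_peak, peak_start, NA_real_),
    peak_end = ifelse(has_peak, peak_end, NA_real_),
    fold = ifelse(has_peak, fold, NA_real_), stringsAsFactors = FALSE)
  truth
}

truth_peaks <- function(truth) {
  t <- truth[truth$has_peak, , drop = FALSE]
  if (!nrow(t)) return(empty_intervals())
  genomic_intervals(t$chrom, t$peak_start, t$peak_end, name = t$gene_id,
                    score = t$fold)
}

# One sequencing track: Poisson background fragments plus fold-enriched
# fragments over the planted peaks (enriched = FALSE gives input).
simulate_track <- function(genome, truth, config, enriched, seed) {
  set.seed(seed)
  res <- config$resolution
  fl <- config$frag_len_range
  mean_frag <- mean(fl)
  rate <- config$depth / mean_frag          # fragments per bp
  steps_l <- list()
  lib <- 0
  for (ci in seq_len(nrow(genome$layout))) {
    ch <- genome$layout$chrom[ci]; len <- genome$layout$length[ci]
    n_bg <- rpois(1, len * rate)
    flen <- round(runif(n_bg, fl[1], fl[2]))
    fstart <- floor(runif(n_bg, 0, len - flen))
    if (enriched) {
      tp <- truth[truth$has_peak & truth$chrom == ch, , drop = FALSE]
      if (nrow(tp)) {
        n_extra <- rpois(nrow(tp), (tp$fold - 1) * rate *
                           (tp$peak_end - tp$peak_start))
        idx <- rep(seq_len(nrow(tp)), n_extra)
        if (length(idx)) {
          elen <- round(runif(length(idx), fl[1], fl[2]))
          ecenter <- floor(runif(length(idx), tp$peak_start[idx],
                                 tp$peak_end[idx]))
          estart <- pmax(ecenter - floor(elen / 2), 0)
          fstart <- c(fstart, estart)
          flen <- c(flen, elen)
        }
      }
    }
    fend <- pmin(fstart + flen, len)
    nbins <- ceiling(len / res)
    add <- tabulate(fstart %/% res + 1, nbins + 1)
    sub <- tabulate(pmin((fend - 1) %/% res + 2, nbins + 1), nbins + 1)
    cov <- cumsum(add - sub)[seq_len(nbins)]
    rl <- rle(cov)
    ends <- cumsum(rl$lengths) * res
    starts <- c(0, head(ends, -1))
    ends <- pmin(ends, len)
    keep <- rl$values > 0
    steps_l[[ch]] <- data.frame(chrom = ch, start = starts[keep],
                                end = ends[keep], value = rl$values[keep],
                                stringsAsFactors = FALSE)
  }
  steps <- do.call(rbind, steps_l)
  rownames(steps) <- NULL
  coverage_track(steps, layout = genome$layout)
}

# methylation site scaffold: positions, strands and true per-site mean
# levels for every context, shared between WT and mutants
meth_site_scaffold <- function(genome, truth, config) {
  set.seed(config$seed + 6)
  het <- het_blocks(genome$layout, config$het_fraction)
  g <- genome$genes$genes
  mcg_class <- sample(names(config$gene_body_mcg_probs), nrow(g),
                      replace = TRUE, prob = config$gene_body_mcg_probs)
  sites_l <- list()
  for (ci in seq_len(nrow(genome$layout))) {
    ch <- genome$layout$chrom[ci]; len <- genome$layout$length[ci]
    for (ctx in CX_CONTEXTS) {
      n <- round(len / 1000 * config$site_density_per_kb[[ctx]])
      pos <- sort(sample.int(len, n)) - 1
      sites_l[[paste(ch, ctx)]] <- data.frame(
        chrom = ch, pos = pos,
        strand = ifelse(runif(n) < 0.5, "+", "-"), context = ctx,
        stringsAsFactors = FALSE)
    }
  }
  sites <- do.call(rbind, sites_l)
  rownames(sites) <- NULL
  in_het <- count_interval_overlaps(
    genomic_intervals(sites$chrom, sites$pos, sites$pos + 1), het) > 0
  mu <- ifelse(in_het,
               unlist(config$meth_levels$het)[sites$context],
               unlist(config$meth_levels$eu)[sites$context])
  # euchromatic gene-body mCG follows the gene's mCG class
  body <- genomic_intervals(g$chrom, g$start, g$end)
  hits <- GenomicRanges::findOverlaps(
    as_granges(genomic_intervals(sites$chrom, sites$pos, sites$pos + 1)),
    as_granges(body))
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  sel <- sites$context[qi] == "CG" & !in_het[qi]
  mu[qi[sel]] <- config$gene_body_mcg_levels[mcg_class[si[sel]]]
  sites$mu <- pmin(pmax(mu, 1e-4), 0.999)
  list(sites = sites, het = het,
       gene_mcg = data.frame(gene_id = g$gene_id, mcg_class = mcg_class,
                             stringsAsFactors = FALSE))
}

# one bisulfite sample from the scaffold (fresh beta-binomial draws)
sample_cx_calls <- function(sites, config, seed) {
  set.seed(seed)
  k <- config$beta_precision
  level <- rbeta(nrow(sites), sites$mu * k, (1 - sites$mu) * k)
  n_total <- rpois(nrow(sites), config$meth_depth)
  n_meth <- rbinom(nrow(sites), n_total, level)
  data.frame(chrom = sites$chrom, pos = sites$pos, strand = sites$strand,
             context = sites$context, n_meth = n_meth, n_total = n_total,
             stringsAsFactors = FALSE)
}

#' Generate the wild-type synthetic epigenome
#'
#' Samples expression, plants acetylation peaks near TSSs (presence,
#' TSS-proximity and height all coupled to expression through
#' `expression_coupling`), simulates IP/input coverage for two
#' replicates from 200-400 bp fragments, draws a three-context
#' beta-binomial bisulfite sample over heterochromatin/euchromatin/
#' gene-body structure, and assigns histone/DHS/TF intervals conditional
#' on the 4acC truth. Every component runs on its own seed stream, so a
#' given config reproduces byte-identical outputs.
#'
#' @param genome Result of [generate_genome()].
#' @param config The same [simulation_config()].
#' @param out_dir Optional directory; when given, writes chrom.sizes,
#'   GFF3, 4 bedGraphs, a CX report, expression TSV, one BED per
#'   reference set, and a JSON truth manifest.
#' @param tracks,methylation,marks Logical switches for the expensive
#'   components (truth and expression are always produced).
#' @return List: `genome`, `expression`, `truth` (manifest), `tracks`
#'   (ip/input x 2 reps), `calls`, `reference_sets`, `files`.
#' @export
generate_epigenome <- function(genome, config, out_dir = NULL,
                               tracks = TRUE, methylation = TRUE,
                               marks = TRUE) {
  truth <- sample_expression_truth(genome, config)
  g <- genome$genes$genes
  expression <- data.frame(gene_id = g$gene_id, fpkm = truth$fpkm,
                           stringsAsFactors = FALSE)
  trk <- NULL
  if (tracks) {
    trk <- list(
      ip = list(rep1 = simulate_track(genome, truth, config, TRUE,
                                      config$seed + 2),
                rep2 = simulate_track(genome, truth, config, TRUE,
                                      config$seed + 3)),
      input = list(rep1 = simulate_track(genome, truth, config, FALSE,
                                         config$seed + 4),
                   rep2 = simulate_track(genome, truth, config, FALSE,
                                         config$seed + 5)))
  }
  calls <- NULL; scaffold <- NULL
  if (methylation) {
    scaffold <- meth_site_scaffold(genome, truth, config)
    calls <- sample_cx_calls(scaffold$sites, config, config$seed + 7)
  }
  refs <- NULL
  if (marks) {
    set.seed(config$seed + 8)
    refs <- list()
    for (mk in names(config$histone_probs)) {
      pr <- config$histone_probs[[mk]]
      on <- runif(nrow(g)) < ifelse(truth$has_peak, pr[1], pr[2])
      refs[[mk]] <- genomic_intervals(g$chrom[on], g$start[on], g$end[on],
                                      name = g$gene_id[on])
    }
    on <- runif(nrow(g)) < ifelse(truth$has_peak, config$dhs_probs[1],
                                  config$dhs_probs[2])
    refs[["DHS"]] <- genomic_intervals(g$chrom[on],
                                       pmax(g$tss[on] - 150, 0),
                                       g$tss[on] + 150,
                                       name = g$gene_id[on])
    for (tf in config$tf_names) {
      on <- runif(nrow(g)) < ifelse(truth$has_peak, config$tf_probs[1],
                                    config$tf_probs[2])
      refs[[tf]] <- genomic_intervals(g$chrom[on],
                                      pmax(g$tss[on] - 100, 0),
                                      g$tss[on] + 100, name = g$gene_id[on])
    }
  }
  manifest <- list(genes = truth,
                   het_blocks = if (!is.null(scaffold)) scaffold$het,
                   gene_mcg = if (!is.null(scaffold)) scaffold$gene_mcg,
                   planted_dmrs = NULL, planted_dars = NULL)
  out <- list(genome = genome, expression = expression, truth = manifest,
              scaffold = scaffold, tracks = trk, calls = calls,
              reference_sets = refs, files = NULL)
  if (!is.null(out_dir))
    out$files <- write_epigenome(out, genome, config, out_dir, "wt")
  out
}

#' Derive a mutant epigenome from the wild-type truth
#'
#' `met1` mode resamples the per-site CG mean levels from a Beta(0.5, 50)
#' (near-complete CG erasure) and leaves CHG/CHH untouched. `rdd` mode
#' plants `rdd_n_hyper` hypermethylated regions gaining `rdd_delta` in
#' all three contexts. Both modes attenuate a `dar_fraction` of the
#' planted peaks by `dar_attenuation`-fold in the mutant IP, creating
#' true DARs; all planted DMRs/DARs are recorded in the manifest.
#'
#' @param genome Result of [generate_genome()].
#' @param wt Result of [generate_epigenome()] (must include methylation
#'   when mutant methylation is requested).
#' @param config The shared [simulation_config()].
#' @param mode `met1` or `rdd`.
#' @param out_dir Optional output directory (mutant-suffixed files).
#' @param tracks,methylation Logical switches as in
#'   [generate_epigenome()].
#' @return List: `mode`, `calls`, `tracks`, `truth` (with planted_dmrs /
#'   planted_dars), `files`.
#' @export
generate_mutant_epigenome <- function(genome, wt, config,
                                      mode = c("met1", "rdd"),
                                      out_dir = NULL, tracks = TRUE,
                                      methylation = TRUE) {
  mode <- match.arg(mode)
  off <- if (mode == "met1") 100 else 200
  planted_dmrs <- NULL
  calls <- NULL
  if (methylation) {
    if (is.null(wt$scaffold))
      stopf("wild-type epigenome was generated without methylation")
    sites <- wt$scaffold$sites
    set.seed(config$seed + off + 1)
    if (mode == "met1") {
      cg <- sites$context == "CG"
      sites$mu[cg] <- pmin(pmax(rbeta(sum(cg), config$met1_beta[1],
                                      config$met1_beta[2]), 1e-4), 0.999)
    } else {
      # hyper regions are euchromatic (demethylase-target-like): inside
      # the heterochromatin block the ceiling leaves no room for +delta
      lens <- rep(config$rdd_region_length, config$rdd_n_hyper)
      het <- het_blocks(genome$layout, config$het_fraction)
      template <- genomic_intervals(
        rep(genome$layout$chrom[1], config$rdd_n_hyper), 0, lens)
      planted_dmrs <- sample_matched_random_regions(
        template, genome$layout, config$seed + off + 2)
      for (try in seq_len(100)) {
        bad <- count_interval_overlaps(planted_dmrs, het) > 0
        if (!any(bad)) break
        redraw <- sample_matched_random_regions(
          template[bad, , drop = FALSE], genome$layout,
          config$seed + off + 2 + try)
        planted_dmrs[bad, c("chrom", "start", "end")] <-
          redraw[, c("chrom", "start", "end")]
      }
      planted_dmrs$name <- sprintf("hyper_%d", seq_len(nrow(planted_dmrs)))
      inside <- count_interval_overlaps(
        genomic_intervals(sites$chrom, sites$pos, sites$pos + 1),
        planted_dmrs) > 0
      sites$mu[inside] <- pmin(sites$mu[inside] + config$rdd_delta, 0.95)
    }
    calls <- sample_cx_calls(sites, config, config$seed + off + 3)
  }
  trk <- NULL; planted_dars <- NULL
  if (tracks) {
    truth_mut <- wt$truth$genes
    set.seed(config$seed + off + 4)
    peak_idx <- which(truth_mut$has_peak)
    n_att <- round(length(peak_idx) * config$dar_fraction)
    att <- sample(peak_idx, n_att)
    truth_mut$fold[att] <- pmax(truth_mut$fold[att] /
                                  config$dar_attenuation, 1)
    planted_dars <- genomic_intervals(truth_mut$chrom[att],
                                      truth_mut$peak_start[att],
                                      truth_mut$peak_end[att],
                                      name = truth_mut$gene_id[att])
    trk <- list(
      ip = list(rep1 = simulate_track(genome, truth_mut, config, TRUE,
                                      config$seed + off + 5),
                rep2 = simulate_track(genome, truth_mut, config, TRUE,
                                      config$seed + off + 6)),
      input = list(rep1 = simulate_track(genome, truth_mut, config, FALSE,
                                         config$seed + off + 7),
                   rep2 = simulate_track(genome, truth_mut, config, FALSE,
                                         config$seed + off + 8)))
  }
  out <- list(mode = mode, calls = calls, tracks = trk,
              truth = list(genes = if (tracks) truth_mut else wt$truth$genes,
                           planted_dmrs = planted_dmrs,
                           planted_dars = planted_dars),
              files = NULL)
  if (!is.null(out_dir))
    out$files <- write_epigenome(out, genome, config, out_dir, mode)
  out
}

# write an epigenome bundle to disk; returns the named file list
write_epigenome <- function(x, genome, config, out_dir, prefix) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(out_dir, paste0(...))
  files <- list()
  if (prefix == "wt") {
    files$chrom_sizes <- write_chrom_sizes(genome$layout, fp("chrom.sizes"))
    files$gff3 <- write_gff3(genome$genes, fp("genes.gff3"))
    files$expression <- write_expression_tsv(x$expression,
                                             fp("expression.tsv"))
    if (!is.null(x$reference_sets)) {
      files$reference_beds <- vapply(names(x$reference_sets), function(nm)
        write_bed(x$reference_sets[[nm]], fp(nm, ".bed")), character(1))
    }
  }
  if (!is.null(x$tracks)) {
    for (kind in c("ip", "input")) for (rep in c("rep1", "rep2")) {
      key <- paste(prefix, kind, rep, sep = "_")
      files[[key]] <- write_bedgraph(x$tracks[[kind]][[rep]],
                                     fp(key, ".bedgraph"))
    }
  }
  if (!is.null(x$calls))
    files$cx_report <- write_cx_report(x$calls, fp(prefix, "_cx_report.txt"))
  manifest <- x$truth
  manifest$config_seed <- config$seed
  jsonlite::write_json(manifest, fp(prefix, "_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  files$manifest <- fp(prefix, "_manifest.json")
  files
}
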