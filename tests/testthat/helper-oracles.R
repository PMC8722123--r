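# Independent brute-force oracles and toy-data builders. These never call
# the code paths they check.

`%or%` <- function(x, y) if (is.null(x)) y else x

empty_sub <- function() data.frame(gene_id = character(),
                                   chrom = character(), start = numeric(),
                                   end = numeric(), stringsAsFactors = FALSE)

# assemble a gene_models object directly from data frames
make_gm <- function(genes, exons = NULL, utr5 = NULL, utr3 = NULL) {
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  genes$tes <- ifelse(genes$strand == "+", genes$end - 1, genes$start)
  if (is.null(genes$biotype)) genes$biotype <- "protein_coding"
  if (is.null(exons))
    exons <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                        start = genes$start, end = genes$end,
                        stringsAsFactors = FALSE)
  gm <- list(genes = genes, exons = exons, utr5 = utr5 %or% empty_sub(),
             utr3 = utr3 %or% empty_sub())
  class(gm) <- "gene_models"
  gm
}

one_gene <- function(id = "g1", chrom = "chr1", strand = "+", start = 5000,
                     end = 7000) {
  data.frame(gene_id = id, chrom = chrom, strand = strand, start = start,
             end = end, stringsAsFactors = FALSE)
}

# random toy genome (independent of the package generator): genes may
# overlap each other, exons split the span, UTRs cap the terminal exons
random_toy_genome <- function(seed, max_len = 1e5, max_genes = 50) {
  set.seed(seed)
  len <- sample(2e4:max_len, 1)
  layout <- acetylseq::genome_layout("chr1", len)
  n <- sample.int(max_genes, 1)
  gl <- sample(500:3000, n, replace = TRUE)
  gs <- sample.int(len - max(gl) - 1, n, replace = TRUE)
  genes <- data.frame(gene_id = sprintf("g%02d", seq_len(n)), chrom = "chr1",
                      strand = sample(c("+", "-"), n, replace = TRUE),
                      start = gs, end = gs + gl, stringsAsFactors = FALSE)
  ex_l <- list(); u5_l <- list(); u3_l <- list()
  for (i in seq_len(n)) {
    n_ex <- sample.int(3, 1)
    if (n_ex > 1) {
      cuts <- sort(sample(seq(genes$start[i] + 50, genes$end[i] - 50, by = 1),
                          2 * (n_ex - 1)))
      bounds <- c(genes$start[i], cuts, genes$end[i])
      es <- bounds[seq(1, 2 * n_ex - 1, 2)]; ee <- bounds[seq(2, 2 * n_ex, 2)]
      keep <- ee > es; es <- es[keep]; ee <- ee[keep]
    } else { es <- genes$start[i]; ee <- genes$end[i] }
    ex_l[[i]] <- data.frame(gene_id = genes$gene_id[i], chrom = "chr1",
                            start = es, end = ee, stringsAsFactors = FALSE)
    ul <- min(sample(20:150, 1), floor((ee[1] - es[1]) / 2))
    ur <- min(sample(20:150, 1), floor((ee[length(ee)] - es[length(es)]) / 2))
    left <- data.frame(gene_id = genes$gene_id[i], chrom = "chr1",
                       start = es[1], end = es[1] + ul,
                       stringsAsFactors = FALSE)
    right <- data.frame(gene_id = genes$gene_id[i], chrom = "chr1",
                        start = ee[length(ee)] - ur, end = ee[length(ee)],
                        stringsAsFactors = FALSE)
    if (genes$strand[i] == "+") { u5_l[[i]] <- left; u3_l[[i]] <- right }
    else { u5_l[[i]] <- right; u3_l[[i]] <- left }
  }
  gm <- make_gm(genes, do.call(rbind, ex_l), do.call(rbind, u5_l),
                do.call(rbind, u3_l))
  list(layout = layout, genes = gm)
}

# per-base category labels by painting in reverse priority order:
# promoter first, then utr3 / intron / exon / utr5 overwrite it
oracle_labels <- function(gm, layout, promoter_bp = 1000) {
  g <- gm$genes
  labs <- setNames(lapply(layout$length, function(L)
    rep("intergenic", L)), layout$chrom)
  paint <- function(chrom, s, e, lab) {
    L <- length(labs[[chrom]])
    s <- max(s, 0); e <- min(e, L)
    if (s < e) labs[[chrom]][(s + 1):e] <<- lab
  }
  for (i in seq_len(nrow(g))) {   # promoters (lowest priority)
    if (g$strand[i] == "+") paint(g$chrom[i], g$start[i] - promoter_bp,
                                  g$start[i], "promoter")
    else paint(g$chrom[i], g$end[i], g$end[i] + promoter_bp, "promoter")
  }
  sub_rows <- function(tab, id) tab[tab$gene_id == id, , drop = FALSE]
  base_mask <- function(chrom, tab) {
    m <- rep(FALSE, length(labs[[chrom]]))
    for (j in seq_len(nrow(tab)))
      m[(tab$start[j] + 1):tab$end[j]] <- TRUE
    m
  }
  for (lab in c("utr3", "intron", "exon", "utr5")) {
    for (i in seq_len(nrow(g))) {
      id <- g$gene_id[i]; ch <- g$chrom[i]
      ex <- base_mask(ch, sub_rows(gm$exons, id))
      u5 <- base_mask(ch, sub_rows(gm$utr5, id))
      u3 <- base_mask(ch, sub_rows(gm$utr3, id))
      body <- rep(FALSE, length(ex))
      body[(g$start[i] + 1):g$end[i]] <- TRUE
      m <- switch(lab, utr3 = u3, intron = body & !ex,
                  exon = ex & !u5 & !u3, utr5 = u5)
      labs[[ch]][m] <- lab
    }
  }
  labs
}

oracle_classify <- function(peak, labs) {
  v <- labs[[peak$chrom]][(peak$start + 1):min(peak$end,
                                               length(labs[[peak$chrom]]))]
  cats <- c("utr5", "exon", "intron", "utr3", "promoter")
  counts <- vapply(cats, function(k) sum(v == k), numeric(1))
  if (all(counts == 0)) "intergenic" else cats[which.max(counts)]
}

# per-base expansion of a step track on one chromosome
oracle_base_vector <- function(steps, chrom, len) {
  v <- numeric(len)
  s <- steps[steps$chrom == chrom, , drop = FALSE]
  for (j in seq_len(nrow(s)))
    v[(s$start[j] + 1):min(s$end[j], len)] <- s$value[j]
  v
}

# two-sided Fisher p by direct binomial-coefficient enumeration
fisher_oracle_p <- function(a, b, c, d) {
  k <- a + b; m <- a + c; n2 <- b + d; N <- m + n2
  if (N == 0) return(1)
  lo <- max(0, k - n2); hi <- min(k, m)
  xs <- lo:hi
  probs <- choose(m, xs) * choose(n2, k - xs) / choose(N, k)
  p_obs <- probs[xs == a]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

mk_calls <- function(pos, n_meth, n_total, context = "CG", chrom = "chr1",
                     strand = "+") {
  data.frame(chrom = chrom, pos = pos, strand = strand, context = context,
             n_meth = n_meth, n_total = n_total, stringsAsFactors = FALSE)
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
mw_oracle_p <- function(x, y) {
  allv <- c(x, y); nx <- length(x); n <- length(allv)
  r <- rank(allv)
  mu <- nx * (n + 1) / 2
  obs <- abs(sum(r[seq_len(nx)]) - mu)
  combs <- utils::combn(n, nx)
  stats <- apply(combs, 2, function(idx) abs(sum(r[idx]) - mu))
  mean(stats >= obs - 1e-9)
}
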