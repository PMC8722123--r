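#' Read a BED3+ file of genomic intervals
#'
#' BED is already 0-based half-open, so coordinates are taken as-is.
#' Columns 4-6 map to name/score/strand when present; `track`, `browser`
#' and `#` lines are skipped.
#'
#' @param path BED file path.
#' @return Interval table in input order.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  lineno <- which(keep)
  if (!length(lineno)) return(empty_intervals())
  parts <- strsplit(lines[lineno], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3))
    stopf("BED line %d has fewer than 3 fields", lineno[which(nf < 3)[1]])
  grab <- function(k) vapply(parts, function(p)
    if (length(p) >= k) p[k] else NA_character_, character(1))
  chrom <- grab(1)
  start <- suppressWarnings(as.numeric(grab(2)))
  end <- suppressWarnings(as.numeric(grab(3)))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) |
                 end != floor(end))
  if (length(bad))
    stopf("non-integer coordinates at line %d", lineno[bad[1]])
  bad <- which(start >= end)
  if (length(bad)) stopf("start >= end at line %d", lineno[bad[1]])
  name <- grab(4); name[name == "."] <- NA_character_
  score_chr <- grab(5)
  score <- suppressWarnings(as.numeric(score_chr))
  score[!is.na(score_chr) & score_chr == "."] <- NA_real_
  strand <- grab(6); strand[is.na(strand)] <- "."
  if (any(!strand %in% c("+", "-", ".")))
    stopf("invalid strand at line %d",
          lineno[which(!strand %in% c("+", "-", "."))[1]])
  genomic_intervals(chrom, start, end, name, score, strand)
}

#' Write intervals as BED
#'
#' Mirrors [read_bed()] bit-exactly: scores in 6-decimal fixed point,
#' missing name/score as `.`. BED6 when any name/score/strand is set,
#' BED3 otherwise.
#'
#' @param x Interval table.
#' @param path Output path.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  fmt_num <- function(v) ifelse(v == floor(v), sprintf("%d", as.integer(v)),
                                sprintf("%s", v))
  cols <- c("chrom", "start", "end")
  has6 <- any(!is.na(x$name)) || any(!is.na(x$score)) ||
    any(x$strand != ".", na.rm = TRUE)
  lines <- if (nrow(x) == 0) {
    character(0)
  } else if (has6) {
    sprintf("%s\t%d\t%d\t%s\t%s\t%s", x$chrom, as.integer(x$start),
            as.integer(x$end),
            ifelse(is.na(x$name), ".", x$name),
            ifelse(is.na(x$score), ".", sprintf("%.6f", x$score)),
            ifelse(is.na(x$strand), ".", x$strand))
  } else {
    sprintf("%s\t%d\t%d", x$chrom, as.integer(x$start), as.integer(x$end))
  }
  writeLines(lines, path)
  invisible(path)
}

GENE_BIOTYPES <- c("protein_coding", "te_gene", "pseudogene", "mirna",
                   "trna", "snrna", "snorna", "other_ncrna")

#' Read gene models from GFF3
#'
#' Parses `gene`/`mRNA`/`exon`/`five_prime_UTR`/`three_prime_UTR` features
#' into strand-aware gene models. GFF3 1-based inclusive coordinates are
#' converted to the internal 0-based half-open convention at this boundary.
#' When a gene carries several mRNAs, the representative transcript is the
#' longest one (ties broken by file order). The TSS is the first
#' transcribed base (`start` on `+`, `end - 1` on `-`); the TES is the
#' last transcribed base.
#'
#' @param path GFF3 file path.
#' @param biotype_attr Attribute naming the gene biotype
#'   (default `gene_biotype`); absent attribute means `protein_coding`,
#'   unknown values map to `other_ncrna` with a warning.
#' @return An object of class `gene_models`: a list with data frames
#'   `genes` (gene_id, chrom, strand, start, end, tss, tes, biotype),
#'   `exons`, `utr5`, `utr3` (gene_id, chrom, start, end).
#' @export
read_gene_models <- function(path, biotype_attr = "gene_biotype") {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  lineno <- which(keep)
  nf <- lengths(parts)
  if (any(nf != 9))
    stopf("GFF3 line %d does not have 9 fields", lineno[which(nf != 9)[1]])
  f <- function(k) vapply(parts, `[[`, character(1), k)
  feat <- data.frame(chrom = f(1), type = f(3),
                     start = as.numeric(f(4)) - 1, end = as.numeric(f(5)),
                     strand = f(7), attr = f(9), line = lineno,
                     stringsAsFactors = FALSE)
  get_attr <- function(attr, key) {
    m <- regmatches(attr, regexec(paste0("(?:^|;)", key, "=([^;]+)"), attr))
    vapply(m, function(z) if (length(z) == 2) z[2] else NA_character_,
           character(1))
  }
  feat$id <- get_attr(feat$attr, "ID")
  feat$parent <- get_attr(feat$attr, "Parent")

  genes <- feat[feat$type == "gene", ]
  if (any(!genes$strand %in% c("+", "-")))
    stopf("unknown strand '%s' for gene at line %d",
          genes$strand[!genes$strand %in% c("+", "-")][1],
          genes$line[!genes$strand %in% c("+", "-")][1])
  biotype <- get_attr(genes$attr, biotype_attr)
  biotype[is.na(biotype)] <- "protein_coding"
  unknown <- !biotype %in% GENE_BIOTYPES
  if (any(unknown)) {
    warnf("%d gene(s) with unknown biotype mapped to other_ncrna (e.g. '%s')",
          sum(unknown), biotype[unknown][1])
    biotype[unknown] <- "other_ncrna"
  }

  mrna <- feat[feat$type == "mRNA", ]
  subfeat <- feat[feat$type %in% c("exon", "five_prime_UTR",
                                   "three_prime_UTR"), ]
  gene_by_id <- setNames(seq_len(nrow(genes)), genes$id)
  # representative transcript: longest mRNA span, ties by file order
  rep_mrna_id <- rep(NA_character_, nrow(genes))
  if (nrow(mrna)) {
    gi <- gene_by_id[mrna$parent]
    if (anyNA(gi))
      stopf("mRNA at line %d has unknown parent gene",
            mrna$line[which(is.na(gi))[1]])
    out_of <- mrna$start < genes$start[gi] | mrna$end > genes$end[gi]
    if (any(out_of))
      stopf("mRNA at line %d lies outside its parent gene span",
            mrna$line[which(out_of)[1]])
    span <- mrna$end - mrna$start
    ord <- order(gi, -span, mrna$line)
    first <- !duplicated(gi[ord])
    rep_mrna_id[gi[ord][first]] <- mrna$id[ord][first]
  }

  take_children <- function(type) {
    s <- subfeat[subfeat$type == type & subfeat$parent %in%
                   rep_mrna_id[!is.na(rep_mrna_id)], ]
    if (!nrow(s))
      return(data.frame(gene_id = character(), chrom = character(),
                        start = numeric(), end = numeric(),
                        stringsAsFactors = FALSE))
    tr2gene <- setNames(genes$id[!is.na(rep_mrna_id)],   # mRNA id -> gene id
                        rep_mrna_id[!is.na(rep_mrna_id)])
    gid <- tr2gene[s$parent]
    gi <- gene_by_id[gid]
    out_of <- s$start < genes$start[gi] | s$end > genes$end[gi]
    if (any(out_of))
      stopf("%s at line %d lies outside its parent span", type,
            s$line[which(out_of)[1]])
    out <- data.frame(gene_id = gid, chrom = s$chrom, start = s$start,
                      end = s$end, stringsAsFactors = FALSE)
    out[order(match(out$gene_id, genes$id), out$start), , drop = FALSE]
  }
  exons <- take_children("exon")
  utr5 <- take_children("five_prime_UTR")
  utr3 <- take_children("three_prime_UTR")
  # genes without an mRNA (or without exon children): whole span is exonic
  have <- unique(exons$gene_id)
  missing <- genes$id[!genes$id %in% have]
  if (length(missing)) {
    mi <- gene_by_id[missing]
    exons <- rbind(exons, data.frame(gene_id = missing,
                                     chrom = genes$chrom[mi],
                                     start = genes$start[mi],
                                     end = genes$end[mi],
                                     stringsAsFactors = FALSE))
  }

  gm <- list(
    genes = data.frame(
      gene_id = genes$id, chrom = genes$chrom, strand = genes$strand,
      start = genes$start, end = genes$end,
      tss = ifelse(genes$strand == "+", genes$start, genes$end - 1),
      tes = ifelse(genes$strand == "+", genes$end - 1, genes$start),
      biotype = biotype, stringsAsFactors = FALSE),
    exons = exons, utr5 = utr5, utr3 = utr3)
  class(gm) <- "gene_models"
  gm
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes on %d chromosome(s)\n",
              nrow(x$genes), length(unique(x$genes$chrom))))
  invisible(x)
}

#' Write gene models as GFF3
#'
#' Inverse of [read_gene_models()]: emits one representative mRNA per
#' gene with its exons and UTRs, converting back to 1-based inclusive
#' coordinates.
#'
#' @param gm A `gene_models` object.
#' @param path Output path.
#' @export
write_gff3 <- function(gm, path) {
  g <- gm$genes
  out <- character(0)
  line <- function(chrom, type, s0, e0, strand, attrs)
    sprintf("%s\tacetylseq\t%s\t%d\t%d\t.\t%s\t.\t%s", chrom, type,
            as.integer(s0 + 1), as.integer(e0), strand, attrs)
  blocks <- lapply(seq_len(nrow(g)), function(i) {
    gid <- g$gene_id[i]
    mid <- paste0(gid, ".1")
    sub <- function(tab, type) {
      s <- tab[tab$gene_id == gid, , drop = FALSE]
      if (!nrow(s)) return(character(0))
      line(s$chrom, type, s$start, s$end, g$strand[i],
           sprintf("Parent=%s", mid))
    }
    c(line(g$chrom[i], "gene", g$start[i], g$end[i], g$strand[i],
           sprintf("ID=%s;gene_biotype=%s", gid, g$biotype[i])),
      line(g$chrom[i], "mRNA", g$start[i], g$end[i], g$strand[i],
           sprintf("ID=%s;Parent=%s", mid, gid)),
      sub(gm$exons, "exon"), sub(gm$utr5, "five_prime_UTR"),
      sub(gm$utr3, "three_prime_UTR"))
  })
  writeLines(c("##gff-version 3", unlist(blocks)), path)
  invisible(path)
}

CX_CONTEXTS <- c("CG", "CHG", "CHH")

#' Read a Bismark-style CX report
#'
#' Tab-separated lines: chromosome, 1-based position, strand, methylated
#' count, unmethylated count, context, trinucleotide. Positions are
#' converted to 0-based; sites with zero total coverage are kept (they
#' are filtered downstream by coverage thresholds).
#'
#' @param path CX report path.
#' @return Data frame of cytosine calls: chrom, pos (0-based), strand,
#'   context, n_meth, n_total.
#' @export
read_cx_report <- function(path) {
  x <- data.table::fread(path, header = FALSE, sep = "\t",
                         colClasses = list(character = c(1, 3, 6, 7)))
  if (ncol(x) < 6) stopf("CX report needs at least 6 columns: %s", path)
  n_meth <- as.numeric(x[[4]]); n_un <- as.numeric(x[[5]])
  bad <- which(is.na(n_meth) | is.na(n_un) | n_meth < 0 | n_un < 0)
  if (length(bad)) stopf("negative or non-numeric count at line %d", bad[1])
  ctx <- toupper(x[[6]])
  bad <- which(!ctx %in% CX_CONTEXTS)
  if (length(bad))
    stopf("unknown context '%s' at line %d", x[[6]][bad[1]], bad[1])
  data.frame(chrom = x[[1]], pos = as.numeric(x[[2]]) - 1, strand = x[[3]],
             context = ctx, n_meth = n_meth, n_total = n_meth + n_un,
             stringsAsFactors = FALSE)
}

#' Write cytosine calls as a Bismark-style CX report
#' @param calls Cytosine call table (see [read_cx_report()]).
#' @param path Output path.
#' @export
write_cx_report <- function(calls, path) {
  tri <- ifelse(calls$context == "CG", "CGA",
                ifelse(calls$context == "CHG", "CAG", "CTT"))
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s", calls$chrom,
                   as.integer(calls$pos + 1), calls$strand,
                   as.integer(calls$n_meth),
                   as.integer(calls$n_total - calls$n_meth),
                   calls$context, tri)
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene expression table
#'
#' @param path TSV with mandatory header columns `gene_id` and `fpkm`.
#' @return Data frame with gene_id and non-negative fpkm.
#' @export
read_expression_tsv <- function(path) {
  x <- as.data.frame(data.table::fread(path, header = TRUE, sep = "\t"))
  if (!all(c("gene_id", "fpkm") %in% names(x)))
    stopf("expression table must have 'gene_id' and 'fpkm' header columns")
  x$fpkm <- as.numeric(x$fpkm)
  if (any(is.na(x$fpkm) | x$fpkm < 0))
    stopf("fpkm values must be non-negative numbers")
  x[, c("gene_id", "fpkm")]
}

#' Write a gene expression table
#' @param expr Data frame with gene_id and fpkm.
#' @param path Output path.
#' @export
write_expression_tsv <- function(expr, path) {
  lines <- c("gene_id\tfpkm",
             sprintf("%s\t%.6f", expr$gene_id, expr$fpkm))
  writeLines(lines, path)
  invisible(path)
}
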