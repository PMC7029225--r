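#' File formats
#'
#' Tabular intermediates are plain TSV (header row, no quoting, no row
#' names). Genomes travel as FASTA (Biostrings), annotations as GTF
#' (1-based inclusive, `gene_id`/`transcript_id` attributes; rtracklayer),
#' variants as VCF v4.2 (1-based; read with vcfR, written by a minimal
#' writer with one GT column per sample).
#'
#' @name pgx_io
NULL

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, colClasses = NA) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = colClasses)
}

#' Write/read a count matrix as TSV (feature ids in the first column)
#' @param x A [count_matrix()].
#' @param path File path.
#' @export
write_count_matrix <- function(x, path) {
  stopifnot(inherits(x, "count_matrix"))
  df <- data.frame(feature_id = rownames(x$counts), x$counts,
                   check.names = FALSE)
  write_tsv(df, path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  count_matrix(m)
}

#' Write/read a two-group design TSV (columns sample_id, group)
#' @param design Design data.frame or named vector (see [as_design]).
#' @param path File path.
#' @export
write_design <- function(design, path) write_tsv(as_design(design), path)

#' @rdname write_design
#' @export
read_design <- function(path) as_design(read_tsv(path, colClasses = "character"))

#' Write transcript models as GTF
#'
#' Emits one `exon` row per exon and one `CDS` row per CDS segment, with
#' `gene_id` and `transcript_id` attributes, via rtracklayer.
#'
#' @param models List of [transcript_model()] objects.
#' @param path Output GTF path.
#' @export
write_annotation_gtf <- function(models, path) {
  rows <- lapply(models, function(m) {
    ex <- m$exons
    cd <- cds_segments(m)
    # phase: leftover bases of the previous codon, in transcript order
    len <- cd$end - cd$start + 1L
    tx_order <- if (m$strand == "+") seq_len(nrow(cd)) else rev(seq_len(nrow(cd)))
    before <- cumsum(c(0L, len[tx_order]))[seq_len(nrow(cd))]
    phase <- integer(nrow(cd))
    phase[tx_order] <- (3L - before %% 3L) %% 3L
    data.frame(
      chrom = m$chrom,
      start = c(ex$start, cd$start),
      end = c(ex$end, cd$end),
      strand = m$strand,
      type = c(rep("exon", nrow(ex)), rep("CDS", nrow(cd))),
      phase = c(rep(NA_integer_, nrow(ex)), phase),
      gene_id = m$gene_id,
      transcript_id = m$transcript_id)
  })
  tab <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = tab$chrom,
    ranges = IRanges::IRanges(tab$start, tab$end),
    strand = tab$strand,
    type = tab$type, source = "pgxpipe", phase = tab$phase,
    gene_id = tab$gene_id, transcript_id = tab$transcript_id)
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read transcript models from GTF
#'
#' Reconstructs [transcript_model()] objects from `exon` and `CDS` rows
#' grouped by `transcript_id`.
#'
#' @param path GTF path.
#' @return Named list of transcript models (names are transcript ids).
#' @export
read_annotation_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   type = as.character(gr$type),
                   gene_id = gr$gene_id,
                   transcript_id = gr$transcript_id)
  models <- lapply(split(df, df$transcript_id), function(g) {
    ex <- g[g$type == "exon", , drop = FALSE]
    cd <- g[g$type == "CDS", , drop = FALSE]
    if (nrow(ex) == 0L || nrow(cd) == 0L)
      stop("transcript ", g$transcript_id[1L], " lacks exon or CDS rows")
    transcript_model(g$transcript_id[1L], g$gene_id[1L], g$chrom[1L],
                     g$strand[1L],
                     data.frame(start = ex$start, end = ex$end),
                     min(cd$start), max(cd$end))
  })
  models[order(names(models))]
}

#' Write per-sample SNVs as VCF v4.2
#'
#' One record per variant with a GT genotype column per sample (`0/1` for
#' the carrying sample, `0/0` otherwise).
#'
#' @param variants Data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `sample_id`.
#' @param samples Character vector fixing the sample-column order.
#' @param path Output VCF path.
#' @export
write_variants_vcf <- function(variants, samples, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t")), con)
  if (nrow(variants) > 0L) {
    o <- order(variants$chrom, variants$pos)
    variants <- variants[o, , drop = FALSE]
    for (i in seq_len(nrow(variants))) {
      gt <- ifelse(samples == variants$sample_id[i], "0/1", "0/0")
      writeLines(paste(c(variants$chrom[i], variants$pos[i], ".",
                         variants$ref[i], variants$alt[i], ".", "PASS", ".",
                         "GT", gt), collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' Read per-sample SNVs from VCF
#'
#' Parses with vcfR; every sample whose genotype contains the alternate
#' allele yields one row.
#'
#' @param path VCF path.
#' @return Data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `sample_id`.
#' @export
read_variants_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  empty <- data.frame(chrom = character(0L), pos = integer(0L),
                      ref = character(0L), alt = character(0L),
                      sample_id = character(0L))
  if (is.null(fix) || nrow(v@gt) == 0L) return(empty)
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  rows <- lapply(seq_len(nrow(fix)), function(i) {
    carriers <- colnames(gt)[grepl("1", gt[i, ])]
    if (length(carriers) == 0L) return(NULL)
    data.frame(chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
               ref = fix$REF[i], alt = fix$ALT[i], sample_id = carriers)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out
}
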