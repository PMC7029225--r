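#' Transcript models
#'
#' A `transcript_model` describes one transcript as an ordered chain of
#' genomic exons plus a coding span, on a named chromosome and strand. It is
#' the substrate for variant application and novel-exon insertion. All
#' coordinates are 1-based and closed, the convention shared by GTF, VCF and
#' the Bioconductor ranges infrastructure; conversions therefore happen
#' nowhere.
#'
#' @param transcript_id,gene_id Character identifiers.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons A data.frame with integer columns `start` and `end`
#'   (1-based, closed), non-overlapping. Rows may be given in any order and
#'   are sorted by genomic start.
#' @param cds_start,cds_end Genomic bounds of the coding region; must lie
#'   within the exon union.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand,
                             exons, cds_start, cds_end) {
  stopifnot(is.character(transcript_id), length(transcript_id) == 1L,
            is.character(gene_id), length(gene_id) == 1L,
            strand %in% c("+", "-"),
            is.data.frame(exons), all(c("start", "end") %in% names(exons)))
  exons <- data.frame(start = as.integer(exons$start),
                      end = as.integer(exons$end))
  exons <- exons[order(exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  if (any(exons$end < exons$start))
    stop("exon with end < start in transcript ", transcript_id)
  if (nrow(exons) > 1L && any(exons$start[-1L] <= exons$end[-nrow(exons)]))
    stop("overlapping exons in transcript ", transcript_id)
  cds_start <- as.integer(cds_start); cds_end <- as.integer(cds_end)
  if (cds_end < cds_start) stop("empty CDS span in transcript ", transcript_id)
  in_exon <- function(p) any(p >= exons$start & p <= exons$end)
  if (!in_exon(cds_start) || !in_exon(cds_end))
    stop("CDS bounds fall outside exons in transcript ", transcript_id)
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 chrom = chrom, strand = strand, exons = exons,
                 cds_start = cds_start, cds_end = cds_end),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("transcript_model %s (gene %s) %s%s, %d exon(s), CDS %d-%d\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand,
              nrow(x$exons), x$cds_start, x$cds_end))
  invisible(x)
}

# Genomic CDS segments (exons intersected with the CDS span), sorted by
# genomic start.
cds_segments <- function(model) {
  s <- pmax(model$exons$start, model$cds_start)
  e <- pmin(model$exons$end, model$cds_end)
  keep <- s <= e
  data.frame(start = s[keep], end = e[keep])
}

spliced_cds_length <- function(model) {
  seg <- cds_segments(model)
  sum(seg$end - seg$start + 1L)
}

#' Extract the spliced coding sequence of a transcript
#'
#' Concatenates the CDS portions of the exons in transcript order; on the
#' minus strand the concatenation is reverse-complemented so the result
#' always reads 5'->3' in coding orientation.
#'
#' @param model A [transcript_model()].
#' @param genome A named [Biostrings::DNAStringSet] (names are chromosomes).
#' @return A single character string whose length is divisible by 3.
#' @export
spliced_cds_sequence <- function(model, genome) {
  if (!model$chrom %in% names(genome))
    stop("chromosome ", model$chrom, " absent from genome")
  seg <- cds_segments(model)
  chrom_seq <- genome[[model$chrom]]
  parts <- vapply(seq_len(nrow(seg)), function(i)
    as.character(Biostrings::subseq(chrom_seq, seg$start[i], seg$end[i])),
    character(1L))
  cds <- paste0(parts, collapse = "")
  if (model$strand == "-")
    cds <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  if (nchar(cds) %% 3L != 0L)
    stop("malformed model: CDS length of transcript ", model$transcript_id,
         " (", nchar(cds), " nt) is not divisible by 3")
  cds
}

# Project a genomic position into a 1-based position along the spliced CDS
# (coding orientation). NA when the position does not hit a CDS segment.
genomic_to_cds <- function(model, pos) {
  seg <- cds_segments(model)
  len <- seg$end - seg$start + 1L
  before <- cumsum(c(0L, len))[seq_len(nrow(seg))]
  hit <- which(pos >= seg$start & pos <= seg$end)
  if (length(hit) == 0L) return(NA_integer_)
  plus0 <- before[hit] + (pos - seg$start[hit])   # 0-based along plus strand
  if (model$strand == "+") plus0 + 1L else sum(len) - plus0
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Apply sample variants to a spliced coding sequence
#'
#' Substitutes single-nucleotide variants into an already-extracted CDS,
#' projecting genomic coordinates through the exon chain. On minus-strand
#' transcripts the variant alleles (reported on the plus strand, as in VCF)
#' are complemented. Variants whose position does not fall in the CDS are
#' skipped with a warning; a reference-allele mismatch is an error. Only
#' SNVs are supported.
#'
#' @param cds Character CDS as returned by [spliced_cds_sequence()].
#' @param model The [transcript_model()] the CDS came from.
#' @param variants A data.frame with columns `chrom`, `pos`, `ref`, `alt`
#'   (single bases, plus-strand).
#' @return The substituted CDS string.
#' @export
apply_variants <- function(cds, model, variants) {
  if (is.null(variants) || nrow(variants) == 0L) return(cds)
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(variants)))
  if (any(nchar(variants$ref) != 1L | nchar(variants$alt) != 1L))
    stop("only SNVs are supported; indel-like record found")
  out <- strsplit(cds, "", fixed = TRUE)[[1L]]
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    if (v$chrom != model$chrom) next
    cpos <- genomic_to_cds(model, as.integer(v$pos))
    if (is.na(cpos)) {
      warning("variant at ", v$chrom, ":", v$pos,
              " outside CDS of ", model$transcript_id, "; skipped")
      next
    }
    ref_t <- if (model$strand == "+") v$ref else COMPLEMENT[[v$ref]]
    alt_t <- if (model$strand == "+") v$alt else COMPLEMENT[[v$alt]]
    if (out[cpos] != ref_t)
      stop("reference mismatch at ", v$chrom, ":", v$pos, " (transcript ",
           model$transcript_id, " position ", cpos, "): expected ", ref_t,
           ", CDS has ", out[cpos])
    out[cpos] <- alt_t
  }
  paste0(out, collapse = "")
}

#' Insert a novel exon into a transcript model
#'
#' Produces the novel isoform model obtained by splicing an additional exon
#' into an intron of the host transcript. The new transcript id carries a
#' `_novel` suffix and the coding span is widened to include the exon when
#' necessary.
#'
#' @param model Host [transcript_model()].
#' @param event A list/row with `exon_start` and `exon_end` (genomic, inside
#'   an intron of `model`).
#' @return The novel-isoform [transcript_model()].
#' @export
insert_novel_exon <- function(model, event) {
  es <- as.integer(event$exon_start); ee <- as.integer(event$exon_end)
  ex <- model$exons
  if (any(es <= ex$end & ee >= ex$start))
    stop("invalid event: novel exon ", es, "-", ee,
         " overlaps an existing exon of ", model$transcript_id)
  if (es <= min(ex$start) || ee >= max(ex$end))
    stop("invalid event: novel exon must lie strictly inside an intron of ",
         model$transcript_id)
  transcript_model(paste0(model$transcript_id, "_novel"), model$gene_id,
                   model$chrom, model$strand,
                   rbind(ex, data.frame(start = es, end = ee)),
                   min(model$cds_start, es), max(model$cds_end, ee))
}

#' Remove a previously inserted novel exon
#'
#' Inverse of [insert_novel_exon()] for events whose exon lies inside the
#' host coding span: drops the matching exon row and strips the `_novel`
#' suffix, recovering the host model.
#'
#' @inheritParams insert_novel_exon
#' @return The host [transcript_model()].
#' @export
remove_novel_exon <- function(model, event) {
  es <- as.integer(event$exon_start); ee <- as.integer(event$exon_end)
  hit <- which(model$exons$start == es & model$exons$end == ee)
  if (length(hit) != 1L)
    stop("exon ", es, "-", ee, " not found in ", model$transcript_id)
  ex <- model$exons[-hit, , drop = FALSE]
  transcript_model(sub("_novel$", "", model$transcript_id), model$gene_id,
                   model$chrom, model$strand, ex,
                   max(model$cds_start, min(ex$start)),
                   min(model$cds_end, max(ex$end)))
}

#' Translate a coding sequence
#'
#' Standard genetic code. Translation stops at the first stop codon; the
#' stop symbol is never part of the result. A stop before the final codon
#' yields the truncated protein together with a warning of class
#' `pgx_premature_stop` rather than an error, so peptide evidence upstream
#' of the stop is preserved.
#'
#' @param cds Character coding sequence; length must be divisible by 3.
#' @param require_start Require the sequence to begin with ATG (default
#'   TRUE).
#' @return The amino-acid sequence as a character string.
#' @export
translate_cds <- function(cds, require_start = TRUE) {
  if (nchar(cds) %% 3L != 0L)
    stop("CDS length ", nchar(cds), " not divisible by 3")
  if (require_start && substr(cds, 1L, 3L) != "ATG")
    stop("CDS does not start with ATG")
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                           no.init.codon = TRUE))
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at == -1L) return(aa)
  prot <- substr(aa, 1L, stop_at - 1L)
  if (stop_at < nchar(aa))
    warning(structure(class = c("pgx_premature_stop", "warning", "condition"),
                      list(message = paste0("premature stop codon at residue ",
                                            stop_at, "; protein truncated"),
                           call = sys.call(-1L))))
  prot
}
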