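#' Protein databases with provenance
#'
#' A protein database is a data.frame of translated protein records, one row
#' per protein, with machine-readable provenance:
#' * `canonical` — translation of a reference transcript model;
#' * `saav` — carries one or more single amino acid variants from a sample's
#'   non-synonymous SNVs;
#' * `novel_isoform` — translation of a transcript with a novel exon spliced
#'   in.
#' A fourth label, `confirmed_gene_model`, is reserved for transcripts whose
#' gene model is confirmed rather than altered; it is accepted by readers
#' but never emitted by this builder.
#'
#' Columns: `protein_id`, `sequence`, `provenance`, `source_transcript`,
#' `gene_id`, `sample_id` (`"reference"` for canonical records), `annotations`
#' (`;`-joined `pos:REF>ALT` residue substitutions, empty unless `saav`),
#' `premature_stop` (logical; TRUE when translation was truncated at an
#' internal stop codon).
#'
#' @name protein_db
NULL

protein_record <- function(protein_id, sequence, provenance, source_transcript,
                           gene_id, sample_id, annotations = "",
                           premature_stop = FALSE) {
  data.frame(protein_id = protein_id, sequence = sequence,
             provenance = provenance, source_transcript = source_transcript,
             gene_id = gene_id, sample_id = sample_id,
             annotations = annotations, premature_stop = premature_stop)
}

# Translate, capturing the premature-stop flag instead of surfacing the
# warning per record.
translate_flagged <- function(cds, require_start = TRUE) {
  truncated <- FALSE
  prot <- withCallingHandlers(
    translate_cds(cds, require_start = require_start),
    pgx_premature_stop = function(w) {
      truncated <<- TRUE
      invokeRestart("muffleWarning")
    })
  list(sequence = prot, premature_stop = truncated)
}

aa_substitutions <- function(ref_prot, alt_prot) {
  n <- min(nchar(ref_prot), nchar(alt_prot))
  r <- strsplit(substr(ref_prot, 1L, n), "")[[1L]]
  a <- strsplit(substr(alt_prot, 1L, n), "")[[1L]]
  d <- which(r != a)
  paste(sprintf("%d:%s>%s", d, r[d], a[d]), collapse = ";")
}

#' Translate the canonical proteome of a set of transcript models
#'
#' @param models A list of [transcript_model()] objects.
#' @param genome Named [Biostrings::DNAStringSet].
#' @return A canonical-only protein database (see [protein_db]).
#' @export
canonical_proteins <- function(models, genome) {
  recs <- lapply(models, function(m) {
    tr <- translate_flagged(spliced_cds_sequence(m, genome))
    protein_record(m$transcript_id, tr$sequence, "canonical",
                   m$transcript_id, m$gene_id, "reference",
                   premature_stop = tr$premature_stop)
  })
  db <- do.call(rbind, recs)
  rownames(db) <- NULL
  db
}

#' Build a sample-specific protein database
#'
#' The core proteogenomic step: the canonical proteome is augmented with
#' (1) variant proteins for every transcript hit by at least one
#' non-synonymous SNV of the sample (provenance `saav`; synonymous-only
#' transcripts add nothing), and (2) novel-isoform proteins for every novel
#' exon event listing the sample as carrying the exon. Multiple variants on
#' one transcript are applied jointly before translation, so a codon hit
#' twice reflects both substitutions. The canonical set is always a subset
#' of the result.
#'
#' @param models List of [transcript_model()] objects (the reference
#'   annotation).
#' @param genome Named [Biostrings::DNAStringSet].
#' @param variants Data.frame of the sample's SNVs (`chrom`, `pos`, `ref`,
#'   `alt`); may be NULL or empty.
#' @param events Data.frame of novel exon events (`gene_id`,
#'   `host_transcript`, `exon_start`, `exon_end`, `samples_present` as a
#'   `,`-joined string); may be NULL or empty.
#' @param sample_id The sample the database is built for.
#' @return A protein database data.frame (see [protein_db]).
#' @export
build_sample_database <- function(models, genome, variants, events, sample_id) {
  if (is.null(names(models)))
    names(models) <- vapply(models, `[[`, "", "transcript_id")
  db <- canonical_proteins(models, genome)
  canon_seq <- stats::setNames(db$sequence, db$source_transcript)

  if (!is.null(variants) && nrow(variants) > 0L) {
    for (m in models) {
      hit <- variants[variants$chrom == m$chrom &
                        !is.na(vapply(variants$pos, function(p)
                          genomic_to_cds(m, as.integer(p)), integer(1L))), ,
                      drop = FALSE]
      if (nrow(hit) == 0L) next
      cds <- spliced_cds_sequence(m, genome)
      mut <- apply_variants(cds, m, hit)
      tr <- translate_flagged(mut)
      if (tr$sequence == canon_seq[[m$transcript_id]] && !tr$premature_stop)
        next  # synonymous only
      ann <- aa_substitutions(canon_seq[[m$transcript_id]], tr$sequence)
      db <- rbind(db, protein_record(
        paste0(m$transcript_id, "_saav"), tr$sequence, "saav",
        m$transcript_id, m$gene_id, sample_id, ann, tr$premature_stop))
    }
  }

  if (!is.null(events) && nrow(events) > 0L) {
    for (i in seq_len(nrow(events))) {
      ev <- events[i, ]
      carriers <- strsplit(ev$samples_present, ",", fixed = TRUE)[[1L]]
      if (!sample_id %in% carriers) next
      host <- models[[ev$host_transcript]]
      if (is.null(host)) stop("unknown host transcript ", ev$host_transcript)
      iso <- insert_novel_exon(host, ev)
      tr <- translate_flagged(spliced_cds_sequence(iso, genome))
      db <- rbind(db, protein_record(
        iso$transcript_id, tr$sequence, "novel_isoform",
        host$transcript_id, host$gene_id, sample_id,
        premature_stop = tr$premature_stop))
    }
  }
  rownames(db) <- NULL
  db
}

#' Write a protein database as FASTA
#'
#' Headers follow the grammar
#' `>{protein_id}|{provenance}|{source_transcript}|{sample_id}[|{annotations}]`
#' so provenance survives a round trip through the file. Output is
#' deterministic: identical databases yield byte-identical files.
#'
#' @param db Protein database data.frame.
#' @param path Output FASTA path.
#' @export
write_protein_fasta <- function(db, path) {
  headers <- paste(db$protein_id, db$provenance, db$source_transcript,
                   db$sample_id, sep = "|")
  has_ann <- !is.na(db$annotations) & nzchar(db$annotations)
  headers[has_ann] <- paste(headers[has_ann], db$annotations[has_ann], sep = "|")
  seqs <- Biostrings::AAStringSet(db$sequence)
  names(seqs) <- headers
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

#' Read a protein database written by [write_protein_fasta()]
#'
#' @param path FASTA path.
#' @param tx2gene Optional named character vector mapping transcript ids to
#'   gene ids, used to restore the `gene_id` column (the FASTA header
#'   grammar does not carry it).
#' @return A protein database data.frame (without the `premature_stop`
#'   column, which is not serialised).
#' @export
read_protein_fasta <- function(path, tx2gene = NULL) {
  seqs <- Biostrings::readAAStringSet(path)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  bad <- lengths(parts) < 4L
  if (any(bad))
    stop("malformed protein FASTA header: ", names(seqs)[which(bad)[1L]])
  db <- data.frame(
    protein_id = vapply(parts, `[[`, "", 1L),
    sequence = as.character(seqs),
    provenance = vapply(parts, `[[`, "", 2L),
    source_transcript = vapply(parts, `[[`, "", 3L),
    sample_id = vapply(parts, `[[`, "", 4L),
    annotations = vapply(parts, function(p)
      if (length(p) >= 5L) p[[5L]] else "", ""))
  if (!is.null(tx2gene))
    db$gene_id <- unname(tx2gene[db$source_transcript])
  rownames(db) <- NULL
  db
}
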