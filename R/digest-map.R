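#' In-silico tryptic digestion
#'
#' Cleaves C-terminal to lysine (K) or arginine (R) except when the next
#' residue is proline (P), and returns every fragment spanning at most
#' `missed_cleavages` internal cleavage sites, filtered to the admissible
#' length range. Duplicate sequences are removed; order is deterministic
#' (by start position, then span).
#'
#' Defaults are the field-standard search settings for trypsin: up to two
#' missed cleavages, peptide length 7-35.
#'
#' @param protein Amino-acid string; an empty string yields an empty result.
#' @param missed_cleavages Maximum number of internal cleavage sites.
#' @param min_len,max_len Admissible peptide lengths (inclusive).
#' @return Character vector of peptides.
#' @export
digest <- function(protein, missed_cleavages = 2L, min_len = 7L, max_len = 35L) {
  stopifnot(missed_cleavages >= 0L, min_len >= 1L, min_len <= max_len)
  n <- nchar(protein)
  if (n == 0L) return(character(0L))
  aa <- strsplit(protein, "", fixed = TRUE)[[1L]]
  # cleavage after position i: aa[i] in {K,R} and aa[i+1] != P
  sites <- which(aa[-n] %in% c("K", "R") & aa[-1L] != "P")
  bounds <- c(0L, sites, n)
  nb <- length(bounds)
  peps <- character(0L)
  for (a in seq_len(nb - 1L)) {
    for (b in (a + 1L):min(nb, a + 1L + missed_cleavages)) {
      len <- bounds[b] - bounds[a]
      if (len >= min_len && len <= max_len)
        peps <- c(peps, substr(protein, bounds[a] + 1L, bounds[b]))
    }
  }
  unique(peps)
}

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

# I and L have identical mass and are indistinguishable by standard MS/MS;
# the default matching convention collapses them.
il_normalize <- function(x) gsub("I", "L", x, fixed = TRUE)

peptide_key <- function(x, il_equivalent = TRUE) {
  if (il_equivalent) il_normalize(x) else x
}

#' Build a peptide-to-provenance index over protein databases
#'
#' Digests every record of every database and indexes each peptide by the
#' genes, provenances and samples it can originate from. Lookups are
#' constant-time (hashed environment). Keys follow the matching convention:
#' by default isoleucine and leucine are collapsed before indexing, since
#' MS cannot distinguish them; `il_equivalent = FALSE` gives strict
#' matching.
#'
#' @param databases A list of protein databases (see [protein_db]); each
#'   must carry a `gene_id` column.
#' @param missed_cleavages,min_len,max_len Digestion parameters, see
#'   [digest()].
#' @param il_equivalent Collapse I/L when indexing (default TRUE).
#' @return An object of class `peptide_index`.
#' @export
build_peptide_index <- function(databases, missed_cleavages = 2L,
                                min_len = 7L, max_len = 35L,
                                il_equivalent = TRUE) {
  if (is.data.frame(databases)) databases <- list(databases)
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (db in databases) {
    if (nrow(db) == 0L) next
    if (!"gene_id" %in% names(db))
      stop("database lacks a gene_id column")
    for (i in seq_len(nrow(db))) {
      peps <- digest(db$sequence[i], missed_cleavages, min_len, max_len)
      keys <- peptide_key(peps, il_equivalent)
      for (k in keys) {
        entry <- if (exists(k, envir = env, inherits = FALSE))
          get(k, envir = env) else
          list(genes = character(0L), provenances = character(0L),
               samples = character(0L))
        entry$genes <- union(entry$genes, db$gene_id[i])
        entry$provenances <- union(entry$provenances, db$provenance[i])
        entry$samples <- union(entry$samples, db$sample_id[i])
        assign(k, entry, envir = env)
      }
    }
  }
  structure(list(env = env, il_equivalent = il_equivalent,
                 params = list(missed_cleavages = missed_cleavages,
                               min_len = min_len, max_len = max_len)),
            class = "peptide_index")
}

#' @export
print.peptide_index <- function(x, ...) {
  cat(sprintf("peptide_index: %d peptides (I/L %s)\n",
              length(ls(x$env)),
              if (x$il_equivalent) "equivalent" else "strict"))
  invisible(x)
}

index_lookup <- function(index, peptide) {
  k <- peptide_key(peptide, index$il_equivalent)
  if (exists(k, envir = index$env, inherits = FALSE))
    get(k, envir = index$env) else NULL
}

#' Classify observed peptides as reference or non-reference
#'
#' Reproduces the peptide taxonomy of sample-specific database searches:
#' a peptide found in the canonical index is `reference_unique` when it
#' maps to exactly one gene and `reference_ambiguous` otherwise; a peptide
#' absent from the canonical index but present in at least one sample
#' database is non-reference — `nonref_novel_isoform` if any supporting
#' record is a novel isoform (the isoform label wins ties with variant
#' records, deterministically), otherwise `nonref_saav`. A peptide found
#' nowhere is reported as `unmatched`, not classified.
#'
#' @param peptides Character vector of observed peptide sequences.
#' @param sample_index [build_peptide_index()] over all sample databases.
#' @param canonical_index [build_peptide_index()] over the canonical
#'   database only; must use the same digestion and matching conventions.
#' @return A data.frame with columns `peptide`, `category`, `genes`
#'   (comma-joined, sorted), `n_genes`, `supporting_samples` (comma-joined,
#'   sorted), `n_supporting_samples`.
#' @export
classify_peptides <- function(peptides, sample_index, canonical_index) {
  stopifnot(identical(sample_index$il_equivalent,
                      canonical_index$il_equivalent),
            identical(sample_index$params, canonical_index$params))
  bad <- grepl(paste0("[^", paste(AA_ALPHABET, collapse = ""), "]"), peptides)
  if (any(bad))
    stop("peptide contains non-amino-acid symbols: ", peptides[which(bad)[1L]])
  rows <- lapply(peptides, function(p) {
    canon <- index_lookup(canonical_index, p)
    if (!is.null(canon)) {
      category <- if (length(canon$genes) == 1L)
        "reference_unique" else "reference_ambiguous"
      genes <- canon$genes
      samples <- index_lookup(sample_index, p)$samples
    } else {
      hit <- index_lookup(sample_index, p)
      if (is.null(hit)) {
        category <- "unmatched"; genes <- character(0L); samples <- character(0L)
      } else {
        category <- if ("novel_isoform" %in% hit$provenances)
          "nonref_novel_isoform" else "nonref_saav"
        genes <- hit$genes
        samples <- setdiff(hit$samples, "reference")
      }
    }
    data.frame(peptide = p, category = category,
               genes = paste(sort(genes), collapse = ","),
               n_genes = length(genes),
               supporting_samples = paste(sort(samples), collapse = ","),
               n_supporting_samples = length(samples))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Peptides unique to a novel isoform
#'
#' Digests the novel-isoform proteins generated by an exon-insertion event
#' and returns those peptides that no canonical and no variant (saav)
#' protein can produce — the junction-spanning and exon-internal peptides
#' that make the isoform detectable by MS.
#'
#' @param event Event row with `host_transcript`.
#' @param databases List of sample protein databases (with `gene_id`).
#' @inheritParams build_peptide_index
#' @return Sorted character vector of isoform-unique peptides.
#' @export
peptides_for_novel_exon <- function(event, databases, missed_cleavages = 2L,
                                    min_len = 7L, max_len = 35L,
                                    il_equivalent = TRUE) {
  if (is.data.frame(databases)) databases <- list(databases)
  all_db <- do.call(rbind, databases)
  if (is.null(all_db) || nrow(all_db) == 0L) return(character(0L))
  iso <- all_db[all_db$provenance == "novel_isoform" &
                  all_db$source_transcript == event$host_transcript, ,
                drop = FALSE]
  if (nrow(iso) == 0L) return(character(0L))
  other <- all_db[all_db$provenance %in% c("canonical", "saav"), , drop = FALSE]
  other_keys <- unique(peptide_key(unlist(lapply(
    unique(other$sequence), digest, missed_cleavages, min_len, max_len)),
    il_equivalent))
  iso_peps <- unique(unlist(lapply(unique(iso$sequence), digest,
                                   missed_cleavages, min_len, max_len)))
  keep <- !(peptide_key(iso_peps, il_equivalent) %in% other_keys)
  sort(iso_peps[keep])
}
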