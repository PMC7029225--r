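#' Simulation configuration
#'
#' Defines the study conditions the generator emulates: a two-group
#' lung-tissue design of 10 cases and 8 controls, negative-binomial PSM
#' counts with group fold-changes on a fraction of genes, sample-private
#' non-synonymous SNVs, and one cryptic in-frame exon (default 714 nt, i.e.
#' 238 codons) hidden in an intron of a minus-strand host gene and included
#' predominantly in case samples. All defaults live here and nowhere else.
#'
#' @param n_case,n_control Group sizes (default 10 cases, 8 controls).
#' @param n_genes Number of simulated genes (>= 1).
#' @param frac_de Fraction of genes with a true protein-level group effect.
#' @param log2fc_magnitude Absolute log2 fold-change of true effects.
#' @param nb_mean Mean PSM count per peptide in the baseline group.
#' @param nb_dispersion NB dispersion `phi` (variance = mu + mu^2 * phi).
#' @param variant_rate Per-gene probability of planting one sample-private
#'   non-synonymous SNV.
#' @param inclusion_bias Probability that a case sample carries the novel
#'   exon; controls carry it with probability `1 - inclusion_bias`.
#' @param concordant_fraction Fraction of true-DE genes whose transcript
#'   effect shares the protein direction (the rest get the opposite sign).
#' @param novel_exon_length Cryptic exon length in nt; must be divisible
#'   by 3 (in-frame).
#' @param n_pep_per_gene Quantified unique peptides per gene.
#' @param usage_total_mean Mean total junction evidence per sample for the
#'   exon-usage simulation.
#' @param usage_psi_included,usage_psi_background Inclusion probability of
#'   the novel exon in carriers vs non-carriers.
#' @param edge_prob Background interaction-edge probability between gene
#'   pairs.
#' @param seed Integer seed; every generator output is a pure function of
#'   the configuration including this seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_case = 10L, n_control = 8L, n_genes = 50L,
                       frac_de = 0.2, log2fc_magnitude = 2,
                       nb_mean = 30, nb_dispersion = 0.3,
                       variant_rate = 0.3, inclusion_bias = 0.9,
                       concordant_fraction = 0.8,
                       novel_exon_length = 714L, n_pep_per_gene = 4L,
                       usage_total_mean = 60, usage_psi_included = 0.5,
                       usage_psi_background = 0.02, edge_prob = 0.05,
                       seed = 1L) {
  stopifnot(n_case >= 1L, n_control >= 1L, n_genes >= 1L,
            frac_de >= 0, frac_de <= 1,
            is.finite(log2fc_magnitude), log2fc_magnitude != 0,
            nb_mean > 0, nb_dispersion > 0,
            variant_rate >= 0, variant_rate <= 1,
            inclusion_bias >= 0, inclusion_bias <= 1,
            concordant_fraction >= 0, concordant_fraction <= 1,
            novel_exon_length %% 3L == 0L, novel_exon_length >= 3L,
            n_pep_per_gene >= 1L, edge_prob >= 0, edge_prob <= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("sim_config: %d case / %d control, %d genes ",
                     "(%.0f%% DE at |log2FC| = %g), seed %d\n"),
              x$n_case, x$n_control, x$n_genes, 100 * x$frac_de,
              x$log2fc_magnitude, x$seed))
  invisible(x)
}

#' Sample ids and group design implied by a configuration
#' @param config A [sim_config()].
#' @return Design data.frame (`sample_id`, `group`).
#' @export
sim_design <- function(config) {
  data.frame(
    sample_id = c(sprintf("case%02d", seq_len(config$n_case)),
                  sprintf("ctrl%02d", seq_len(config$n_control))),
    group = c(rep("case", config$n_case), rep("control", config$n_control)))
}

# ---- sequence-level helpers -------------------------------------------------

# Codons per amino acid, stop codons excluded; deterministic order.
codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), gc)
}

# A protein built from tryptic segments: each internal segment ends in K/R
# and no segment starts with P, so cleavage sites are unambiguous and
# peptides fall in the standard 7-35 length window.
random_protein <- function(n_segments, rng_alphabet = AA_ALPHABET) {
  body_aa <- setdiff(rng_alphabet, c("K", "R", "P"))
  segs <- vapply(seq_len(n_segments), function(i) {
    len <- sample(7:12, 1L)
    core <- paste(sample(body_aa, len - 1L, replace = TRUE), collapse = "")
    paste0(core, sample(c("K", "R"), 1L))
  }, character(1L))
  paste0("M", substring(paste(segs, collapse = ""), 2L))
}

reverse_translate <- function(protein, codons = codon_table()) {
  aa <- strsplit(protein, "", fixed = TRUE)[[1L]]
  paste(vapply(aa, function(a) {
    cs <- codons[[a]]
    cs[sample.int(length(cs), 1L)]
  }, character(1L)), collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

# Inverse of genomic_to_cds: genomic position of a 1-based CDS coordinate.
cds_to_genomic <- function(model, cpos) {
  seg <- cds_segments(model)
  len <- seg$end - seg$start + 1L
  before <- cumsum(c(0L, len))[seq_len(nrow(seg))]
  total <- sum(len)
  plus0 <- if (model$strand == "+") cpos - 1L else total - cpos
  i <- findInterval(plus0, before)
  seg$start[i] + (plus0 - before[i])
}

# ---- generators -------------------------------------------------------------

#' Generate a toy genome and reference transcript models
#'
#' Builds `n_genes` multi-exon protein-coding genes on one chromosome.
#' Every CDS starts with ATG, ends with a stop codon, has codon-aligned
#' exon boundaries, and gene 1 — the novel-exon host, mirroring a
#' minus-strand discovery gene — is always on the minus strand with a
#' stop-free cryptic exon of `novel_exon_length` nt physically embedded in
#' its first intron but absent from the annotation. Output is a pure
#' function of the configuration.
#'
#' @param config A [sim_config()].
#' @return List with `genome` (DNAStringSet), `models` (named list of
#'   [transcript_model()]), and `cryptic_exon` (data.frame describing the
#'   unannotated exon: `gene_id`, `host_transcript`, `exon_start`,
#'   `exon_end`, `insertion_index`, `insert_protein`).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  codons <- codon_table()
  chrom <- "chr1"
  pieces <- character(0L)
  cursor <- 0L
  models <- list()
  cryptic <- NULL

  spacer <- function(n) {
    pieces <<- c(pieces, random_dna(n))
    cursor <<- cursor + n
  }

  for (g in seq_len(config$n_genes)) {
    gene_id <- sprintf("GENE%03d", g)
    tx_id <- sprintf("TX%03d", g)
    is_host <- g == 1L
    strand <- if (is_host) "-" else sample(c("+", "-"), 1L)
    n_seg <- sample(14:20, 1L)
    protein <- random_protein(n_seg)
    cds <- paste0(reverse_translate(protein, codons), "TAA")
    n_exons <- sample(2:4, 1L)
    n_codons <- nchar(cds) %/% 3L
    cuts <- sort(sample(seq(8L, n_codons - 8L), n_exons - 1L)) * 3L
    bounds <- c(0L, cuts, nchar(cds))
    chunks <- substring(cds, bounds[-length(bounds)] + 1L, bounds[-1L])

    intron_len <- sample(150:400, n_exons - 1L, replace = TRUE)
    insert_protein <- NULL
    insert_cds <- NULL
    if (is_host) {
      # first intron (coding order) hosts the cryptic exon
      insert_protein <- random_protein(config$novel_exon_length %/% 3L %/% 9L + 1L)
      insert_protein <- substr(insert_protein, 1L,
                               config$novel_exon_length %/% 3L)
      # pad deterministically if the segment construction came up short
      while (nchar(insert_protein) < config$novel_exon_length %/% 3L)
        insert_protein <- paste0(insert_protein, "A")
      insert_cds <- reverse_translate(insert_protein, codons)
      intron_len[1L] <- config$novel_exon_length + 200L
    }

    spacer(100L)
    # genomic layout: plus strand = coding order; minus strand = reversed
    # chunk order, each chunk reverse-complemented
    coding_order <- seq_len(n_exons)
    genomic_order <- if (strand == "+") coding_order else rev(coding_order)
    exon_coords <- data.frame(start = integer(n_exons), end = integer(n_exons))
    cryptic_interval <- NULL
    for (k in seq_along(genomic_order)) {
      ci <- genomic_order[k]
      seq_k <- if (strand == "+") chunks[ci] else revcomp(chunks[ci])
      exon_coords$start[ci] <- cursor + 1L
      exon_coords$end[ci] <- cursor + nchar(seq_k)
      pieces <- c(pieces, seq_k)
      cursor <- cursor + nchar(seq_k)
      if (k < n_exons) {
        # intron following this exon in genomic order sits between
        # coding-order exons min/max of the adjacent pair
        intron_idx <- if (strand == "+") ci else genomic_order[k + 1L]
        ilen <- intron_len[intron_idx]
        if (is_host && intron_idx == 1L) {
          # embed the cryptic exon 100 nt into the intron, minus-strand
          # oriented like its host
          left <- 100L
          iseq <- paste0(random_dna(left), revcomp(insert_cds),
                         random_dna(ilen - left - nchar(insert_cds)))
          cryptic_interval <- c(cursor + left + 1L,
                                cursor + left + nchar(insert_cds))
          pieces <- c(pieces, iseq)
          cursor <- cursor + ilen
        } else {
          pieces <- c(pieces, random_dna(ilen))
          cursor <- cursor + ilen
        }
      }
    }
    spacer(100L)

    models[[tx_id]] <- transcript_model(
      tx_id, gene_id, chrom, strand, exon_coords,
      min(exon_coords$start), max(exon_coords$end))
    if (is_host)
      cryptic <- data.frame(
        gene_id = gene_id, host_transcript = tx_id,
        exon_start = cryptic_interval[1L], exon_end = cryptic_interval[2L],
        insertion_index = 2L, insert_protein = insert_protein)
  }

  genome <- Biostrings::DNAStringSet(
    stats::setNames(paste(pieces, collapse = ""), chrom))
  list(genome = genome, models = models, cryptic_exon = cryptic)
}

#' Generate sample-private non-synonymous SNVs
#'
#' For each gene, with probability `variant_rate`, plants one missense SNV
#' in the CDS of one randomly chosen sample (never touching the start
#' codon and never creating a stop codon), so translating the mutated CDS
#' differs from the reference protein at exactly one residue. The planted
#' single-amino-acid variant is recorded as ground truth.
#'
#' @param sim Output of [generate_genome()].
#' @param config A [sim_config()].
#' @return List with `variants` (data.frame `chrom`, `pos`, `ref`, `alt`,
#'   `sample_id`) and `saav_truth` (data.frame `gene_id`, `transcript_id`,
#'   `codon`, `ref_aa`, `alt_aa`, `sample_id`).
#' @export
generate_variants <- function(sim, config) {
  stopifnot(length(sim$models) >= 1L)
  set.seed(config$seed + 1L)
  design <- sim_design(config)
  gc <- Biostrings::GENETIC_CODE
  vrows <- list(); trows <- list()
  for (m in sim$models) {
    if (stats::runif(1L) >= config$variant_rate) next
    cds <- spliced_cds_sequence(m, sim$genome)
    n_codons <- nchar(cds) %/% 3L
    placed <- FALSE
    for (attempt in seq_len(50L)) {
      codon_i <- sample(2:(n_codons - 1L), 1L)
      within <- sample(1:3, 1L)
      cpos <- (codon_i - 1L) * 3L + within
      codon <- substr(cds, (codon_i - 1L) * 3L + 1L, codon_i * 3L)
      ref_base <- substr(cds, cpos, cpos)
      ref_aa <- gc[[codon]]
      for (alt_base in sample(setdiff(c("A", "C", "G", "T"), ref_base))) {
        alt_codon <- codon
        substr(alt_codon, within, within) <- alt_base
        alt_aa <- gc[[alt_codon]]
        if (alt_aa != ref_aa && alt_aa != "*") {
          gpos <- cds_to_genomic(m, cpos)
          plus_ref <- if (m$strand == "+") ref_base else COMPLEMENT[[ref_base]]
          plus_alt <- if (m$strand == "+") alt_base else COMPLEMENT[[alt_base]]
          sample_id <- sample(design$sample_id, 1L)
          vrows[[length(vrows) + 1L]] <- data.frame(
            chrom = m$chrom, pos = gpos, ref = plus_ref, alt = plus_alt,
            sample_id = sample_id)
          trows[[length(trows) + 1L]] <- data.frame(
            gene_id = m$gene_id, transcript_id = m$transcript_id,
            codon = codon_i, ref_aa = ref_aa, alt_aa = alt_aa,
            sample_id = sample_id)
          placed <- TRUE
          break
        }
      }
      if (placed) break
    }
  }
  list(variants = if (length(vrows)) do.call(rbind, vrows) else
         data.frame(chrom = character(0L), pos = integer(0L),
                    ref = character(0L), alt = character(0L),
                    sample_id = character(0L)),
       saav_truth = if (length(trows)) do.call(rbind, trows) else
         data.frame(gene_id = character(0L), transcript_id = character(0L),
                    codon = integer(0L), ref_aa = character(0L),
                    alt_aa = character(0L), sample_id = character(0L)))
}

#' Generate the novel-exon event and per-sample inclusion flags
#'
#' Uses the cryptic exon planted by [generate_genome()] (or, absent that,
#' searches for an intron long enough to host one, failing with the gene
#' name if none exists). Case samples carry the exon with probability
#' `inclusion_bias`, controls with probability `1 - inclusion_bias`.
#'
#' @param sim Output of [generate_genome()].
#' @param config A [sim_config()].
#' @return List with `events` (single-row data.frame `gene_id`,
#'   `host_transcript`, `exon_start`, `exon_end`, `insertion_index`,
#'   `samples_present`) and `inclusion` (data.frame `sample_id`,
#'   `included`).
#' @export
generate_novel_exon <- function(sim, config) {
  set.seed(config$seed + 2L)
  design <- sim_design(config)
  ce <- sim$cryptic_exon
  if (is.null(ce)) {
    for (m in sim$models) {
      gaps <- m$exons$start[-1L] - m$exons$end[-nrow(m$exons)] - 1L
      if (any(gaps >= config$novel_exon_length + 2L)) {
        i <- which(gaps >= config$novel_exon_length + 2L)[1L]
        ce <- data.frame(gene_id = m$gene_id, host_transcript = m$transcript_id,
                         exon_start = m$exons$end[i] + 2L,
                         exon_end = m$exons$end[i] + 1L + config$novel_exon_length,
                         insertion_index = i + 1L,
                         insert_protein = NA_character_)
        break
      }
    }
    if (is.null(ce))
      stop("no intron long enough to host a ", config$novel_exon_length,
           "-nt exon in any gene (first gene: ",
           sim$models[[1L]]$gene_id, ")")
  }
  p_incl <- ifelse(design$group == "case", config$inclusion_bias,
                   1 - config$inclusion_bias)
  included <- stats::runif(nrow(design)) < p_incl
  events <- ce[, c("gene_id", "host_transcript", "exon_start", "exon_end",
                   "insertion_index")]
  events$samples_present <- paste(design$sample_id[included], collapse = ",")
  list(events = events,
       inclusion = data.frame(sample_id = design$sample_id,
                              included = included))
}

# Choose the true-DE genes and their signed log2 fold-changes. The host
# gene is left non-DE so the novel-exon scenario stays orthogonal.
assign_de_genes <- function(sim, config) {
  set.seed(config$seed + 4L)
  gene_ids <- vapply(sim$models, `[[`, "", "gene_id")
  candidates <- setdiff(unname(gene_ids), "GENE001")
  n_de <- min(round(config$frac_de * config$n_genes), length(candidates))
  de <- sort(sample(candidates, n_de))
  data.frame(gene_id = de,
             log2fc = sample(c(-1, 1), n_de, replace = TRUE) *
               config$log2fc_magnitude)
}

#' Generate the peptide-identification (PSM) table
#'
#' Emulates search-engine output against the sample-specific databases.
#' Quantified reference peptides are drawn from the canonical digests
#' (gene-unique peptides only, `n_pep_per_gene` per gene); variant
#' peptides from each SAAV carrier's database; novel-isoform-unique
#' peptides from the exon carriers' databases. Counts are negative
#' binomial with mean `nb_mean * 2^(log2fc)` in cases for true-DE genes;
#' peptides a sample's database cannot produce never receive counts in
#' that sample.
#'
#' @param sample_dbs Named list of per-sample protein databases.
#' @param canonical_db Canonical protein database ([canonical_proteins()]).
#' @param de_truth Data.frame `gene_id`, `log2fc` of true effects.
#' @param events Novel-exon events (see [generate_novel_exon()]).
#' @param config A [sim_config()].
#' @return List with `psm` (data.frame `peptide`, `sample`, `psm_count`,
#'   nonzero rows only) and `truth` (peptide-level provenance:
#'   `peptide`, `origin`, `gene_id`).
#' @export
generate_psm_table <- function(sample_dbs, canonical_db, de_truth, events,
                               config) {
  set.seed(config$seed + 3L)
  design <- sim_design(config)
  samples <- design$sample_id
  is_case <- design$group == "case"
  size <- 1 / config$nb_dispersion
  lfc <- stats::setNames(rep(0, length(unique(canonical_db$gene_id))),
                         sort(unique(canonical_db$gene_id)))
  lfc[de_truth$gene_id] <- de_truth$log2fc

  # gene-unique canonical peptides
  canon_digests <- lapply(canonical_db$sequence, digest)
  names(canon_digests) <- canonical_db$gene_id
  pep_gene <- data.frame(
    peptide = unlist(canon_digests, use.names = FALSE),
    gene_id = rep(canonical_db$gene_id, lengths(canon_digests)))
  pep_gene$key <- il_normalize(pep_gene$peptide)
  key_genes <- tapply(pep_gene$gene_id, pep_gene$key,
                      function(g) length(unique(g)))
  uniq <- pep_gene[key_genes[pep_gene$key] == 1L, , drop = FALSE]

  rows <- list(); truth <- list()
  for (g in names(canon_digests)) {
    peps <- sort(unique(uniq$peptide[uniq$gene_id == g]))
    peps <- utils::head(peps, config$n_pep_per_gene)
    if (length(peps) == 0L) next
    mu <- config$nb_mean * 2^(ifelse(is_case, lfc[[g]], 0))
    for (p in peps) {
      cnt <- stats::rnbinom(length(samples), size = size, mu = mu)
      keep <- cnt > 0
      if (any(keep))
        rows[[length(rows) + 1L]] <- data.frame(
          peptide = p, sample = samples[keep], psm_count = cnt[keep])
      truth[[length(truth) + 1L]] <- data.frame(
        peptide = p, origin = "reference", gene_id = g)
    }
  }

  canon_keys <- unique(pep_gene$key)

  # SAAV peptides: those a carrier's saav record produces beyond canonical
  for (s in samples) {
    db <- sample_dbs[[s]]
    sv <- db[db$provenance == "saav", , drop = FALSE]
    for (i in seq_len(nrow(sv))) {
      peps <- digest(sv$sequence[i])
      peps <- peps[!(il_normalize(peps) %in% canon_keys)]
      for (p in sort(peps)) {
        cnt <- stats::rnbinom(1L, size = size, mu = config$nb_mean)
        if (cnt > 0)
          rows[[length(rows) + 1L]] <- data.frame(
            peptide = p, sample = s, psm_count = cnt)
        truth[[length(truth) + 1L]] <- data.frame(
          peptide = p, origin = "saav", gene_id = sv$gene_id[i])
      }
    }
  }

  # novel-isoform-unique peptides, carriers only
  if (!is.null(events) && nrow(events) > 0L) {
    iso_peps <- peptides_for_novel_exon(events[1L, ], sample_dbs)
    iso_peps <- utils::head(iso_peps, 8L)
    carriers <- strsplit(events$samples_present[1L], ",", fixed = TRUE)[[1L]]
    for (p in iso_peps) {
      for (s in carriers) {
        cnt <- stats::rnbinom(1L, size = size, mu = config$nb_mean)
        if (cnt > 0)
          rows[[length(rows) + 1L]] <- data.frame(
            peptide = p, sample = s, psm_count = cnt)
      }
      truth[[length(truth) + 1L]] <- data.frame(
        peptide = p, origin = "novel_isoform", gene_id = events$gene_id[1L])
    }
  }

  psm <- do.call(rbind, rows)
  psm <- psm[order(psm$peptide, psm$sample), , drop = FALSE]
  rownames(psm) <- NULL
  tr <- unique(do.call(rbind, truth))
  rownames(tr) <- NULL
  list(psm = psm, truth = tr)
}

#' Generate a transcript count matrix with controllable concordance
#'
#' Negative-binomial transcript counts per gene and sample. A fraction
#' `concordant_fraction` of true-DE genes receives a transcript effect of
#' the same sign and magnitude as its protein effect; the remainder get
#' the opposite sign, so direction concordance is exactly controlled by
#' construction.
#'
#' @param sim Output of [generate_genome()].
#' @param de_truth Data.frame `gene_id`, `log2fc`.
#' @param config A [sim_config()].
#' @return List with `counts` (a [count_matrix()], genes x samples) and
#'   `truth` (data.frame `gene_id`, `tx_log2fc`, `concordant`).
#' @export
generate_transcript_counts <- function(sim, de_truth, config) {
  set.seed(config$seed + 5L)
  design <- sim_design(config)
  gene_ids <- sort(unname(vapply(sim$models, `[[`, "", "gene_id")))
  is_case <- design$group == "case"
  size <- 1 / config$nb_dispersion
  concord <- stats::runif(nrow(de_truth)) < config$concordant_fraction
  tx_lfc <- stats::setNames(rep(0, length(gene_ids)), gene_ids)
  tx_lfc[de_truth$gene_id] <- ifelse(concord, de_truth$log2fc,
                                     -de_truth$log2fc)
  m <- t(vapply(gene_ids, function(g) {
    mu <- config$nb_mean * 2^(ifelse(is_case, tx_lfc[[g]], 0))
    stats::rnbinom(nrow(design), size = size, mu = mu)
  }, numeric(nrow(design))))
  colnames(m) <- design$sample_id
  truth <- data.frame(gene_id = de_truth$gene_id,
                      tx_log2fc = unname(tx_lfc[de_truth$gene_id]),
                      concordant = concord)
  list(counts = count_matrix(m), truth = truth)
}

#' Generate per-sample inclusion/total evidence for the novel exon
#'
#' Total junction evidence per sample is negative binomial; inclusion
#' evidence is binomial with inclusion probability `usage_psi_included`
#' for exon carriers and `usage_psi_background` otherwise.
#'
#' @param inclusion Data.frame `sample_id`, `included` (from
#'   [generate_novel_exon()]).
#' @param config A [sim_config()].
#' @return Data.frame `sample_id`, `inclusion`, `total`.
#' @export
generate_exon_usage_counts <- function(inclusion, config) {
  set.seed(config$seed + 6L)
  total <- stats::rnbinom(nrow(inclusion), size = 5,
                          mu = config$usage_total_mean)
  psi <- ifelse(inclusion$included, config$usage_psi_included,
                config$usage_psi_background)
  inc <- stats::rbinom(nrow(inclusion), total, psi)
  data.frame(sample_id = inclusion$sample_id, inclusion = inc, total = total)
}

# Synthetic interaction edges (background Erdos-Renyi plus a clique on the
# true-DE genes) and gene sets (one enriched in the DE genes plus random
# decoys). Both stand in for external interaction/annotation databases and
# are labelled synthetic throughout.
generate_network_annotation <- function(sim, de_truth, config) {
  set.seed(config$seed + 7L)
  genes <- sort(unname(vapply(sim$models, `[[`, "", "gene_id")))
  pairs <- utils::combn(genes, 2L)
  pick <- stats::runif(ncol(pairs)) < config$edge_prob
  bg <- data.frame(gene_a = pairs[1L, pick], gene_b = pairs[2L, pick],
                   evidence = sample(c("database", "experimental", "both"),
                                     sum(pick), replace = TRUE))
  edges <- bg
  if (nrow(de_truth) >= 2L) {
    cl <- utils::combn(sort(de_truth$gene_id), 2L)
    edges <- rbind(edges, data.frame(gene_a = cl[1L, ], gene_b = cl[2L, ],
                                     evidence = "experimental"))
  }
  edges <- as_edge_list(edges)
  sets <- list(SET_DE = sort(unique(c(
    de_truth$gene_id, sample(genes, min(3L, length(genes)))))))
  for (i in seq_len(8L))
    sets[[sprintf("SET%02d", i)]] <- sort(sample(genes, min(8L, length(genes))))
  gene_sets <- data.frame(
    set_id = rep(names(sets), lengths(sets)),
    gene_id = unlist(sets, use.names = FALSE))
  list(edges = edges, gene_sets = gene_sets)
}

#' Simulate a complete toy proteogenomic study
#'
#' Runs every generator under one configuration and, when `outdir` is
#' given, writes the full set of study inputs: genome FASTA, annotation
#' GTF, variants VCF, novel-exon events TSV, PSM TSV, transcript-count
#' TSV, design TSV, exon-usage TSV, synthetic interaction-edge TSV,
#' synthetic gene-set TSV, and a ground-truth JSON recording every planted
#' event. All outputs are pure functions of the configuration; rerunning
#' with the same configuration reproduces them byte for byte.
#'
#' @param config A [sim_config()].
#' @param outdir Optional output directory (created if missing).
#' @return Invisibly, a list with all in-memory pieces: `genome`,
#'   `models`, `design`, `variants`, `events`, `sample_dbs`,
#'   `canonical_db`, `psm`, `tx_counts`, `usage_counts`, `edges`,
#'   `gene_sets`, `ground_truth`, and `paths` when written.
#' @export
simulate_study <- function(config = sim_config(), outdir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  gen <- generate_genome(config)
  design <- sim_design(config)
  vr <- generate_variants(gen, config)
  ne <- generate_novel_exon(gen, config)
  de_truth <- assign_de_genes(gen, config)

  canonical_db <- canonical_proteins(gen$models, gen$genome)
  sample_dbs <- lapply(stats::setNames(design$sample_id, design$sample_id),
                       function(s) build_sample_database(
                         gen$models, gen$genome,
                         vr$variants[vr$variants$sample_id == s, , drop = FALSE],
                         ne$events, s))

  pt <- generate_psm_table(sample_dbs, canonical_db, de_truth, ne$events,
                           config)
  tc <- generate_transcript_counts(gen, de_truth, config)
  uc <- generate_exon_usage_counts(ne$inclusion, config)
  net <- generate_network_annotation(gen, de_truth, config)

  ground_truth <- list(
    design = design,
    de_proteins = de_truth,
    saav_events = vr$saav_truth,
    novel_exon = ne$events[, c("gene_id", "host_transcript", "exon_start",
                               "exon_end", "insertion_index")],
    novel_exon_inclusion = ne$inclusion,
    transcript_truth = tc$truth,
    peptide_truth = pt$truth,
    enriched_set = "SET_DE")

  out <- list(config = config, genome = gen$genome, models = gen$models,
              cryptic_exon = gen$cryptic_exon, design = design,
              variants = vr$variants, events = ne$events,
              inclusion = ne$inclusion, canonical_db = canonical_db,
              sample_dbs = sample_dbs, psm = pt$psm,
              tx_counts = tc$counts, usage_counts = uc,
              edges = net$edges, gene_sets = net$gene_sets,
              ground_truth = ground_truth)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      genome = file.path(outdir, "genome.fa"),
      gtf = file.path(outdir, "annotation.gtf"),
      vcf = file.path(outdir, "variants.vcf"),
      events = file.path(outdir, "novel_exons.tsv"),
      psm = file.path(outdir, "psm.tsv"),
      tx_counts = file.path(outdir, "transcript_counts.tsv"),
      design = file.path(outdir, "design.tsv"),
      usage = file.path(outdir, "exon_usage.tsv"),
      edges = file.path(outdir, "edges.tsv"),
      gene_sets = file.path(outdir, "gene_sets.tsv"),
      ground_truth = file.path(outdir, "ground_truth.json"))
    Biostrings::writeXStringSet(gen$genome, paths$genome, width = 70L)
    write_annotation_gtf(gen$models, paths$gtf)
    write_variants_vcf(vr$variants, design$sample_id, paths$vcf)
    write_tsv(ne$events, paths$events)
    write_tsv(pt$psm, paths$psm)
    write_count_matrix(tc$counts, paths$tx_counts)
    write_design(design, paths$design)
    write_tsv(uc, paths$usage)
    write_tsv(net$edges, paths$edges)
    write_tsv(net$gene_sets, paths$gene_sets)
    jsonlite::write_json(ground_truth, paths$ground_truth, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    out$paths <- paths
  }
  invisible(out)
}
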