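#' Pipeline run configuration
#'
#' One object holds every knob of the end-to-end run: the simulation
#' configuration, digestion parameters, the presence and exclusivity
#' filters, test thresholds, and which stages to execute. Stages not
#' listed in `stages` are skipped and their outputs are loaded from a
#' previous run in the same `outdir` (stage-level resumability).
#'
#' @param outdir Output directory for all intermediates and the report.
#' @param sim A [sim_config()]; its seed drives every stochastic stage.
#' @param missed_cleavages,min_len,max_len Digestion parameters.
#' @param il_equivalent I/L matching convention for classification.
#' @param min_psm,min_case,min_control Consistent-expression filter
#'   ([filter_consistent()]).
#' @param excl_min_total,excl_min_samples Exclusivity rule
#'   ([exclusive_nonref_peptides()]).
#' @param alpha_de FDR threshold for DE calls and enrichment input.
#' @param alpha_network Stricter FDR threshold for the network view.
#' @param n_perm Permutations for the connectivity test.
#' @param stages Character vector of stages to execute, a subset of
#'   `simulate`, `build_db`, `classify`, `quantify`, `detest`, `usage`,
#'   `network`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(outdir, sim = sim_config(),
                       missed_cleavages = 2L, min_len = 7L, max_len = 35L,
                       il_equivalent = TRUE,
                       min_psm = 3L, min_case = 5L, min_control = 4L,
                       excl_min_total = 5L, excl_min_samples = 4L,
                       alpha_de = 0.05, alpha_network = 0.01,
                       n_perm = 999L,
                       stages = c("simulate", "build_db", "classify",
                                  "quantify", "detest", "usage", "network")) {
  stopifnot(inherits(sim, "sim_config"),
            all(stages %in% c("simulate", "build_db", "classify", "quantify",
                              "detest", "usage", "network")))
  structure(as.list(environment()), class = "run_config")
}

pipeline_paths <- function(config) {
  out <- config$outdir
  list(sim = file.path(out, "sim"),
       dbs = file.path(out, "dbs"),
       res = file.path(out, "results"),
       classification = file.path(out, "results", "classification.tsv"),
       gene_matrix = file.path(out, "results", "gene_counts.tsv"),
       gene_matrix_filtered = file.path(out, "results",
                                        "gene_counts_filtered.tsv"),
       nonref_matrix = file.path(out, "results", "nonref_peptide_counts.tsv"),
       exclusive = file.path(out, "results", "exclusive_peptides.tsv"),
       de_protein = file.path(out, "results", "de_protein.tsv"),
       de_transcript = file.path(out, "results", "de_transcript.tsv"),
       concordant = file.path(out, "results", "concordant_genes.tsv"),
       usage = file.path(out, "results", "usage.json"),
       enrichment = file.path(out, "results", "enrichment.tsv"),
       network = file.path(out, "results", "network.json"),
       report_json = file.path(out, "report.json"),
       report_txt = file.path(out, "report.txt"))
}

pipeline_log <- function(stage, msg, verbose) {
  if (verbose) message(sprintf("[%s] %s", stage, msg))
}

#' Run the full proteogenomic pipeline
#'
#' Executes simulate, build_db, classify, quantify, detest, usage and
#' network in dependency order, writing every intermediate under
#' `config$outdir` and returning (and writing) a structured report. A
#' failing stage aborts with the stage named; outputs of earlier stages
#' are preserved on disk. Rerunning with an identical configuration
#' reproduces the report exactly (timestamp aside).
#'
#' @param config A [run_config()].
#' @param verbose Emit one progress message per stage (default FALSE).
#' @return An object of class `run_report` (invisibly written to
#'   `report.json` and `report.txt`).
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  p <- pipeline_paths(config)
  for (d in c(config$outdir, p$sim, p$dbs, p$res))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  on_stage <- function(s) s %in% config$stages
  fail <- function(stage, e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)

  # -- simulate ---------------------------------------------------------------
  if (on_stage("simulate")) {
    pipeline_log("simulate", "generating synthetic study", verbose)
    tryCatch(simulate_study(config$sim, p$sim), error = function(e)
      fail("simulate", e))
  }
  sim_files <- file.path(p$sim, c("genome.fa", "annotation.gtf",
                                  "variants.vcf", "novel_exons.tsv",
                                  "psm.tsv", "transcript_counts.tsv",
                                  "design.tsv", "exon_usage.tsv",
                                  "edges.tsv", "gene_sets.tsv"))
  if (!all(file.exists(sim_files)))
    stop("pipeline stage 'simulate' skipped but inputs are missing in ",
         p$sim, call. = FALSE)
  genome <- Biostrings::readDNAStringSet(file.path(p$sim, "genome.fa"))
  names(genome) <- sub(" .*", "", names(genome))
  models <- read_annotation_gtf(file.path(p$sim, "annotation.gtf"))
  variants <- read_variants_vcf(file.path(p$sim, "variants.vcf"))
  events <- read_tsv(file.path(p$sim, "novel_exons.tsv"))
  psm <- read_tsv(file.path(p$sim, "psm.tsv"))
  design <- read_design(file.path(p$sim, "design.tsv"))
  tx_counts <- read_count_matrix(file.path(p$sim, "transcript_counts.tsv"))
  usage_counts <- read_tsv(file.path(p$sim, "exon_usage.tsv"))
  edges <- read_tsv(file.path(p$sim, "edges.tsv"))
  gene_sets <- read_tsv(file.path(p$sim, "gene_sets.tsv"))
  tx2gene <- vapply(models, `[[`, "", "gene_id")

  # -- build_db ---------------------------------------------------------------
  db_paths <- file.path(p$dbs, paste0(design$sample_id, ".fa"))
  names(db_paths) <- design$sample_id
  if (on_stage("build_db")) {
    pipeline_log("build_db", "building sample-specific databases", verbose)
    tryCatch(for (s in design$sample_id) {
      db <- build_sample_database(
        models, genome, variants[variants$sample_id == s, , drop = FALSE],
        events, s)
      write_protein_fasta(db, db_paths[[s]])
    }, error = function(e) fail("build_db", e))
  }
  if (!all(file.exists(db_paths)))
    stop("pipeline stage 'build_db' skipped but databases are missing",
         call. = FALSE)
  sample_dbs <- lapply(db_paths, read_protein_fasta, tx2gene = tx2gene)

  # -- classify ---------------------------------------------------------------
  if (on_stage("classify")) {
    pipeline_log("classify", "indexing digests and classifying peptides",
                 verbose)
    tryCatch({
      canonical_db <- canonical_proteins(models, genome)
      canonical_index <- build_peptide_index(
        canonical_db, config$missed_cleavages, config$min_len,
        config$max_len, config$il_equivalent)
      sample_index <- build_peptide_index(
        sample_dbs, config$missed_cleavages, config$min_len,
        config$max_len, config$il_equivalent)
      classification <- classify_peptides(sort(unique(psm$peptide)),
                                          sample_index, canonical_index)
      write_tsv(classification, p$classification)
    }, error = function(e) fail("classify", e))
  }
  if (!file.exists(p$classification))
    stop("pipeline stage 'classify' skipped but classification is missing",
         call. = FALSE)
  classification <- read_tsv(p$classification,
                             colClasses = c(supporting_samples = "character",
                                            genes = "character"))

  # -- quantify ---------------------------------------------------------------
  if (on_stage("quantify")) {
    pipeline_log("quantify", "building and filtering count matrices", verbose)
    tryCatch({
      gm <- gene_count_matrix(psm, classification, design$sample_id)
      gm_f <- filter_consistent(gm, design, config$min_psm, config$min_case,
                                config$min_control)
      nr <- peptide_count_matrix(psm, classification, design$sample_id)
      excl <- exclusive_nonref_peptides(nr, design, config$excl_min_total,
                                        config$excl_min_samples)
      write_count_matrix(gm, p$gene_matrix)
      write_count_matrix(gm_f, p$gene_matrix_filtered)
      write_count_matrix(nr, p$nonref_matrix)
      write_tsv(data.frame(
        peptide = c(excl$case_exclusive, excl$control_exclusive),
        exclusive_to = rep(c("case", "control"),
                           c(length(excl$case_exclusive),
                             length(excl$control_exclusive)))),
        p$exclusive)
    }, error = function(e) fail("quantify", e))
  }
  for (f in c(p$gene_matrix, p$gene_matrix_filtered, p$nonref_matrix,
              p$exclusive))
    if (!file.exists(f))
      stop("pipeline stage 'quantify' skipped but outputs are missing",
           call. = FALSE)
  gm <- read_count_matrix(p$gene_matrix)
  gm_f <- read_count_matrix(p$gene_matrix_filtered)
  nr <- read_count_matrix(p$nonref_matrix)
  excl_tab <- read_tsv(p$exclusive)
  excl <- list(
    case_exclusive = excl_tab$peptide[excl_tab$exclusive_to == "case"],
    control_exclusive = excl_tab$peptide[excl_tab$exclusive_to == "control"])

  # -- detest -----------------------------------------------------------------
  if (on_stage("detest")) {
    pipeline_log("detest", "testing differential expression", verbose)
    tryCatch({
      de_prot <- de_test(gm_f, design, alpha = config$alpha_de)
      tx_f <- filter_consistent(tx_counts, design, config$min_psm,
                                config$min_case, config$min_control)
      de_tx <- de_test(tx_f, design, alpha = config$alpha_de)
      conc <- concordance(de_prot, de_tx, config$alpha_de)
      write_tsv(de_prot, p$de_protein)
      write_tsv(de_tx, p$de_transcript)
      write_tsv(data.frame(feature_id = conc), p$concordant)
    }, error = function(e) fail("detest", e))
  }
  de_prot <- read_tsv(p$de_protein)
  de_tx <- read_tsv(p$de_transcript)
  conc <- read_tsv(p$concordant)$feature_id

  # -- usage ------------------------------------------------------------------
  if (on_stage("usage")) {
    pipeline_log("usage", "testing novel-exon usage", verbose)
    tryCatch({
      ur <- test_novel_exon_usage(usage_counts, design)
      jsonlite::write_json(
        list(u_statistic = ur$u_statistic, p_value = ur$p_value,
             group_medians = as.list(ur$group_medians),
             direction = ur$direction,
             per_sample_usage = as.list(ur$per_sample_usage)),
        p$usage, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }, error = function(e) fail("usage", e))
  }
  usage_res <- jsonlite::read_json(p$usage, simplifyVector = TRUE)

  # -- network ----------------------------------------------------------------
  if (on_stage("network")) {
    pipeline_log("network", "enrichment and connectivity statistics", verbose)
    tryCatch({
      universe <- rownames(gm_f$counts)
      de_set <- intersect(de_prot$feature_id[de_prot$fdr < config$alpha_de],
                          universe)
      net_set <- intersect(de_prot$feature_id[de_prot$fdr < config$alpha_network],
                           universe)
      if (length(de_set) > 0L) {
        enr <- hypergeom_enrich(de_set, gene_sets, universe)
        write_tsv(enr, p$enrichment)
      } else {
        write_tsv(data.frame(set_id = character(0L), overlap = integer(0L),
                             set_size = integer(0L),
                             universe_size = integer(0L),
                             de_size = integer(0L), p_value = numeric(0L),
                             fdr = numeric(0L)), p$enrichment)
      }
      net <- if (length(net_set) > 0L) {
        deg <- induced_subgraph_degrees(net_set, edges)
        perm <- connectivity_permutation_test(
          net_set, edges, universe, config$n_perm,
          seed = config$sim$seed + 8L)
        list(n_genes = length(net_set),
             max_degree_gene = names(deg)[which.max(deg)],
             max_degree = unname(max(deg)),
             observed_internal_edges = perm$observed,
             permutation_p = perm$p_value, null_mean = perm$null_mean)
      } else list(n_genes = 0L)
      jsonlite::write_json(net, p$network, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
    }, error = function(e) fail("network", e))
  }
  enr <- read_tsv(p$enrichment)
  net <- jsonlite::read_json(p$network, simplifyVector = TRUE)

  # -- report -----------------------------------------------------------------
  cat_counts <- table(factor(classification$category,
                             levels = c("reference_unique",
                                        "reference_ambiguous", "nonref_saav",
                                        "nonref_novel_isoform", "unmatched")))
  stopifnot(sum(cat_counts) == nrow(classification))
  report <- structure(list(
    version = as.character(utils::packageVersion("pgxpipe")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = list(
      sim = unclass(config$sim),
      digestion = list(missed_cleavages = config$missed_cleavages,
                       min_len = config$min_len, max_len = config$max_len,
                       il_equivalent = config$il_equivalent),
      filters = list(min_psm = config$min_psm, min_case = config$min_case,
                     min_control = config$min_control,
                     excl_min_total = config$excl_min_total,
                     excl_min_samples = config$excl_min_samples),
      thresholds = list(alpha_de = config$alpha_de,
                        alpha_network = config$alpha_network,
                        n_perm = config$n_perm)),
    peptides = list(
      n_classified = nrow(classification),
      by_category = as.list(as.integer(cat_counts) |>
                              stats::setNames(names(cat_counts))),
      n_nonreference = sum(classification$category %in%
                             c("nonref_saav", "nonref_novel_isoform"))),
    quantification = list(
      n_genes = nrow(gm$counts),
      n_genes_filtered = nrow(gm_f$counts),
      n_nonref_peptides = nrow(nr$counts),
      n_case_exclusive = length(excl$case_exclusive),
      n_control_exclusive = length(excl$control_exclusive),
      case_exclusive = excl$case_exclusive,
      control_exclusive = excl$control_exclusive),
    differential_expression = list(
      n_tested = nrow(de_prot),
      n_fdr05 = sum(de_prot$fdr < 0.05),
      n_up = sum(de_prot$fdr < 0.05 & de_prot$log2fc > 0),
      n_down = sum(de_prot$fdr < 0.05 & de_prot$log2fc < 0),
      n_fdr01 = sum(de_prot$fdr < 0.01),
      n_transcript_fdr05 = sum(de_tx$fdr < 0.05),
      n_concordant = length(conc)),
    usage = list(p_value = usage_res$p_value,
                 direction = usage_res$direction,
                 group_medians = usage_res$group_medians),
    network = c(list(top_enrichment = if (nrow(enr) > 0L)
      as.list(enr[1L, c("set_id", "overlap", "p_value", "fdr")]) else NULL),
      net)),
    class = "run_report")
  # internal consistency: category tallies must add up
  stopifnot(report$peptides$n_classified ==
              sum(unlist(report$peptides$by_category)))
  jsonlite::write_json(unclass(report), p$report_json, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  writeLines(utils::capture.output(print(report)), p$report_txt)
  invisible(report)
}

#' @export
print.run_report <- function(x, ...) {
  cat("pgxpipe run report (version ", x$version, ", ", x$timestamp, ")\n",
      sep = "")
  cat(sprintf("peptides classified: %d (non-reference: %d)\n",
              x$peptides$n_classified, x$peptides$n_nonreference))
  for (k in names(x$peptides$by_category))
    cat(sprintf("  %-22s %d\n", k, x$peptides$by_category[[k]]))
  cat(sprintf("genes quantified: %d (%d after presence filter)\n",
              x$quantification$n_genes, x$quantification$n_genes_filtered))
  cat(sprintf("exclusive non-reference peptides: %d case / %d control\n",
              x$quantification$n_case_exclusive,
              x$quantification$n_control_exclusive))
  cat(sprintf("differential expression: %d tested, %d at FDR<0.05 (%d up, %d down), %d at FDR<0.01\n",
              x$differential_expression$n_tested,
              x$differential_expression$n_fdr05,
              x$differential_expression$n_up,
              x$differential_expression$n_down,
              x$differential_expression$n_fdr01))
  cat(sprintf("transcript-concordant DE genes: %d\n",
              x$differential_expression$n_concordant))
  cat(sprintf("novel-exon usage: p = %.4g (%s)\n",
              x$usage$p_value, x$usage$direction))
  if (!is.null(x$network$top_enrichment))
    cat(sprintf("top enrichment: %s (overlap %d, FDR %.3g)\n",
                x$network$top_enrichment$set_id,
                x$network$top_enrichment$overlap,
                x$network$top_enrichment$fdr))
  if (!is.null(x$network$permutation_p))
    cat(sprintf("network connectivity: %d internal edges, permutation p = %.4g\n",
                x$network$observed_internal_edges, x$network$permutation_p))
  invisible(x)
}
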