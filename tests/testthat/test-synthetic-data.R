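test_that("configuration invariants are enforced", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_genes = 0))
  expect_error(sim_config(nb_dispersion = 0))
  expect_error(sim_config(inclusion_bias = 1.2))
  expect_error(sim_config(novel_exon_length = 713L))
  expect_error(sim_config(log2fc_magnitude = 0))
})

test_that("generated gene models are well-formed coding genes", {
  cfg <- sim_config(n_genes = 5, seed = 101)
  gen <- generate_genome(cfg)
  expect_length(gen$models, 5L)
  strands <- vapply(gen$models, `[[`, "", "strand")
  expect_true("-" %in% strands)
  for (m in gen$models) {
    expect_gte(nrow(m$exons), 2L)
    cds <- spliced_cds_sequence(m, gen$genome)
    expect_identical(nchar(cds) %% 3L, 0L)
    expect_identical(substr(cds, 1, 3), "ATG")
    expect_true(substr(cds, nchar(cds) - 2, nchar(cds)) %in%
                  c("TAA", "TAG", "TGA"))
    # translation runs clean to the terminal stop
    expect_no_warning(prot <- translate_cds(cds))
    expect_gt(nchar(prot), 50L)
  }
  # minus-strand definition: spliced CDS equals the reverse complement of
  # the genomic exon concatenation
  mm <- gen$models[[which(strands == "-")[1L]]]
  seg <- do.call(paste0, lapply(seq_len(nrow(mm$exons)), function(i)
    as.character(Biostrings::subseq(gen$genome[[mm$chrom]],
                                    mm$exons$start[i], mm$exons$end[i]))))
  expect_identical(
    spliced_cds_sequence(mm, gen$genome),
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(seg))))
})

test_that("simulation outputs are byte-identical across runs at a fixed seed", {
  cfg <- sim_config(n_genes = 6, seed = 103)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_study(cfg, d1)
  simulate_study(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
  # and a different seed changes the genome
  d3 <- withr::local_tempdir()
  simulate_study(sim_config(n_genes = 6, seed = 104), d3)
  expect_false(identical(readLines(file.path(d1, "genome.fa")),
                         readLines(file.path(d3, "genome.fa"))))
})

test_that("planted variants are sample-private missense SNVs", {
  cfg <- sim_config(n_genes = 12, variant_rate = 1, seed = 107)
  gen <- generate_genome(cfg)
  vr <- generate_variants(gen, cfg)
  expect_gt(nrow(vr$variants), 0L)
  models_by_tx <- gen$models
  for (i in seq_len(nrow(vr$saav_truth))) {
    tr <- vr$saav_truth[i, ]
    m <- models_by_tx[[tr$transcript_id]]
    cds <- spliced_cds_sequence(m, gen$genome)
    v <- vr$variants[i, ]
    mut <- apply_variants(cds, m, v)
    p_ref <- translate_cds(cds)
    p_alt <- translate_cds(mut)
    diffs <- which(strsplit(p_ref, "")[[1L]] != strsplit(p_alt, "")[[1L]])
    expect_identical(length(diffs), 1L)
    expect_identical(diffs, tr$codon)
    expect_identical(substr(p_alt, diffs, diffs), tr$alt_aa)
  }
  # zero rate produces an empty variant set
  vr0 <- generate_variants(gen, sim_config(n_genes = 12, variant_rate = 0,
                                           seed = 107))
  expect_identical(nrow(vr0$variants), 0L)
})

test_that("variants survive a VCF round trip", {
  cfg <- sim_config(n_genes = 10, variant_rate = 1, seed = 109)
  gen <- generate_genome(cfg)
  vr <- generate_variants(gen, cfg)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_variants_vcf(vr$variants, sim_design(cfg)$sample_id, f)
  back <- read_variants_vcf(f)
  o1 <- vr$variants[order(vr$variants$pos), ]
  o2 <- back[order(back$pos), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
})

test_that("annotation survives a GTF round trip", {
  cfg <- sim_config(n_genes = 5, seed = 113)
  gen <- generate_genome(cfg)
  f <- withr::local_tempfile(fileext = ".gtf")
  write_annotation_gtf(gen$models, f)
  back <- read_annotation_gtf(f)
  expect_setequal(names(back), names(gen$models))
  for (tx in names(gen$models)) {
    expect_identical(back[[tx]]$exons, gen$models[[tx]]$exons)
    expect_identical(back[[tx]]$strand, gen$models[[tx]]$strand)
    expect_identical(back[[tx]]$gene_id, gen$models[[tx]]$gene_id)
  }
})

test_that("novel exon events honour inclusion probabilities and framing", {
  cfg <- sim_config(n_genes = 4, inclusion_bias = 1, seed = 127)
  gen <- generate_genome(cfg)
  ne <- generate_novel_exon(gen, cfg)
  incl <- merge(ne$inclusion, sim_design(cfg), by = "sample_id")
  expect_true(all(incl$included[incl$group == "case"]))
  expect_false(any(incl$included[incl$group == "control"]))
  # in-frame arithmetic: a 714-nt exon adds exactly 238 residues
  ev <- ne$events[1L, ]
  expect_identical(ev$exon_end - ev$exon_start + 1L, 714L)
  host <- gen$models[[ev$host_transcript]]
  iso <- insert_novel_exon(host, ev)
  expect_true(all(diff(iso$exons$start) > 0))
  p0 <- translate_cds(spliced_cds_sequence(host, gen$genome))
  p1 <- translate_cds(spliced_cds_sequence(iso, gen$genome))
  expect_identical(nchar(p1) - nchar(p0), 238L)
})

test_that("PSM counts follow the planted negative-binomial group model", {
  # near-Poisson limit: pooled variance/mean ratio of null peptide counts
  # approaches 1 (checked on > 1000 draws)
  cfg <- sim_config(n_genes = 15, frac_de = 0, variant_rate = 0,
                    nb_dispersion = 1e-8, seed = 131)
  st <- simulate_study(cfg)
  # only reference peptides share the common NB model in every sample;
  # isoform peptides are structurally absent from exon non-carriers
  truth <- st$ground_truth$peptide_truth
  peps <- truth$peptide[truth$origin == "reference"]
  psm <- st$psm[st$psm$peptide %in% peps, ]
  # rebuild the full peptide x sample matrix including zeros
  m <- matrix(0, length(peps), 18,
              dimnames = list(peps, st$design$sample_id))
  m[cbind(psm$peptide, psm$sample)] <- psm$psm_count
  draws <- as.vector(m)
  expect_gt(length(draws), 1000L)
  expect_gt(var(draws) / mean(draws), 0.9)
  expect_lt(var(draws) / mean(draws), 1.1)
  # null genes: case/control means agree within Monte-Carlo error across
  # >= 200 peptide features
  cfg2 <- sim_config(n_genes = 60, frac_de = 0, variant_rate = 0, seed = 137)
  st2 <- simulate_study(cfg2)
  truth2 <- st2$ground_truth$peptide_truth
  peps2 <- truth2$peptide[truth2$origin == "reference"]
  psm2 <- st2$psm[st2$psm$peptide %in% peps2, ]
  m2 <- matrix(0, length(peps2), 18,
               dimnames = list(peps2, st2$design$sample_id))
  m2[cbind(psm2$peptide, psm2$sample)] <- psm2$psm_count
  expect_gte(nrow(m2), 200L)
  is_case <- st2$design$group == "case"
  ratio <- mean(m2[, is_case]) / mean(m2[, !is_case])
  expect_gt(ratio, 0.95); expect_lt(ratio, 1.05)
})

test_that("every emitted peptide digests out of the emitting sample's database", {
  st <- simulate_study(sim_config(n_genes = 8, variant_rate = 0.8, seed = 139))
  digests <- lapply(st$sample_dbs, function(db)
    unique(unlist(lapply(db$sequence, digest))))
  ok <- vapply(seq_len(nrow(st$psm)), function(i)
    st$psm$peptide[i] %in% digests[[st$psm$sample[i]]], logical(1L))
  expect_true(all(ok))
})

test_that("transcript counts control concordance by construction", {
  cfg <- sim_config(n_genes = 20, frac_de = 0.3, concordant_fraction = 1,
                    seed = 149)
  gen <- generate_genome(cfg)
  de <- pgxpipe:::assign_de_genes(gen, cfg)
  tc <- generate_transcript_counts(gen, de, cfg)
  expect_identical(dim(tc$counts$counts), c(20L, 18L))
  expect_true(all(sign(tc$truth$tx_log2fc) == sign(de$log2fc)))
  cfg0 <- sim_config(n_genes = 20, frac_de = 0.3, concordant_fraction = 0,
                     seed = 149)
  tc0 <- generate_transcript_counts(gen, de, cfg0)
  expect_true(all(sign(tc0$truth$tx_log2fc) == -sign(de$log2fc)))
})
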