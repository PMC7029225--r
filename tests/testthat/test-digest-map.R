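test_that("tryptic cleavage rule, missed cleavages and bounds behave as defined", {
  expect_identical(digest("MKRPTIDE", 0L, 1L, 50L), c("MK", "RPTIDE"))
  expect_identical(digest("MKRPTIDE", 1L, 1L, 50L),
                   c("MK", "MKRPTIDE", "RPTIDE"))
  expect_identical(digest("", 2L), character(0L))
  # length window filters
  expect_identical(digest("MKRPTIDE", 0L, 3L, 50L), "RPTIDE")
  expect_error(digest("MK", 0L, 5L, 3L))
})

test_that("digestion equals brute-force substring enumeration", {
  set.seed(21)
  for (i in 1:60) {
    prot <- random_aa_string(sample(1:30, 1L))
    mc <- sample(0:2, 1L)
    expect_setequal(digest(prot, mc, 1L, 30L), oracle_digest(prot, mc, 1L, 30L))
    expect_setequal(digest(prot, mc, 4L, 12L), oracle_digest(prot, mc, 4L, 12L))
  }
})

make_db <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(protein_id = r[[1]], sequence = r[[2]], provenance = r[[3]],
               source_transcript = r[[1]], gene_id = r[[4]],
               sample_id = r[[5]], annotations = "", premature_stop = FALSE)))
}

test_that("the peptide index maps peptides to their source genes", {
  empty_db <- make_db(list("p0", "MAAAAAAK", "canonical", "G0",
                           "reference"))[0, ]
  empty <- build_peptide_index(list(empty_db))
  expect_identical(length(ls(empty$env)), 0L)
  db <- make_db(list("p1", "MAAAAAAKDDDDDDR", "canonical", "G1", "reference"),
                list("p2", "MCCCCCCKDDDDDDR", "canonical", "G2", "reference"))
  idx <- build_peptide_index(db, missed_cleavages = 0L, min_len = 7L,
                             max_len = 35L)
  one <- pgxpipe:::index_lookup(idx, "MAAAAAAK")
  expect_identical(one$genes, "G1")
  shared <- pgxpipe:::index_lookup(idx, "DDDDDDR")
  expect_setequal(shared$genes, c("G1", "G2"))
})

test_that("classification reproduces the reference/non-reference taxonomy", {
  canon <- make_db(list("p1", "MAAAAAAKDDDDDDR", "canonical", "G1", "reference"),
                   list("p2", "MCCCCCCKEEEEEER", "canonical", "G2", "reference"))
  s1 <- rbind(canon,
              make_db(list("p1v", "MAAAAYAKDDDDDDR", "saav", "G1", "s1")))
  s2 <- rbind(canon,
              make_db(list("p2n", "MCCCCCCKWWWWWWKEEEEEER", "novel_isoform",
                           "G2", "s2")))
  ci <- build_peptide_index(canon, 0L, 7L, 35L)
  si <- build_peptide_index(list(s1, s2), 0L, 7L, 35L)
  cls <- classify_peptides(c("MAAAAAAK", "DDDDDDR", "MAAAAYAK", "WWWWWWK",
                             "MNNNNNNK"), si, ci)
  expect_identical(cls$category,
                   c("reference_unique", "reference_unique", "nonref_saav",
                     "nonref_novel_isoform", "unmatched"))
  expect_identical(cls$genes[1L], "G1")
  expect_identical(cls$supporting_samples[3L], "s1")
  expect_identical(cls$supporting_samples[4L], "s2")
  expect_error(classify_peptides("MAAA1AAK", si, ci), "non-amino-acid")
})

test_that("no canonical digestion product is ever classified non-reference", {
  st <- simulate_study(sim_config(n_genes = 8, variant_rate = 0.9, seed = 13))
  ci <- build_peptide_index(st$canonical_db)
  si <- build_peptide_index(st$sample_dbs)
  all_canon_peps <- unique(unlist(lapply(st$canonical_db$sequence, digest)))
  cls <- classify_peptides(all_canon_peps, si, ci)
  expect_true(all(startsWith(cls$category, "reference")))
})

test_that("every planted variant residue inside a digestible peptide is recovered", {
  st <- simulate_study(sim_config(n_genes = 10, variant_rate = 1, seed = 17))
  ci <- build_peptide_index(st$canonical_db)
  si <- build_peptide_index(st$sample_dbs)
  for (s in unique(st$ground_truth$saav_events$sample_id)) {
    sv <- st$sample_dbs[[s]]
    sv <- sv[sv$provenance == "saav", ]
    for (i in seq_len(nrow(sv))) {
      novel <- setdiff(digest(sv$sequence[i]),
                       unlist(lapply(st$canonical_db$sequence, digest)))
      if (length(novel) == 0L) next
      cls <- classify_peptides(novel, si, ci)
      expect_true(any(cls$category == "nonref_saav"))
    }
  }
})

test_that("I/L-equivalent matching never claims more novelty than strict", {
  # a peptide whose only difference from canonical is I->L must stay reference
  canon <- make_db(list("p1", "MAIAAAAKDDDDDDR", "canonical", "G1", "reference"))
  s1 <- rbind(canon,
              make_db(list("p1v", "MALAAAAKDDDDDDR", "saav", "G1", "s1")))
  ci_il <- build_peptide_index(canon, 0L, 7L, 35L, il_equivalent = TRUE)
  si_il <- build_peptide_index(list(s1), 0L, 7L, 35L, il_equivalent = TRUE)
  ci_st <- build_peptide_index(canon, 0L, 7L, 35L, il_equivalent = FALSE)
  si_st <- build_peptide_index(list(s1), 0L, 7L, 35L, il_equivalent = FALSE)
  peps <- c("MAIAAAAK", "MALAAAAK", "DDDDDDR")
  il <- classify_peptides(peps, si_il, ci_il)
  strict <- classify_peptides(peps, si_st, ci_st)
  n_nonref <- function(x) sum(startsWith(x$category, "nonref"))
  expect_lte(n_nonref(il), n_nonref(strict))
  expect_identical(il$category[2L], "reference_unique")     # I/L collapsed
  expect_identical(strict$category[2L], "nonref_saav")      # strict sees it
})

test_that("isoform-unique peptides include a junction-spanning peptide", {
  st <- simulate_study(sim_config(n_genes = 6, inclusion_bias = 1, seed = 19))
  peps <- peptides_for_novel_exon(st$events[1L, ], st$sample_dbs)
  expect_gt(length(peps), 0L)
  # none of them digests out of any canonical or saav protein
  other <- unique(unlist(lapply(st$canonical_db$sequence, digest)))
  expect_false(any(gsub("I", "L", peps) %in% gsub("I", "L", other)))
  # at least one spans the host/novel junction: it contains residues on
  # both sides of the insertion boundary
  host <- st$models[[st$events$host_transcript[1L]]]
  host_prot <- translate_cds(spliced_cds_sequence(host, st$genome))
  iso <- insert_novel_exon(host, st$events[1L, ])
  iso_prot <- translate_cds(spliced_cds_sequence(iso, st$genome))
  ins_len <- nchar(iso_prot) - nchar(host_prot)
  # insertion point: first residue where isoform and host disagree
  cut <- which(strsplit(iso_prot, "")[[1L]][seq_len(nchar(host_prot))] !=
                 strsplit(host_prot, "")[[1L]])[1L]
  spans <- vapply(peps, function(p) {
    at <- regexpr(p, iso_prot, fixed = TRUE)
    at > 0 && at < cut && at + nchar(p) - 1L >= cut
  }, logical(1L))
  expect_true(any(spans))
  expect_identical(peptides_for_novel_exon(st$events[1L, ], list()),
                   character(0L))
})
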