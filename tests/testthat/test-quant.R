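toy_design <- function(n_case = 10L, n_control = 8L) {
  data.frame(sample_id = c(sprintf("case%02d", seq_len(n_case)),
                           sprintf("ctrl%02d", seq_len(n_control))),
             group = rep(c("case", "control"), c(n_case, n_control)))
}

toy_classification <- data.frame(
  peptide = c("AAAAAAK", "CCCCCCK", "DDDDDDK", "EEEEEEK"),
  category = c("reference_unique", "reference_unique", "reference_ambiguous",
               "nonref_saav"),
  genes = c("G1", "G1", "G1,G2", "G1"),
  n_genes = c(1L, 1L, 2L, 1L),
  supporting_samples = "", n_supporting_samples = 0L)

test_that("gene counts sum uniquely mapping peptides and exclude the rest", {
  psm <- data.frame(peptide = c("AAAAAAK", "CCCCCCK", "DDDDDDK", "EEEEEEK"),
                    sample = "S", psm_count = c(3L, 4L, 100L, 50L))
  m <- gene_count_matrix(psm, toy_classification, samples = "S")
  expect_identical(unname(m$counts["G1", "S"]), 7)
  expect_identical(rownames(m$counts), "G1")  # ambiguous gene pair absent
  # empty table gives an all-zero matrix over the classified gene universe
  m0 <- gene_count_matrix(psm[0, ], toy_classification, samples = "S")
  expect_true(all(m0$counts == 0))
  # unknown sample and unclassified peptide are validation errors
  expect_error(gene_count_matrix(
    data.frame(peptide = "AAAAAAK", sample = "S9", psm_count = 1L),
    toy_classification, samples = "S"), "unknown sample")
  expect_error(gene_count_matrix(
    data.frame(peptide = "ZZZZZZK", sample = "S", psm_count = 1L),
    toy_classification, samples = "S"), "unclassified")
})

test_that("count conservation: gene totals equal unique-peptide PSM totals", {
  st <- simulate_study(sim_config(n_genes = 10, seed = 23))
  ci <- build_peptide_index(st$canonical_db)
  si <- build_peptide_index(st$sample_dbs)
  cls <- classify_peptides(unique(st$psm$peptide), si, ci)
  gm <- gene_count_matrix(st$psm, cls, st$design$sample_id)
  uniq_peps <- cls$peptide[cls$category == "reference_unique"]
  expect_equal(sum(gm$counts),
               sum(st$psm$psm_count[st$psm$peptide %in% uniq_peps]))
})

test_that("the presence filter keeps >=3 PSMs in >=5 cases or >=4 controls", {
  d <- toy_design()
  mk <- function(case_counts, ctrl_counts) {
    m <- matrix(c(case_counts, ctrl_counts), nrow = 1,
                dimnames = list("F", d$sample_id))
    count_matrix(m)
  }
  keep <- function(x) nrow(filter_consistent(x, d)$counts) == 1L
  # >=3 PSMs in exactly 5 of 10 cases, nothing in controls: kept
  expect_true(keep(mk(c(rep(3, 5), rep(0, 5)), rep(0, 8))))
  # 4 cases and 3 controls at >=3: neither branch satisfied, dropped
  expect_false(keep(mk(c(rep(3, 4), rep(0, 6)), c(rep(3, 3), rep(0, 5)))))
  # >=3 in 4 controls: kept via the control branch
  expect_true(keep(mk(rep(0, 10), c(rep(3, 4), rep(0, 4)))))
  # counts of 2 never satisfy the >=3 rule
  expect_false(keep(mk(rep(2, 10), rep(2, 8))))
  # all-zero feature dropped
  expect_false(keep(mk(rep(0, 10), rep(0, 8))))
  expect_error(filter_consistent(mk(rep(3, 10), rep(3, 8)), d,
                                 min_case = 11L), "exceeds group size")
})

test_that("raising filter thresholds never enlarges the surviving set", {
  set.seed(31)
  d <- toy_design()
  m <- matrix(rpois(50 * 18, 3), nrow = 50,
              dimnames = list(sprintf("F%02d", 1:50), d$sample_id))
  x <- count_matrix(m)
  base <- rownames(filter_consistent(x, d, 3L, 5L, 4L)$counts)
  for (args in list(c(4L, 5L, 4L), c(3L, 6L, 4L), c(3L, 5L, 5L))) {
    tighter <- rownames(filter_consistent(x, d, args[1], args[2],
                                          args[3])$counts)
    expect_true(all(tighter %in% base))
  }
})

test_that("group exclusivity follows the >=5 PSM / >=4 sample rule", {
  d <- toy_design()
  mk <- function(...) {
    rows <- list(...)
    m <- do.call(rbind, rows)
    rownames(m) <- sprintf("P%d", seq_along(rows))
    colnames(m) <- d$sample_id
    count_matrix(m)
  }
  x <- mk(c(2, 1, 1, 1, rep(0, 6), rep(0, 8)),   # 4 cases, total 5: exclusive
          c(2, 1, 1, 1, rep(0, 6), 1, rep(0, 7)), # 1 control count: neither
          c(1, 1, 1, 1, rep(0, 6), rep(0, 8)),   # total 4 < 5: excluded
          c(5, 5, 5, rep(0, 7), rep(0, 8)),      # only 3 samples: excluded
          c(rep(0, 10), 3, 1, 1, 1, rep(0, 4)))  # control-exclusive
  ex <- exclusive_nonref_peptides(x, d)
  expect_identical(ex$case_exclusive, "P1")
  expect_identical(ex$control_exclusive, "P5")
  expect_length(intersect(ex$case_exclusive, ex$control_exclusive), 0L)
})

test_that("upper-quartile normalization matches the order-statistic definition", {
  m <- matrix(c(1, 2, 3, 4, 0,
                2, 4, 6, 8, 0), ncol = 2,
              dimnames = list(sprintf("F%d", 1:5), c("s1", "s2")))
  x <- upper_quartile_normalize(count_matrix(m))
  # nonzero 75th percentiles are 3.25 and 6.5; factors are rescaled to
  # geometric mean 1, so their ratio must equal 3.25/6.5
  expect_equal(unname(x$scale_factors["s1"] / x$scale_factors["s2"]),
               3.25 / 6.5, tolerance = 1e-12)
  expect_equal(unname(prod(x$scale_factors))^(1 / 2), 1, tolerance = 1e-12)
  # equal count vectors give factors exactly 1
  eq <- upper_quartile_normalize(count_matrix(
    matrix(c(1, 5, 2, 1, 5, 2), ncol = 2,
           dimnames = list(c("f1", "f2", "f3"), c("a", "b")))))
  expect_equal(unname(eq$scale_factors), c(1, 1), tolerance = 1e-12)
  # all-zero sample is a hard error naming the sample
  bad <- count_matrix(matrix(c(1, 2, 0, 0), ncol = 2,
                             dimnames = list(c("f1", "f2"),
                                             c("ok", "empty"))))
  expect_error(upper_quartile_normalize(bad), "empty")
})

test_that("normalization is scale-equivariant and idempotent", {
  set.seed(37)
  m <- matrix(rpois(40, 10) + 1, ncol = 4,
              dimnames = list(sprintf("F%d", 1:10), sprintf("s%d", 1:4)))
  x <- upper_quartile_normalize(count_matrix(m))
  # scaling one sample by c leaves between-sample normalized ratios intact
  m2 <- m; m2[, 2] <- m2[, 2] * 7
  x2 <- upper_quartile_normalize(count_matrix(m2))
  ratios <- x2$normalized / x$normalized
  expect_lt(max(apply(ratios, 2, function(col) diff(range(col)))), 1e-12)
  expect_equal(x2$normalized[, 1] / x2$normalized[, 2],
               x$normalized[, 1] / x$normalized[, 2], tolerance = 1e-12)
  # renormalizing the normalized view returns factors of 1
  again <- upper_quartile_normalize(count_matrix(x$normalized))
  expect_equal(unname(again$scale_factors), rep(1, 4), tolerance = 1e-12)
})
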