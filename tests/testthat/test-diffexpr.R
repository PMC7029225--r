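de_design <- function(n_case = 10L, n_control = 8L) {
  data.frame(sample_id = c(sprintf("case%02d", seq_len(n_case)),
                           sprintf("ctrl%02d", seq_len(n_control))),
             group = rep(c("case", "control"), c(n_case, n_control)))
}

nb_matrix <- function(design, lfc, mu = 30, phi = 0.3) {
  is_case <- design$group == "case"
  m <- t(vapply(seq_along(lfc), function(i)
    rnbinom(nrow(design), size = 1 / phi,
            mu = mu * 2^(ifelse(is_case, lfc[i], 0))),
    numeric(nrow(design))))
  dimnames(m) <- list(sprintf("F%04d", seq_along(lfc)), design$sample_id)
  count_matrix(m)
}

test_that("the conditional exact test matches its closed-form limits", {
  d <- de_design(2L, 2L)
  # balanced split of total 10 under the phi = 0 binomial null: p = 1
  expect_equal(nb_exact_test(setNames(c(3, 2, 4, 1), d$sample_id), d, 0), 1)
  # fully one-sided split 10 vs 0: p = 2 * 0.5^10
  expect_equal(nb_exact_test(setNames(c(6, 4, 0, 0), d$sample_id), d, 0),
               2 * 0.5^10)
  # zero total is p = 1 by convention
  expect_equal(nb_exact_test(setNames(rep(0, 4), d$sample_id), d, 0.3), 1)
})

test_that("the exact test is symmetric under label swap", {
  set.seed(41)
  d <- de_design(5L, 4L)
  d_swapped <- d
  d_swapped$group <- ifelse(d$group == "case", "control", "case")
  for (i in 1:20) {
    cnt <- setNames(rnbinom(9, size = 3, mu = 20), d$sample_id)
    phi <- runif(1, 0, 0.6)
    sf <- setNames(exp(runif(9, -0.2, 0.2)), d$sample_id)
    expect_equal(nb_exact_test(cnt, d, phi, sf),
                 nb_exact_test(cnt, d_swapped, phi, sf))
  }
})

test_that("dispersion estimation recovers the generative dispersion", {
  set.seed(43)
  d <- de_design()
  # Poisson data: mean estimate near zero
  pois <- nb_matrix(d, rep(0, 500), mu = 30, phi = 1e-9)
  expect_lt(mean(estimate_dispersion(pois, d)), 0.05)
  # NB phi = 0.4 recovered within a factor-two band at n = 10 vs 8
  nb <- nb_matrix(d, rep(0, 500), mu = 30, phi = 0.4)
  expect_gt(mean(estimate_dispersion(nb, d)), 0.2)
  expect_lt(mean(estimate_dispersion(nb, d)), 0.6)
  # constant counts: raw moment term zero, estimate collapses to the prior
  const <- count_matrix(matrix(5, nrow = 3, ncol = 18,
                               dimnames = list(c("a", "b", "c"),
                                               d$sample_id)))
  phi_hat <- estimate_dispersion(const, d)
  expect_true(all(phi_hat == phi_hat[1]))
  expect_error(estimate_dispersion(nb, de_design(1L, 8L)), ">= 2 samples")
})

test_that("BH adjustment validates input and matches the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("de_test returns coherent fold-changes, FDR and directions", {
  set.seed(47)
  d <- de_design()
  lfc <- c(rep(2, 10), rep(-2, 10), rep(0, 80))
  x <- nb_matrix(d, lfc)
  res <- de_test(x, d)
  expect_s3_class(res, "de_result")
  expect_true(all(res$fdr >= 0 & res$fdr <= 1))
  sig <- res[res$fdr < 0.05, ]
  expect_true(all(sig$direction == ifelse(sig$log2fc > 0, "up", "down")))
  expect_true(all(res$direction[res$fdr >= 0.05] == "none"))
  # the strong planted effects dominate the calls
  expect_gt(mean(res$feature_id[res$fdr < 0.05] %in%
                   sprintf("F%04d", 1:20)), 0.8)
})

test_that("concordance requires significance and a shared direction", {
  prot <- data.frame(feature_id = c("A", "B", "C", "D"),
                     log2fc = c(1.2, 1.0, -0.8, 1.1),
                     p_value = c(0.001, 0.001, 0.001, 0.2),
                     fdr = c(0.01, 0.01, 0.01, 0.4),
                     direction = c("up", "up", "down", "none"))
  tx <- data.frame(feature_id = c("A", "B", "C", "D"),
                   log2fc = c(0.9, -1.0, -0.5, 1.0),
                   p_value = c(0.01, 0.001, 0.2, 0.001),
                   fdr = c(0.05, 0.01, 0.4, 0.01),
                   direction = c("up", "down", "none", "up"))
  # A: both up and significant; B: direction mismatch; C: transcript not
  # significant; D: protein not significant
  expect_identical(concordance(prot, tx), "A")
})

test_that("planted concordant effects are recovered in the synthetic study", {
  st <- simulate_study(sim_config(n_genes = 40, frac_de = 0.25,
                                  concordant_fraction = 1, seed = 53))
  ci <- build_peptide_index(st$canonical_db)
  si <- build_peptide_index(st$sample_dbs)
  cls <- classify_peptides(unique(st$psm$peptide), si, ci)
  gm <- filter_consistent(gene_count_matrix(st$psm, cls, st$design$sample_id),
                          st$design)
  de_prot <- de_test(gm, st$design)
  de_tx <- de_test(filter_consistent(st$tx_counts, st$design), st$design)
  conc <- concordance(de_prot, de_tx)
  truth <- st$ground_truth$de_proteins$gene_id
  # every concordant call is a planted effect (construction guarantees the
  # direction agreement only for true DE genes)
  expect_true(all(conc %in% truth))
  expect_gt(length(conc), 0L)
})
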