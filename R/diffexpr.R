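#' Moment-based shrunken dispersion estimation
#'
#' Per-feature negative-binomial dispersion under the mean/dispersion
#' parameterisation `variance = mu + mu^2 * phi`. The raw estimate is the
#' method-of-moments value `max(0, (s^2 - m) / m^2)` computed on
#' scale-factor-adjusted counts pooled across the two groups (each group
#' contributes its within-group moments, weighted by degrees of freedom,
#' so true expression differences do not inflate the estimate). Raw
#' estimates are then shrunk toward the 10%-trimmed mean of all raw
#' estimates with a fixed weight, which stabilises the small-sample noise
#' of per-feature moments.
#'
#' @param x A [count_matrix()]; normalized with
#'   [upper_quartile_normalize()] first if `scale_factors` is absent.
#' @param design Sample design, groups `case`/`control`, each with >= 2
#'   samples.
#' @param shrink_weight Weight on the trimmed-mean prior (default 0.5).
#' @param trim Trim fraction for the prior (default 0.1).
#' @return Named numeric vector of dispersions (>= 0), one per feature.
#' @export
estimate_dispersion <- function(x, design, shrink_weight = 0.5, trim = 0.1) {
  stopifnot(inherits(x, "count_matrix"), shrink_weight >= 0, shrink_weight <= 1)
  d <- as_design(design)
  if (is.null(x$scale_factors)) x <- upper_quartile_normalize(x)
  adj <- x$normalized
  groups <- list(case = d$sample_id[d$group == "case"],
                 control = d$sample_id[d$group == "control"])
  if (any(lengths(groups) < 2L))
    stop("dispersion estimation needs >= 2 samples per group")
  num <- 0; den <- 0
  mu_parts <- 0
  for (ids in groups) {
    g <- adj[, ids, drop = FALSE]
    m <- rowMeans(g)
    v <- apply(g, 1L, stats::var)
    w <- length(ids) - 1L
    num <- num + w * (v - m)
    mu_parts <- mu_parts + w * m^2
    den <- den + w
  }
  raw <- pmax(0, (num / den) / (mu_parts / den))
  raw[!is.finite(raw)] <- 0
  prior <- mean(raw, trim = trim)
  phi <- (1 - shrink_weight) * raw + shrink_weight * prior
  stats::setNames(pmax(0, phi), rownames(adj))
}

#' Negative-binomial conditional exact test for one feature
#'
#' Conditions on the total count and asks how extreme the observed
#' case/control split of that total is. Group sums are modelled as
#' negative binomial with size `n_g / phi` and means proportional to the
#' summed scale factors of each group (under the null of equal underlying
#' expression); at `phi = 0` this reduces to the binomial conditional test
#' of Poisson counts. The two-sided p-value sums the probabilities of all
#' splits no more probable than the observed one (minimum-likelihood
#' ordering), which is well defined for asymmetric discrete nulls.
#'
#' @param counts Named numeric vector of one feature's raw counts.
#' @param design Sample design, groups `case`/`control`.
#' @param dispersion Non-negative dispersion `phi`.
#' @param scale_factors Named per-sample scale factors (default all 1).
#' @return Two-sided p-value; a zero total gives p = 1 by convention.
#' @export
nb_exact_test <- function(counts, design, dispersion, scale_factors = NULL) {
  stopifnot(dispersion >= 0)
  d <- as_design(design)
  if (is.null(scale_factors))
    scale_factors <- stats::setNames(rep(1, length(counts)), names(counts))
  case_ids <- d$sample_id[d$group == "case"]
  ctrl_ids <- d$sample_id[d$group == "control"]
  sa <- sum(counts[case_ids]); sb <- sum(counts[ctrl_ids])
  total <- sa + sb
  if (total == 0) return(1)
  fa <- sum(scale_factors[case_ids]); fb <- sum(scale_factors[ctrl_ids])
  k <- 0:total
  if (dispersion < 1e-8) {
    dens <- stats::dbinom(k, size = total, prob = fa / (fa + fb))
  } else {
    lambda <- total / (fa + fb)
    dens <- stats::dnbinom(k, size = length(case_ids) / dispersion,
                           mu = lambda * fa) *
      stats::dnbinom(total - k, size = length(ctrl_ids) / dispersion,
                     mu = lambda * fb)
    dens <- dens / sum(dens)
  }
  obs <- dens[sa + 1L]
  min(1, sum(dens[dens <= obs * (1 + 1e-10)]))
}

#' Two-group differential expression on spectral counts
#'
#' Runs the shrunken-dispersion NB conditional exact test per feature,
#' computes log2 fold-changes (case over control) on normalized group
#' means with a pseudo-count of 0.5, and adjusts p-values with
#' Benjamini-Hochberg.
#'
#' @param x A [count_matrix()] (filtered); normalized internally if
#'   needed.
#' @param design Sample design, groups `case`/`control`.
#' @param alpha FDR threshold used only to set the `direction` label
#'   (default 0.05).
#' @param dispersion Optional externally supplied per-feature dispersions;
#'   estimated with [estimate_dispersion()] when NULL.
#' @return A data.frame of class `de_result` with columns `feature_id`,
#'   `log2fc`, `p_value`, `fdr`, `direction` (`up`/`down`/`none`).
#' @export
de_test <- function(x, design, alpha = 0.05, dispersion = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  d <- as_design(design)
  if (is.null(x$scale_factors)) x <- upper_quartile_normalize(x)
  if (is.null(dispersion)) dispersion <- estimate_dispersion(x, d)
  case_ids <- d$sample_id[d$group == "case"]
  ctrl_ids <- d$sample_id[d$group == "control"]
  feats <- rownames(x$counts)
  norm <- x$normalized
  l2fc <- log2(rowMeans(norm[, case_ids, drop = FALSE]) + 0.5) -
    log2(rowMeans(norm[, ctrl_ids, drop = FALSE]) + 0.5)
  p <- vapply(feats, function(f)
    nb_exact_test(x$counts[f, ], d, dispersion[[f]], x$scale_factors),
    numeric(1L))
  fdr <- bh_adjust(unname(p))
  direction <- ifelse(fdr < alpha, ifelse(l2fc > 0, "up", "down"), "none")
  res <- data.frame(feature_id = feats, log2fc = unname(l2fc),
                    p_value = unname(p), fdr = fdr, direction = direction)
  rownames(res) <- NULL
  class(res) <- c("de_result", "data.frame")
  res
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf("de_result: %d feature(s), %d with FDR < 0.05 (%d up, %d down)\n",
              nrow(x), sum(x$fdr < 0.05),
              sum(x$direction == "up"), sum(x$direction == "down")))
  NextMethod()
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment via [stats::p.adjust()]; inputs are validated to
#' lie in `[0, 1]`.
#'
#' @param p Numeric vector of p-values.
#' @return FDR-adjusted values in `[0, 1]`.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Protein-transcript direction concordance
#'
#' Features significant at the protein level whose transcript-level test
#' is nominally significant in the same fold-change direction.
#'
#' @param protein_de,transcript_de [de_test()] results sharing a feature
#'   id space.
#' @param fdr_threshold Protein FDR cut-off (default 0.05).
#' @param p_threshold Transcript nominal p cut-off (default 0.05).
#' @return Character vector of concordant feature ids.
#' @export
concordance <- function(protein_de, transcript_de, fdr_threshold = 0.05,
                        p_threshold = 0.05) {
  m <- merge(protein_de, transcript_de, by = "feature_id",
             suffixes = c(".prot", ".tx"))
  hit <- m$fdr.prot < fdr_threshold & m$p_value.tx < p_threshold &
    sign(m$log2fc.prot) == sign(m$log2fc.tx) & m$log2fc.prot != 0
  sort(m$feature_id[hit])
}
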