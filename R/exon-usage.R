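#' Per-sample exon usage fraction
#'
#' Usage is the inclusion evidence divided by the total evidence at the
#' event locus (e.g. junction reads supporting inclusion over all junction
#' reads). A zero total yields a missing value, and the sample is excluded
#' downstream. The numerator/denominator pair is deliberately generic, so
#' read-based and transcript-quantification-based definitions both fit.
#'
#' @param inclusion,total Non-negative counts, `inclusion <= total`
#'   (vectorised).
#' @return Numeric fraction(s) in `[0, 1]`, NA where `total` is 0.
#' @export
usage_fraction <- function(inclusion, total) {
  if (any(inclusion < 0 | total < 0)) stop("counts must be non-negative")
  if (any(inclusion > total)) stop("inclusion count exceeds total count")
  ifelse(total == 0, NA_real_, inclusion / total)
}

#' Mann-Whitney U test
#'
#' Rank-sum U with midranks for ties. The p-value is exact (full
#' enumeration of label assignments, two-sided by doubling the smaller
#' tail, capped at 1) when the pooled sample size is at most
#' `exact_threshold` and there are no ties; otherwise the normal
#' approximation with tie-corrected variance and continuity correction is
#' used. Computation is delegated to [stats::wilcox.test()], whose exact
#' small-sample path implements precisely this convention.
#'
#' @param a,b Numeric vectors (missing values removed).
#' @param exact_threshold Largest pooled size for the exact path
#'   (default 25).
#' @return List with `u` (U statistic of `a`) and `p_value`.
#' @export
mann_whitney_u <- function(a, b, exact_threshold = 25L) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0L || length(b) == 0L)
    stop("a group is empty after removing missing values")
  use_exact <- (length(a) + length(b)) <= exact_threshold
  ht <- suppressWarnings(
    stats::wilcox.test(a, b, exact = use_exact, correct = TRUE))
  list(u = unname(ht$statistic), p_value = unname(ht$p.value))
}

#' Test differential usage of a novel exon between groups
#'
#' Composes [usage_fraction()] and [mann_whitney_u()]: per-sample usage
#' fractions are compared between cases and controls, reporting the U
#' statistic, two-sided p-value, group medians and the direction of the
#' shift.
#'
#' @param usage_counts Data.frame with columns `sample_id`, `inclusion`,
#'   `total`.
#' @param design Sample design, groups `case`/`control`; at least 2
#'   usable samples per group are required.
#' @param exact_threshold Passed to [mann_whitney_u()].
#' @return An object of class `usage_result`: `per_sample_usage` (named,
#'   NA for excluded samples), `u_statistic`, `p_value`, `group_medians`,
#'   `direction` (`higher_in_case`/`higher_in_control`/`none`).
#' @export
test_novel_exon_usage <- function(usage_counts, design, exact_threshold = 25L) {
  stopifnot(all(c("sample_id", "inclusion", "total") %in% names(usage_counts)))
  d <- as_design(design)
  u <- usage_fraction(usage_counts$inclusion, usage_counts$total)
  names(u) <- usage_counts$sample_id
  case_u <- u[intersect(names(u), d$sample_id[d$group == "case"])]
  ctrl_u <- u[intersect(names(u), d$sample_id[d$group == "control"])]
  if (sum(!is.na(case_u)) < 2L || sum(!is.na(ctrl_u)) < 2L)
    stop("need usage for >= 2 samples per group")
  mw <- mann_whitney_u(case_u, ctrl_u, exact_threshold)
  med <- c(case = stats::median(case_u, na.rm = TRUE),
           control = stats::median(ctrl_u, na.rm = TRUE))
  direction <- if (med[["case"]] > med[["control"]]) "higher_in_case"
    else if (med[["case"]] < med[["control"]]) "higher_in_control"
    else "none"
  structure(list(per_sample_usage = u, u_statistic = mw$u,
                 p_value = mw$p_value, group_medians = med,
                 direction = direction),
            class = "usage_result")
}

#' @export
print.usage_result <- function(x, ...) {
  cat(sprintf(
    "usage_result: U = %.1f, p = %.4g, medians case %.3f / control %.3f (%s)\n",
    x$u_statistic, x$p_value, x$group_medians[["case"]],
    x$group_medians[["control"]], x$direction))
  invisible(x)
}
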