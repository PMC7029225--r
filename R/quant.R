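#' Spectral-count matrices
#'
#' A `count_matrix` wraps a features-by-samples matrix of non-negative
#' counts together with, after [upper_quartile_normalize()], per-sample
#' scale factors and the normalized view `counts / scale_factor`.
#'
#' @param counts Numeric matrix, features in rows, samples in columns; row
#'   and column names required.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(!is.null(rownames(counts)) || nrow(counts) == 0L,
            !is.null(colnames(counts)))
  if (any(counts < 0)) stop("negative counts are not allowed")
  structure(list(counts = counts, scale_factors = NULL, normalized = NULL),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d feature(s) x %d sample(s)%s\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$scale_factors)) "" else ", normalized"))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

# Standardise a design into a data.frame(sample_id, group) with groups
# "case"/"control", both non-empty.
as_design <- function(design) {
  if (is.data.frame(design)) {
    stopifnot(all(c("sample_id", "group") %in% names(design)))
    d <- data.frame(sample_id = as.character(design$sample_id),
                    group = as.character(design$group))
  } else {
    d <- data.frame(sample_id = names(design), group = as.character(design))
  }
  if (!all(d$group %in% c("case", "control")))
    stop("design groups must be 'case' or 'control'")
  if (anyDuplicated(d$sample_id))
    stop("duplicated sample id in design")
  if (!all(c("case", "control") %in% d$group))
    stop("both groups must be non-empty")
  d
}

#' Gene-level spectral-count matrix from classified peptides
#'
#' Sums, per gene and sample, the PSM counts of peptides classified
#' `reference_unique` for that gene. Ambiguously mapping and non-reference
#' peptides contribute to no gene, mirroring quantification restricted to
#' peptides uniquely mapping to annotated genes.
#'
#' @param psm_table Data.frame with columns `peptide`, `sample`,
#'   `psm_count`.
#' @param classifications Output of [classify_peptides()] covering every
#'   peptide in `psm_table`.
#' @param samples Optional character vector fixing the sample universe and
#'   column order; any `psm_table` sample outside it is an error.
#' @return A [count_matrix()] over the genes with at least one uniquely
#'   mapping peptide (all-zero rows retained).
#' @export
gene_count_matrix <- function(psm_table, classifications, samples = NULL) {
  stopifnot(all(c("peptide", "sample", "psm_count") %in% names(psm_table)))
  missing_cls <- setdiff(psm_table$peptide, classifications$peptide)
  if (length(missing_cls) > 0L)
    stop("unclassified peptide(s) in psm_table: ", missing_cls[1L])
  if (is.null(samples)) samples <- sort(unique(psm_table$sample))
  unknown <- setdiff(psm_table$sample, samples)
  if (length(unknown) > 0L)
    stop("unknown sample id in psm_table: ", unknown[1L])
  uniq <- classifications[classifications$category == "reference_unique", ,
                          drop = FALSE]
  genes <- sort(unique(uniq$genes))
  m <- matrix(0, nrow = length(genes), ncol = length(samples),
              dimnames = list(genes, samples))
  tab <- merge(psm_table, uniq[, c("peptide", "genes")], by = "peptide")
  if (nrow(tab) > 0L) {
    agg <- stats::aggregate(psm_count ~ genes + sample, data = tab, FUN = sum)
    m[cbind(agg$genes, agg$sample)] <- agg$psm_count
  }
  count_matrix(m)
}

#' Peptide-level count matrix for selected categories
#'
#' @inheritParams gene_count_matrix
#' @param categories Classification categories to keep (default: the two
#'   non-reference categories).
#' @return A [count_matrix()] with peptides in rows.
#' @export
peptide_count_matrix <- function(psm_table, classifications, samples = NULL,
                                 categories = c("nonref_saav",
                                                "nonref_novel_isoform")) {
  if (is.null(samples)) samples <- sort(unique(psm_table$sample))
  keep <- classifications$peptide[classifications$category %in% categories]
  peps <- sort(unique(keep))
  m <- matrix(0, nrow = length(peps), ncol = length(samples),
              dimnames = list(peps, samples))
  tab <- psm_table[psm_table$peptide %in% peps, , drop = FALSE]
  if (nrow(tab) > 0L) {
    agg <- stats::aggregate(psm_count ~ peptide + sample, data = tab, FUN = sum)
    m[cbind(agg$peptide, agg$sample)] <- agg$psm_count
  }
  count_matrix(m)
}

#' Consistent-expression filter
#'
#' Keeps features expressed with at least `min_psm` raw PSMs in at least
#' `min_case` case samples or at least `min_control` control samples
#' (defaults mirror a >=3-PSM, >=5-of-10 cases / >=4-of-8 controls rule).
#' The filter operates on raw counts; feature order is preserved.
#'
#' @param x A [count_matrix()].
#' @param design Sample design (data.frame `sample_id`, `group` or named
#'   vector), groups `case`/`control`.
#' @param min_psm,min_case,min_control Integer thresholds (>= 1).
#' @return The filtered [count_matrix()].
#' @export
filter_consistent <- function(x, design, min_psm = 3L, min_case = 5L,
                              min_control = 4L) {
  stopifnot(inherits(x, "count_matrix"),
            min_psm >= 1L, min_case >= 1L, min_control >= 1L)
  d <- as_design(design)
  case_ids <- d$sample_id[d$group == "case"]
  ctrl_ids <- d$sample_id[d$group == "control"]
  if (min_case > length(case_ids) || min_control > length(ctrl_ids))
    stop("presence threshold exceeds group size")
  cc <- x$counts[, case_ids, drop = FALSE]
  kk <- x$counts[, ctrl_ids, drop = FALSE]
  keep <- rowSums(cc >= min_psm) >= min_case |
    rowSums(kk >= min_psm) >= min_control
  count_matrix(x$counts[keep, , drop = FALSE])
}

#' Group-exclusive non-reference peptides
#'
#' A peptide is case-exclusive when it has zero counts in every control
#' sample, at least `min_psm_total` PSMs in total, and a nonzero count in
#' at least `min_samples` case samples (and symmetrically for
#' control-exclusive). The two sets are disjoint by construction.
#' "Present" means raw count > 0; the total-PSM threshold is applied after
#' exclusivity.
#'
#' @param x A [count_matrix()] restricted to non-reference peptides.
#' @param design Sample design, groups `case`/`control`.
#' @param min_psm_total Minimum total PSMs over all samples (default 5).
#' @param min_samples Minimum number of samples of the exclusive group in
#'   which the peptide is present (default 4).
#' @return List with character vectors `case_exclusive` and
#'   `control_exclusive`.
#' @export
exclusive_nonref_peptides <- function(x, design, min_psm_total = 5L,
                                      min_samples = 4L) {
  stopifnot(inherits(x, "count_matrix"))
  d <- as_design(design)
  case_ids <- d$sample_id[d$group == "case"]
  ctrl_ids <- d$sample_id[d$group == "control"]
  cc <- x$counts[, case_ids, drop = FALSE]
  kk <- x$counts[, ctrl_ids, drop = FALSE]
  total <- rowSums(x$counts[, c(case_ids, ctrl_ids), drop = FALSE])
  case_excl <- rowSums(kk) == 0 & total >= min_psm_total &
    rowSums(cc > 0) >= min_samples
  ctrl_excl <- rowSums(cc) == 0 & total >= min_psm_total &
    rowSums(kk > 0) >= min_samples
  list(case_exclusive = rownames(x$counts)[case_excl],
       control_exclusive = rownames(x$counts)[ctrl_excl])
}

#' Upper-quartile normalization
#'
#' Per-sample scale factors proportional to the 75th percentile of that
#' sample's nonzero counts (type-7 linear interpolation), rescaled so the
#' factors have geometric mean 1; the normalized view is
#' `counts / scale_factor`. Computing quartiles on nonzero counts only is
#' the dominant convention for sparse count matrices.
#'
#' @param x A [count_matrix()]; every sample must have at least one nonzero
#'   count.
#' @return `x` with `scale_factors` and `normalized` populated.
#' @export
upper_quartile_normalize <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  q <- vapply(colnames(x$counts), function(s) {
    v <- x$counts[, s]
    v <- v[v > 0]
    if (length(v) == 0L)
      stop("sample ", s, " has no nonzero counts; cannot normalize")
    stats::quantile(v, 0.75, type = 7, names = FALSE)
  }, numeric(1L))
  sf <- q / exp(mean(log(q)))
  x$scale_factors <- sf
  x$normalized <- sweep(x$counts, 2L, sf, "/")
  x
}
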