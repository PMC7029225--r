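#' Canonicalise an interaction edge list
#'
#' Stores each undirected edge with its endpoints sorted, drops self-edges
#' and duplicate pairs, and carries through a per-edge evidence label
#' (`database`, `experimental` or `both`).
#'
#' @param edges Data.frame with columns `gene_a`, `gene_b` and optionally
#'   `evidence`.
#' @return Data.frame of class `edge_list` with canonical, unique,
#'   self-edge-free rows.
#' @export
as_edge_list <- function(edges) {
  stopifnot(all(c("gene_a", "gene_b") %in% names(edges)))
  a <- pmin(as.character(edges$gene_a), as.character(edges$gene_b))
  b <- pmax(as.character(edges$gene_a), as.character(edges$gene_b))
  ev <- if ("evidence" %in% names(edges)) as.character(edges$evidence)
    else rep("database", length(a))
  keep <- a != b & !duplicated(paste(a, b, sep = "\r"))
  out <- data.frame(gene_a = a[keep], gene_b = b[keep], evidence = ev[keep])
  rownames(out) <- NULL
  class(out) <- c("edge_list", "data.frame")
  out
}

#' Hypergeometric gene-set over-representation
#'
#' One-sided upper-tail hypergeometric test of the overlap between a
#' differentially expressed gene set and each annotation gene set, each
#' intersected with the quantified universe first (standard background
#' correction for detection bias), with Benjamini-Hochberg adjustment
#' across sets. Sets disjoint from the universe are excluded with a
#' warning.
#'
#' @param de_set Character vector of significant genes; must be a subset
#'   of `universe`.
#' @param gene_sets Named list of character vectors, or a long data.frame
#'   with columns `set_id`, `gene_id`.
#' @param universe Character vector of all quantified genes.
#' @return Data.frame with columns `set_id`, `overlap`, `set_size`,
#'   `universe_size`, `de_size`, `p_value`, `fdr`, sorted by `p_value`.
#' @export
hypergeom_enrich <- function(de_set, gene_sets, universe) {
  if (length(universe) == 0L) stop("empty universe")
  if (length(de_set) == 0L) stop("empty DE set")
  universe <- unique(universe)
  de_set <- unique(de_set)
  if (!all(de_set %in% universe))
    stop("de_set must be a subset of the universe")
  if (is.data.frame(gene_sets)) {
    stopifnot(all(c("set_id", "gene_id") %in% names(gene_sets)))
    gene_sets <- split(as.character(gene_sets$gene_id),
                       as.character(gene_sets$set_id))
  }
  rows <- lapply(names(gene_sets), function(sid) {
    g <- intersect(unique(gene_sets[[sid]]), universe)
    if (length(g) == 0L) {
      warning("gene set ", sid, " is disjoint from the universe; excluded")
      return(NULL)
    }
    ov <- length(intersect(g, de_set))
    p <- stats::phyper(ov - 1L, length(g), length(universe) - length(g),
                       length(de_set), lower.tail = FALSE)
    data.frame(set_id = sid, overlap = ov, set_size = length(g),
               universe_size = length(universe), de_size = length(de_set),
               p_value = p)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no gene set overlaps the universe")
  out$fdr <- bh_adjust(out$p_value)
  out <- out[order(out$p_value, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Within-set degrees of an induced interaction subgraph
#'
#' For each gene of the DE set, counts interaction edges whose both
#' endpoints lie in the set — the readout behind statements like "protein
#' X with 19 connections" in a DE-restricted interaction network.
#'
#' @param de_set Character vector of genes.
#' @param edges An [as_edge_list()] data.frame.
#' @return Named integer vector over `de_set` (zero for isolated genes).
#' @export
induced_subgraph_degrees <- function(de_set, edges) {
  edges <- as_edge_list(edges)
  de_set <- unique(de_set)
  keep <- edges$gene_a %in% de_set & edges$gene_b %in% de_set
  deg <- stats::setNames(integer(length(de_set)), de_set)
  tab <- table(c(edges$gene_a[keep], edges$gene_b[keep]))
  deg[names(tab)] <- as.integer(tab)
  deg
}

#' Permutation test for excess network connectivity
#'
#' Asks whether the DE set carries more internal interaction edges than
#' random gene sets of the same size drawn from the quantified universe.
#' The p-value uses the add-one estimator
#' `(1 + #{null >= observed}) / (n_perm + 1)`, so it is never zero, and is
#' fully reproducible given `seed`.
#'
#' @param de_set Character vector, subset of `universe`.
#' @param edges An [as_edge_list()] data.frame.
#' @param universe Character vector of candidate genes.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Optional integer seed.
#' @return List with `observed` (internal edge count), `p_value`,
#'   `null_mean`, `n_perm`.
#' @export
connectivity_permutation_test <- function(de_set, edges, universe,
                                          n_perm = 999L, seed = NULL) {
  stopifnot(n_perm >= 100L)
  universe <- unique(universe)
  de_set <- unique(de_set)
  if (!all(de_set %in% universe)) stop("de_set must be a subset of universe")
  if (length(de_set) > length(universe))
    stop("de_set larger than universe")
  edges <- as_edge_list(edges)
  edges <- edges[edges$gene_a %in% universe & edges$gene_b %in% universe, ,
                 drop = FALSE]
  ia <- match(edges$gene_a, universe)
  ib <- match(edges$gene_b, universe)
  count_internal <- function(members) {
    inset <- logical(length(universe))
    inset[members] <- TRUE
    sum(inset[ia] & inset[ib])
  }
  observed <- count_internal(match(de_set, universe))
  if (!is.null(seed)) set.seed(seed)
  k <- length(de_set)
  null <- vapply(seq_len(n_perm), function(i)
    count_internal(sample.int(length(universe), k)), numeric(1L))
  list(observed = observed,
       p_value = (1 + sum(null >= observed)) / (n_perm + 1),
       null_mean = mean(null), n_perm = n_perm)
}
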