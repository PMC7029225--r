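# Independent oracles and small fixtures used across test files. These are
# deliberately naive re-derivations (enumeration, brute force, literal codon
# table) kept separate from the package implementation.

# --- codon-table translation oracle (independent of Biostrings) --------------
ORACLE_CODONS <- local({
  bases <- c("T", "C", "A", "G")
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1L]]
  codons <- as.vector(t(outer(
    as.vector(t(outer(bases, bases, paste0))), bases, paste0)))
  stats::setNames(aas, codons)
})

oracle_translate <- function(cds) {
  n <- nchar(cds) %/% 3L
  out <- character(0L)
  for (i in seq_len(n)) {
    aa <- ORACLE_CODONS[[substr(cds, 3L * i - 2L, 3L * i)]]
    if (aa == "*") break
    out <- c(out, aa)
  }
  paste(out, collapse = "")
}

# --- brute-force tryptic digestion oracle ------------------------------------
oracle_digest <- function(prot, mc, min_len, max_len) {
  n <- nchar(prot)
  if (n == 0L) return(character(0L))
  aa <- strsplit(prot, "", fixed = TRUE)[[1L]]
  is_site <- function(i) i >= 1L && i < n && aa[i] %in% c("K", "R") &&
    aa[i + 1L] != "P"
  out <- character(0L)
  for (i in seq_len(n)) for (j in i:n) {
    len <- j - i + 1L
    if (len < min_len || len > max_len) next
    if (!(i == 1L || is_site(i - 1L))) next
    if (!(j == n || is_site(j))) next
    internal <- if (j > i)
      sum(vapply(i:(j - 1L), is_site, logical(1L))) else 0L
    if (internal <= mc) out <- c(out, substr(prot, i, j))
  }
  unique(out)
}

random_aa_string <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]], len,
               replace = TRUE), collapse = "")
}

# --- exact Mann-Whitney enumeration oracle (tie-free data) -------------------
oracle_mw_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  r <- rank(pooled)
  u_of <- function(sel) sum(r[sel]) - n * (n + 1) / 2
  obs <- u_of(seq_len(n))
  sel <- utils::combn(length(pooled), n)
  us <- apply(sel, 2L, u_of)
  min(1, 2 * min(mean(us <= obs), mean(us >= obs)))
}

# --- hand-built two-gene toy annotation --------------------------------------
# geneP: plus strand, two exons; geneM: minus strand, one exon. Sequences are
# written out explicitly so every expectation is checkable by eye.
toy_annotation <- function() {
  #           1        10        20        30        40        50
  # geneP CDS "ATG AAA CGT CCT ATT GAT GAA TAA" split after codon 4
  cdsP <- "ATGAAACGTCCTATTGATGAATAA"
  ex1 <- substr(cdsP, 1L, 12L)
  ex2 <- substr(cdsP, 13L, 24L)
  intron <- "GGGGGGGGGGGGGGGGGGGGGGGGGGGGGG"   # 30 nt
  # geneM CDS "ATGATGTAG" -> genomic plus strand "CTACATCAT"
  chrom <- paste0(ex1, intron, ex2, "AAAA", "CTACATCAT", "AAAA")
  genome <- Biostrings::DNAStringSet(c(chrT = chrom))
  mP <- transcript_model("TXP", "GENEP", "chrT", "+",
                         data.frame(start = c(1L, 43L), end = c(12L, 54L)),
                         1L, 54L)
  mM <- transcript_model("TXM", "GENEM", "chrT", "-",
                         data.frame(start = 59L, end = 67L), 59L, 67L)
  list(genome = genome, models = list(TXP = mP, TXM = mM))
}
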