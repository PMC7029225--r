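---
title: "Methods: sample-specific proteogenomic analysis with pgxpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sample-specific proteogenomic analysis with pgxpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgxpipe)
```

# The problem and the model

Shotgun proteomics identifies peptides by matching MS/MS spectra against a
protein database; anything absent from that database is invisible. In a
case-control tissue study with matched RNA-seq, each sample's transcriptome
predicts protein sequence that the canonical reference lacks: single amino
acid variants (SAAVs) from non-synonymous SNVs, and novel isoforms from
unannotated splice events. pgxpipe implements the resulting workflow:

1. build a *sample-specific* protein database per sample (canonical
   proteome ∪ that sample's variant and isoform proteins);
2. classify observed peptides as reference (unique or ambiguous gene
   mapping) vs non-reference (SAAV or novel isoform);
3. quantify by spectral counts (PSMs) with presence and exclusivity
   filters and upper-quartile normalization;
4. test differential expression, novel-exon usage, gene-set
   over-representation and network connectivity.

The flagship scenario the synthetic generator reproduces is a cryptic
in-frame exon in a minus-strand gene: a 714-nt insertion that adds exactly
714/3 = 238 residues to the translated protein and whose junction-spanning
tryptic peptides exist in no canonical protein, making the isoform
identifiable only through the sample-specific database.

# Coordinates and sequence handling

All coordinates are **1-based and closed** everywhere — the native
convention of GTF, VCF and the Bioconductor ranges stack. Because the
internal convention equals the file conventions, no conversions exist and
no off-by-one class can arise. (A 0-based half-open internal convention
would be equally consistent but foreign to the R ecosystem this package
lives in.)

Strand handling is centralised in `spliced_cds_sequence()` (exons are
concatenated in genomic order, then reverse-complemented for minus-strand
transcripts) and `apply_variants()` (VCF alleles are plus-strand, so they
are complemented before substitution into a minus-strand CDS).

Other sequence-level policies:

* **Only SNVs.** The non-reference peptides of interest at protein level
  are single-residue substitutions; indel records are rejected with a
  clear error rather than silently mistranslated.
* **Joint application.** All of a sample's variants on a transcript are
  substituted before translation, so two hits in one codon yield the
  codon containing both.
* **Premature stops truncate, with a flag.** A variant or frameshift that
  creates an internal stop produces the truncated protein plus a warning
  of class `pgx_premature_stop` (captured into the database record). The
  truncated record is retained because peptides upstream of the stop
  remain valid evidence; aborting would discard them.
* **Novel exons are assumed in frame when their length is divisible
  by 3**; other lengths translate through to the first stop and are
  flagged the same way.
* A `confirmed_gene_model` provenance label is reserved in the record
  grammar but never emitted: the package has no operational definition
  for it, so it exists only for forward compatibility of the header
  format.

# Digestion and the matching convention

Tryptic digestion cleaves C-terminal to K or R except before P. Defaults —
≤2 missed cleavages, peptide length 7–35 — are the field-standard search
settings; they are explicit arguments everywhere because no single
published convention is universal.

Reference-vs-novel decisions default to treating **isoleucine and leucine
as indistinguishable** (identical residue mass; standard fragmentation
cannot separate them). This only ever *removes* novelty claims: a peptide
whose sole difference from a canonical peptide is I↔L is classified
reference, preventing false positives. Strict matching is available via
`il_equivalent = FALSE`, and a property test asserts the I/L convention
never yields more non-reference calls than strict matching.

Tie-break: a peptide explainable by both a SAAV record and a novel
isoform is labelled `nonref_novel_isoform`, deterministically. One label
per peptide keeps downstream tallies consistent; the supporting records
remain inspectable through the index.

Gene-level quantification uses **gene-level** mapping uniqueness, not
isoform-level: a peptide shared by two isoforms of one gene is still
"uniquely mapping" for counting purposes.

# Quantification rules

* Presence filter: keep a feature expressed with ≥ `min_psm` (3) raw PSMs
  in ≥ `min_case` (5) case samples **or** ≥ `min_control` (4) controls.
  Filtering operates on *raw* counts — the thresholds are integer PSM
  counts, and normalization would make them unit-less. Whether such
  filters should precede or follow normalization is genuinely open; raw-
  count filtering is chosen and stated.
* Exclusivity: a non-reference peptide is case-exclusive when every
  control count is zero, total PSMs ≥ `excl_min_total` (5) and it is
  present (count > 0) in ≥ `excl_min_samples` (4) cases; symmetrically
  for controls. The total-PSM threshold applies after exclusivity.
* Upper-quartile normalization: per-sample factor ∝ the 75th percentile
  of the sample's **nonzero** counts, computed with type-7 linear
  interpolation (R's default order statistic), then rescaled so factors
  have geometric mean 1. Restricting to nonzero counts is the dominant
  convention for sparse count matrices (the 75th percentile of a sparse
  column is otherwise 0); type 7 and geometric-mean anchoring are stated
  so the procedure is reproducible bit for bit. Renormalizing a
  normalized matrix returns factors of 1 to within 1e-12.

# The differential-expression test

The DE component is authored here rather than delegated: a conditional
exact test with moment-based shrunken dispersion, with the conventional
interface (log2FC, p, BH FDR).

* **Dispersion.** Under `variance = μ + μ²φ`, the raw per-feature moment
  estimate `max(0, (s² − m)/m²)` is computed on scale-factor-adjusted
  counts *within* groups (df-weighted), so true group differences do not
  masquerade as dispersion. Raw estimates are then shrunk halfway toward
  the 10%-trimmed mean over features: per-feature moments at n = 10 + 8
  are noisy, and features share technology-driven dispersion. The weight
  (0.5) and trim (0.1) are exposed arguments.
* **Exact test.** Conditioning on a feature's total count, the observed
  case/control split is compared with its conditional null distribution:
  group sums are treated as NB with size `n_g/φ` and means proportional
  to the groups' summed scale factors. At φ = 0 this is exactly the
  binomial conditional test of Poisson counts. Two-sidedness sums the
  probabilities of all splits no more probable than the observed one
  (minimum-likelihood ordering) — well defined for asymmetric discrete
  nulls, unlike tail doubling. A zero total returns p = 1.
* **Fold-changes** are case-over-control ratios of normalized group means
  with a pseudo-count of 0.5, keeping them finite and bounded.
* Covariates are deliberately out of scope: the test is unadjusted
  two-group. With demographically imbalanced groups this is a real
  limitation, flagged here rather than hidden.

Property tests at the study's scale (n = 10 vs 8, 2,000 features, 20
replicates) check that the null rejection rate at p < 0.05 stays in
[0.03, 0.07], the realized false-discovery proportion at FDR < 0.05 stays
≤ 0.10 with 10% planted effects at |log2FC| = 2, and ≥ 70% of planted
effects are recovered.

# Exon usage and the Mann–Whitney test

"Usage" is defined as an inclusion/total evidence ratio per sample
(0/0 = missing, sample excluded); the numerator/denominator pair is
generic, so junction-read and transcript-quantification definitions both
fit — the upstream definition is not prescribed by the package.
Group comparison uses the Mann–Whitney U test via `stats::wilcox.test`:
exact enumeration when the pooled size is ≤ 25 and tie-free (two-sided by
doubling the smaller tail, capped at 1), otherwise the normal
approximation with tie-corrected variance and continuity correction. An
independent enumeration oracle in the test suite confirms equality of the
exact path for all pooled sizes ≤ 12.

# Enrichment and connectivity

Over-representation uses the one-sided hypergeometric upper tail, each
set first intersected with the **quantified-gene universe** (not the
whole annotation): detection in spectral counting is abundance-biased,
and testing against all annotated genes would manufacture enrichment of
highly expressed categories. The network view applies a stricter
FDR < 0.01 input threshold than enrichment (FDR < 0.05), both
configurable. Edge evidence labels (`database`/`experimental`/`both`)
are carried through but not filtered by default. The connectivity
permutation test draws size-matched gene sets uniformly from the
universe and uses the add-one estimator `(1 + #{null ≥ obs})/(n_perm+1)`,
which is never zero and is exactly reproducible given its seed.

# What the synthetic generator emulates — and what it does not

The generator's defaults are the study conditions: 10 cases vs 8
controls; 50 multi-exon coding genes; 20% true-DE genes at |log2FC| = 2;
NB PSM counts with mean 30 and dispersion 0.3; per-gene probability 0.3
of one sample-private missense SNV; one cryptic 714-nt in-frame exon in
the first intron of a minus-strand host gene, carried by cases with
probability 0.9 and by controls with 0.1; transcript counts whose DE
direction agrees with the protein effect for 80% of true-DE genes. Counts
use the mean/dispersion NB parameterisation (variance = μ + μ²φ), the
standard for count DE simulation. Where the emulated design fixes no
value (gene count, NB mean, usage evidence depth of ~60 per sample,
background edge probability 0.05), values were chosen once as typical of
a desk-scale study of this kind and are documented in `?sim_config`.

Faithful by construction:

* every PSM-table peptide digests out of the emitting sample's database;
* SAAVs are missense by construction (never touching the start codon,
  never creating a stop);
* isoform peptides never receive counts in samples not carrying the exon;
* all outputs are pure functions of the configuration (byte-identical
  reruns).

Deliberately not modelled: MS/MS spectra, retention times and
identification error (the PSM table emulates *post-search* output);
read-level RNA-seq (per-sample presence of variants/isoforms is an
explicit flag, because evidence thresholds for calling presence from
reads are a study-specific choice upstream of this package);
heterozygosity and phasing (any sample variant is applied); protein
inference by parsimony; PTMs and semi-tryptic peptides. Passing tests
therefore demonstrate correctness of the pipeline's logic and the
statistical calibration of its tests under a clean generative model —
not robustness to search-engine error, chimeric spectra or alignment
artefacts in real data.

# Numerical and degenerate-input choices

* Exact-test probability comparison uses a relative tolerance of 1e-10
  when summing "no more probable" outcomes, so floating-point noise
  cannot drop the observed outcome itself.
* BH adjustment delegates to `stats::p.adjust`; hypergeometric tails to
  `stats::phyper`; translation to `Biostrings::translate` (an
  independent hand-written codon-table oracle cross-checks it in the
  tests).
* Degenerate inputs fail loudly and by name: an all-zero sample in
  normalization, thresholds exceeding group sizes, a CDS not divisible
  by 3, a reference-allele mismatch, a gene set disjoint from the
  universe, a group emptied by missing usage values.
* Pipeline determinism: the report is a pure function of the run
  configuration; the timestamp is the only excluded field.

# Problem sizes

The test suite exercises the generator at 5–60 genes and the statistical
properties at the study's native 10-vs-8 design with 500–2,000 features
and 20–200 replicates; the acceptance script runs the full default
configuration (50 genes, 18 samples, 999 permutations). These sizes make
every property check run in seconds to a few minutes while keeping the
group-size asymmetry and count regime of the emulated study.

# Known limitations

* The DE test conditions on totals with group sums approximated as NB;
  with strongly unequal scale factors within a group the approximation
  coarsens (the geometric-mean-1 factors keep it mild in practice).
* Dispersion shrinkage with a fixed weight is simpler than empirical-
  Bayes approaches; it is calibrated for the emulated regime, not
  optimal for all.
* No covariate adjustment in any test.
* Classification trusts the digestion model: peptides produced by
  non-tryptic cleavage would be reported `unmatched`.
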