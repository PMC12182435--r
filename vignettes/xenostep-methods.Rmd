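---
title: "Methods: cross-species shared T-cell epitope scoring"
author: "xenostep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species shared T-cell epitope scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xenostep)
```

# The model

`xenostep` quantifies indirect CD4+ T-cell alloreactivity between a
transplant recipient and one or two donor grafts, in the human (HLA) and
swine (SLA) MHC systems.

An *indirect epitope* here is a pair: a recipient class-II presenter
allele (HLA-DRB1-like, at two-field resolution) together with the
specific 9mer core peptide it presents. The **T2 score** of a
recipient/donor pair counts these pairs after a three-stage pipeline:

1. **Donor peptidome.** All 15mers of every donor MHC protein, class I
   and class II, pooled as a set. A swine donor contributes all SLA loci
   in its genotype; the reference xenodonor genotype carries 15 allele
   slots over 7 loci, including three SLA-1 alleles, so loci admit 1-3
   alleles rather than enforcing diploidy.
2. **Self-filter.** Donor 15mers that also occur among the recipient's
   own MHC-derived 15mers are discarded: peptides the thymus has seen
   are not foreign. Filtering compares full 15mers by default; a
   stricter core-level variant (discarding calls whose 9mer core occurs
   among the recipient's 9mer windows) is available as
   `selfFilter = "core"`.
3. **Presentation.** Each surviving peptide is ranked against each
   recipient presenter allele by a binding predictor; calls at or below
   the percentile threshold (default 10, the conventional weak-binder
   cutoff; the rank scale is 0-100, lower = stronger) contribute their
   (presenter, core) pair. Duplicate pairs reached through several donor
   peptides count once.

The **STEP score** for sequential grafts is the size of the intersection
of the two grafts' epitope sets for the same recipient, a proxy for the
risk that the first graft primes memory T cells reactive to the second.
Intersection makes the score symmetric in graft order, which the
swine-after-human versus human-after-swine comparison verifies
empirically (both directions are computed independently).

Allele identity everywhere is the two-field name (`HLA-A*01:01`); deeper
nomenclature fields are preserved on parsing but ignored in set
operations, matching how alleles are matched in practice when only
two-field typing is available. An alternative epitope identity using the
full 15mer instead of the core (`epitopeIdentity = "peptide"`) is
provided for sensitivity analysis; distinct 15mers can collapse onto one
core, so core-identity scores are never larger.

# Sequence comparison choices

Pairwise dissimilarity is a Hamming distance over a pairwise global
alignment: the count of alignment columns whose symbols differ.

* **Alignment.** Needleman-Wunsch with affine gaps via
  `Biostrings::pairwiseAlignment`. The default scheme is an identity
  matrix (match +1, mismatch 0) with a per-position gap cost of 1:
  when the quantity of interest is a count of differing positions, a
  similarity-calibrated matrix such as BLOSUM62 would distort the
  distance, so BLOSUM62 is optional. `'X'` (unknown residue) never
  counts as a match, including against itself. Traceback is
  deterministic, so reruns give identical alignments.
* **Gap columns** count as differences by default (a length difference
  is a difference); `countGaps = FALSE` ignores them. The published
  convention for this choice is not stated anywhere authoritative, so
  both are exposed and the default is the conservative one.
* **Trees.** Neighbor joining (`ape::nj`) on the distance matrix,
  serialized as Newick. Additive matrices are recovered to their exact
  path metric (checked to 1e-9 in the tests); tiny negative branch
  lengths that NJ can produce on non-additive input are clamped to
  zero. The species-separation claim is tested with an explicit
  monophyly predicate: some single edge must bipartition the leaves
  exactly into the two species.

This is deliberately lighter machinery than a multiple alignment plus
maximum-likelihood phylogeny: the claims being made (two species form
two clades; cross-species distances dwarf within-species ones) are
topological and robust, and pairwise alignment + NJ supports them
without external binaries. The package does not attempt bootstrap
supports or likelihood models.

# The binding predictor contract

Real class-II binding prediction requires a trained model. The pipeline
therefore isolates it behind a one-method contract: given (presenter
allele, presenter sequence, 15mer peptides), return per peptide a
percentile rank and a 9mer core with its offset. Any object with a
`predictBinding` method satisfies it.

The bundled `mockPredictor()` is a pure deterministic function designed
around two requirements: reruns must be bit-identical everywhere
(private Lehmer-LCG streams, no use of R's RNG), and presentation rates
must not depend on residue composition. The second requirement is worth
spelling out. An earlier design scored 9mer windows with a per-presenter
position-weight matrix of independent uniform weights. Under the
synthetic worlds' disjoint species vocabularies (below), each presenter's
mean weight over one species' 10 letters differs from the other's by
enough (the subset mean has standard deviation ≈ 0.09 per position) that
a presenter systematically presents one species' peptides at a multiple
of the other's rate. Real HLA- and SLA-derived peptides share one
20-letter alphabet and similar composition, so a trained predictor has
no such species-level rate bias — the bias was an artifact of crossing a
residue-level scorer with a vocabulary-partitioned toy alphabet, and it
distorted exactly the cross-species contrasts this package exists to
measure. The shipped design instead hashes the (presenter sequence, 9mer
window) pair to a uniform score: presenter-specific, deterministic, and
exchangeable across peptide pools, so any peptide set is presented at
the threshold rate in expectation.

Each 15mer's core is its best-scoring window among the seven 9mer
offsets (earliest offset on ties). The rank is the percentage of a fixed
background set — 10,000 15mers drawn once from a typical vertebrate
residue-frequency model under a constant internal seed, regenerated
deterministically at first use — whose best-window score is at least the
peptide's. The best background peptide therefore ranks at 100/N, and
ranks are monotone in the underlying score, which the tests verify with
a sort-based oracle.

# The synthetic world generator

No public accessions reproduce the original allele universes, so the
package ships a generator whose outputs carry *provable* ground truth,
and all distributional claims in the tests are claims about these
worlds.

* **Disjoint vocabularies.** The human-like universe uses one half of
  the amino-acid alphabet, the swine-like universe the other. Every
  cross-species position differs, so baseline cross-species peptidome
  sharing is exactly zero — not approximately, provably.
* **Injected sharing.** `nSharedKmers` distinct 15mers built from
  human-vocabulary letters are written verbatim into carrier alleles of
  both species, round-robin across alleles, at offsets separated by at
  least one native residue. Any all-human-letter window of a swine
  allele must then lie inside a single injected segment, so the
  cross-species peptidome intersection equals the injected set exactly
  — the key to exact parameter recovery (`n_shared == G` for
  G ∈ {0, 1, 5, 50} in the tests).
* **Divergence hierarchy.** Each species has one base sequence; each
  locus base substitutes `locusDivergence` positions (paralog
  divergence); each allele substitutes `withinDivergence` more
  (allelic polymorphism). Defaults — 180-residue proteins (the order of
  a mature MHC chain), 5 substitutions per allele, 15 per locus —
  realize within-locus ≈ 6%, cross-locus ≈ 22%, cross-species 100%
  divergence. Observed MHC data order these the same way (roughly 12%,
  29%, 54% of positions for class I); the generator preserves the
  hierarchy while the vocabulary construction exaggerates the last step
  to make ground truth exact. Substitution-only evolution (no indels)
  keeps positional Hamming distances exact in the recorded truth.
* **Haplotypes and genotypes.** A weighted haplotype table over the
  human loci (A, B, C, DRB1) with geometrically decaying, jittered
  weights (ratio ≈ e^-0.15 per rank): skewed like population frequency
  tables, but flat enough that two random donors regularly collide on
  alleles the patient lacks — without that, within-species shared
  epitopes would be degenerate at zero and the repeat-transplant
  contrast would be untestable. Genotypes are two weighted haplotype
  draws with replacement; the generated xenodonor takes three alleles
  at the first swine locus and two elsewhere, mirroring the reference
  SLA genotype's shape across all seven loci (class I and II).
* **What is not emulated.** Real allele-frequency spectra, linkage
  disequilibrium, indels, recombination, locus-specific length
  variation, and — most importantly — real binding specificity. Passing
  tests on these worlds demonstrate the pipeline's correctness and the
  robustness of the qualitative contrasts (xenograft epitope load above
  every human donor; order-free memory scores; cross-species memory
  below human-after-human), not quantitative agreement with any
  published score magnitudes, which depend on database snapshots and a
  trained predictor.

# Cohort simulation

Virtual patients (`P0001`...) and donors (`D0001`...) are sampled from
the haplotype table through per-individual RNG substreams keyed by
(master seed, individual id), so enlarging the donor pool never perturbs
patient genotypes and every summary is bit-reproducible from its seed.
For each patient the T2 score is computed against every human donor and
the xenodonor — internally over the union of candidate peptides per
patient, which is provably equivalent to the per-pair scorer and is
cross-checked against it in the tests. Per-patient medians over the
human donor pool (even-length medians are the mean of the central order
statistics) define optimum patients, with all ties retained.

The repeat-transplant analysis draws, per patient, one human donor for
the swine-after-human and human-after-swine directions — both computed
explicitly, in their stated order — and a second, independently drawn
human donor for the human-after-human control. Drawing the second donor
independently (rather than reusing some other pairing) is a choice the
analysis makes explicit; it matches the intent of a randomly allocated
repeat transplant. Reported per direction: the full score vector, the
median, and the fraction of patients sharing zero epitopes.

Test and acceptance runs use 100 patients × 50 donors with an
8-haplotype table, and 200 randomized miniature worlds (≤ 5 alleles of
≤ 40 residues) for the exhaustive brute-force oracle comparisons —
sizes at which exact enumeration is feasible and the qualitative
contrasts are already stable across seeds.

# Numerical and degenerate-input conventions

* Shared-percentage denominator: the summed pool sizes
  (`n_a + n_b`), reported to one decimal; the union denominator is a
  flag. With the published pool counts (158,083 / 13,969 / 894) both
  round to the same 0.5%.
* Windows containing `'X'` are dropped during peptidome extraction, not
  expanded: an unknown residue can be neither matched nor bound.
* `is_presented` is inclusive at the threshold (`rank <= threshold`),
  so loosening a threshold never un-presents a peptide.
* Homozygous alleles are retained in genotype slots but deduplicated in
  every set context (self peptidome, presenter list, donor pool).
* Degenerate inputs fail fast with named errors: empty FASTA or
  genotype files, non-amino-acid residues (with record and position),
  alleles missing from the sequence database (listed at scoring time),
  recipients with no presenter allele, asymmetric or negative distance
  matrices, infeasible injection demands.
* Two-field truncation is applied at comparison time only; raw names
  round-trip through the parser unchanged.

# Known limitations

The mock predictor ranks peptides without any binding biology, so
absolute T2/STEP magnitudes have no clinical meaning; only contrasts
computed under the same predictor are interpretable. Epitope identity is
exact (presenter + identical core); near-identical cores that might
cross-react are counted as distinct, so shared-epitope counts are
conservative lower bounds under more lenient identity notions. The
structural side of cross-species MHC similarity (rigid structure
alignment of crystal structures) is outside this package's scope; only
the generic pairing-scheme enumeration that such designs use is
provided.
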