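---
title: "Methods: models, parameters and design choices in radmut"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in radmut}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(radmut)
```

`radmut` analyses somatic mutations of clonally expanded cell lines
exposed to particle radiation. This vignette documents the statistical
models, the parameters that matter, the synthetic-data generator, and the
design choices made where more than one reasonable convention exists.

## Variant filtering

One cohort is one cell line: its clones are samples of a single jointly
genotyped VCF, so a mutation acquired by one clone after the experimental
bottleneck appears genotyped in that clone only, while pre-existing
(germline or shared ancestral) variation is genotyped in several. The SNV
cascade keeps records that (1) pass the caller's sample and call filters,
(2) lie in uniquely mappable sequence, (3) have population allele
frequency absent or below `af_max` (default 0.001, i.e. 0.1%), (4) are
genotyped in exactly one clone, (5) are not multiallelic, and (6) have at
least two alt-supporting reads in the genotyped clone. Indels add a
genotype-quality floor (`gq_min = 10`) and two cross-clone support rules
(remove when more than two other clones have any alt-supporting read, or
more than one other clone has two or more), which catch residual germline
indels genotyped in one clone only. SVs replace rule 6 with a split-read
floor (`sr_min = 2`) and impose no spanning-read requirement.

Conventions worth stating explicitly:

* "Genotyped" means a non-missing genotype containing a non-reference
  allele for that clone; for multiallelic rows the per-allele genotype is
  used, but such rows are removed outright by rule 5 (the rule operates on
  the VCF row, before per-allele decomposition).
* A missing population allele frequency passes rule 3 — absence from the
  database is evidence of rarity, not missingness to be imputed.
* Mappability is consumed, not computed: either as a 0/1 INFO flag or via
  `apply_mappability_mask()` with a BED mask (0-based half-open; all
  coordinate conversion goes through `pos_to_bed()`/`bed_to_pos()`).
* Genotype quality is required for indels only; SNV rules never touch GQ.
* Inversions are consumed as already-converted records;
  `convert_breakends_to_inversions()` merges mated breakend pairs of
  consistent orientation on one chromosome as a convenience utility.

Every rule is independently toggleable through the `rules` argument;
dropping a rule provably yields a superset (the cascade is a conjunction),
and filtering is idempotent. Both properties are tested.

## Mutation classification

SNVs are tallied strand-symmetrically on the pyrimidine strand, either
into 6 substitution types or the 96 trinucleotide-context categories
(`A[C>A]A`, ...). The genome base must equal the VCF REF allele, otherwise
classification aborts — silent reference mismatches corrupt whole spectra.

Indels follow the 83-category COSMIC-style scheme: 1 bp events are binned
by the homopolymer run length of the affected base (C/T channels after
pyrimidine folding); longer events by the number of additional exact
tandem copies of the indel sequence in the flanking reference; deletions
with no tandem copy by the length of flanking microhomology (the longest
prefix of the deleted sequence matching the sequence immediately after
it, or suffix matching immediately before, capped at length − 1). Two
conventions are decisions rather than published requirements: indels are
**left-normalized** before counting (repeat-unit counts are ambiguous
otherwise), and repeat context takes precedence over microhomology. The
test suite carries a constructive 83-exemplar fixture — one
mini-chromosome per category whose structure implies the category by
construction — and requires every category to be hit exactly once.

## Signature extraction

A categories × clones count catalog is factorized as signatures ×
exposures by non-negative matrix factorization under the Kullback–Leibler
divergence (the natural objective for count data), with multiplicative
updates, at most 1,000 iterations and relative tolerance 1e−8. The
objective is monotone non-increasing, which the tests assert.

For each candidate rank, `n_replicates` runs are performed on per-clone
multinomial bootstrap resamples of the catalog; replicate signatures are
matched one-to-one (greedy cosine matching) to a reference run on the
unresampled catalog, and the per-signature stability is the mean cosine
of matched replicates to their consensus. Rank selection looks for "high
stability and low reconstruction error": among ranks with mean stability
≥ 0.8, a larger rank is accepted only when it lowers the relative
Frobenius reconstruction error by at least 5%. The error-elbow guard
exists because redundant extra components can remain bootstrap-stable
while adding essentially no fit — on simulated three-process catalogs the
"largest stable rank" rule reliably overshot by one, whereas the elbow
rule recovers the generating rank. Exposures are refit per clone by
non-negative least squares against the consensus signatures, so
attributed mutation counts sum to (approximately) the observed burdens;
this matches reporting exposures as "mutations attributed".

Extracted signatures are assigned to a reference catalog when the cosine
similarity is at least 0.85 (inclusive; ties broken lexicographically with
a warning), and decomposed into reference mixtures by non-negative least
squares with pruning of components below 5% weight followed by a refit.
The subsampling robustness check removes half of each external dataset
(uniformly at random, `n_repeats = 3`), re-extracts with the same seed,
and reports best-match cosines and exposure correlations on the cohort's
own clones — with nothing removed the re-extraction is bit-identical.

## Clustered mutations

Point mutations of one clone are nodes of a graph with an edge whenever
two mutations on the same chromosome are strictly less than 1 kb apart
("lower than 1 kb" is a strict inequality; position 100 and 1100 are not
linked). Clusters are connected components of size ≥ 2; components of
size strictly greater than 5 are kataegis-like showers, the rest
omikli-like. Because clustering is via connectivity, chained mutations
whose endpoints are more than 1 kb apart still form one cluster. On a
line, connected components under this rule are exactly maximal runs of
sorted positions with consecutive gaps below the threshold, so the
implementation is a linear sweep; its exact equivalence to an O(n²)
all-pairs union-find oracle is an acceptance-level test. Inter-mutation
distances are reported per qualifying pair (edge), each unordered pair
once; a `consecutive` mode is available as a configuration switch. SNVs
only enter clustering by default; the caller can pass indels explicitly
if wanted.

## Burden statistics

Group comparisons use a label-shuffling randomization test: clone labels
are shuffled globally across the whole cohort (implemented as value
permutation against the fixed design, which is equivalent and keeps
stratified group sizes constant), group means are recomputed per shuffle,
and two empirical p-values are reported per comparison, p = (r + 1)/(n +
1) with r the number of shuffles at least as extreme on each side. The
default is n = 100,000 shuffles; the headline `p` is the minimum of the
two one-sided values (both are retained, since direction matters for
reporting). Comparisons of shuffled to observed differences use a small
relative tolerance (1e−8) so exact ties count as exceedances on both
sides regardless of floating-point summation order. Benjamini–Hochberg
correction is applied within statistic families (SNV signatures, indel
signatures, burdens), and comparisons with unadjusted p ≤ 0.1 are flagged
for reporting. Deletion:insertion ratios are computed per clone or pooled
(deletions/insertions for small indels; DEL/(INS + DUP), log2, for SVs;
zero denominators yield `NA` unless a pseudocount is configured), and
length or distance comparisons use Welch's t-test, with t = 0, p = 1 for
fully degenerate equal groups.

## Regional enrichment

Mutation counts per precomputed genomic bin (BED, 0-based half-open, with
an ordinal covariate such as replication-timing quantile) are modeled by
negative binomial regression with log link (`MASS::glm.nb`, maximum
likelihood dispersion). Sequence composition is controlled by a
log-opportunity offset computed from per-bin at-risk site counts — the
default, since it asserts proportionality to opportunity — with a
covariate-term mode as the alternative when that assumption should be
relaxed. Covariate-level coefficients are log rate ratios against the
reference level. Treatment effects on the regional relationship are
tested as treatment × level interactions in a joint model with Wald
p-values. `simulate_regional_bins()` generates calibration data; with
2,000 bins and a true 2× late-replication rate the level coefficient is
recovered within ±0.1 of ln 2, and with near-zero dispersion the NB fit
agrees with a Poisson fit to 1e−3.

## The synthetic cohort generator

`default_design()` mirrors the shape of a three-cell-line irradiation
experiment: 3 lines × (1 control + 2 helium + 4 proton) = 21 clones, with
haploid, diploid-heterozygous and tetraploid-heterozygous VAF models
(mean VAF 1.0 / 0.5 / 0.25, binomial reads at depth 40). Burdens are of
order 10³ SNVs and 10²–10³ indels per clone, at the scale the motivating
experiments report per clone. Treatment effects are present by
construction: proton clones carry ~2× more deletions relative to
insertions than controls, treated clones carry injected clusters (helium
more than proton: 25 pairs + 3 showers of 7 vs 15 pairs + 1 shower of 6,
spans chosen so consecutive spacings stay under the 1 kb rule), and
treated SVs are deletion-enriched and shorter. Signature exposures differ
mainly between cell lines (oxidative-C>A-, clock-C>T- and T>C-dominated
mixtures respectively), with a small proton-shift toward the oxidative
spectrum within each line; strong between-line differences are what make
the pooled catalog well-conditioned for factorization, and they emulate
the pronounced cell-line specificity of signature activity in real
cohorts.

SNVs are drawn category-first from the exposure-weighted spectrum mixture
and then placed at genome sites whose (pyrimidine-folded) trinucleotide
context matches, sampling without replacement — this guarantees the
realized 96-spectrum converges to the truth mixture. Indels are drawn
from fixed ID83 category mixes and placed constructively at homopolymer
runs located by exact search, or by rejection sampling validated against
the classifier for multi-bp events; the recorded truth label is the
category the placement engine targeted. SV lengths are lognormal per
class. Read counts are binomial at fixed depth with the ploidy-model mean
VAF, clamped to at least two alt reads so every emitted record satisfies
the support rule by construction (at depth 40 the clamping distorts the
mean VAF by well under 0.01). A contaminant block adds one record per
filter rule that violates exactly that rule, enabling record-exact filter
validation. The whole module is deterministic given its seed.

What the simulator does **not** model: sequencing error and artifact
reads, copy-number variation and subclonal structure (each variant has a
single generative VAF), germline variation beyond the contaminant block,
realistic SV breakpoint junctions, and mutation-rate covariation with
chromatin context. Consequently, passing tests show the pipeline's logic
and statistics are correct at realistic burdens and effect sizes; they do
not show robustness to caller artifacts or impure clones. Note also that
the toy genome (12 Mb across two chromosomes — sizes chosen to keep the
full simulate-to-permutation-test cycle around two to three minutes) is
roughly 250× denser in mutations per base than a human genome at equal
burden, so a background level of incidental sub-1 kb mutation pairs is
expected and treatment effects on clustering are read as
treated-vs-control contrasts, not absolute counts.

## Numerical choices and degenerate inputs

* NMF: uniform random initialization in [0.1, 1], epsilon-guarded
  divisions, seeds mandatory for all stochastic steps and derived from a
  single master seed (kept below 2³¹).
* NNLS fits use the Lawson–Hanson algorithm (`pracma::lsqnonneg`).
* Zero-depth VAF, zero vectors in cosine similarity, all-zero catalogs,
  k ≥ min(dim), empty references, single covariate levels, overlapping
  bins and single-treatment interaction models all raise immediate,
  specific errors rather than propagating NaN.
* Empty inputs (no variants, no clusters, no components) return typed,
  zero-row results.

## Known limitations

* The KL-NMF extractor is a faithful but deliberately compact
  implementation: no GPU path, no hierarchical or strand-aware variants,
  and greedy (not Hungarian) replicate matching, which is adequate for
  the small ranks used here.
* ID83 classification requires left-normalizable, anchored VCF indels;
  complex substitutions are rejected, not coerced.
* The regional module consumes precomputed bins; building
  replication-timing or expression tracks is out of scope.
* With very few clones per cohort and near-identical exposure mixtures,
  signature extraction is intrinsically ill-posed (the catalog approaches
  low rank); the rank-selection elbow then correctly prefers the smaller
  rank rather than inventing components.
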