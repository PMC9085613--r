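---
title: "Methods and design of uvshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of uvshift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

uvshift analyses gene-expression evolution across independent
transitions from dioicy (separate haploid sexes) to monoicy (co-sexual
haploid individuals), as found in brown algae and other UV sexual
systems.  This vignette documents the models, the tunable parameters
and their defaults, the synthetic-data generator that underpins the
test suite, the numerical choices, and the known limitations.

## Sex-biased gene calling

A gene counts as *expressed* for a (species, sex) group when at least
one library exceeds the pooled 5th percentile of the TPM distribution
over all genes and libraries of the group (type-7 linear-interpolation
quantile, strict inequality).  The strict inequality means a fully
degenerate all-equal matrix yields an empty expressed set; this is a
deliberate edge-case convention, not a practical concern.

Differential expression between sexes is tested on log2(TPM + 1)
restricted to the union of the two sexes' expressed sets.  Because the
package consumes TPM rather than raw counts, a count-dispersion model
is not applicable; the default engine is the **limma-trend moderated
t** (`lmFit` + `eBayes(trend = TRUE)`), which pools variance
information across genes.  This matters at the study's replicate
depths: with two replicates per sex, an unmoderated Welch test has ~2
degrees of freedom and its smallest attainable p-values (~0.02–0.1)
can never clear a 5% Benjamini–Hochberg threshold, so a plain t-test
silently loses essentially all calls in 2-replicate species.  The
engine is pluggable (`engine = "welch"` gives the unmoderated test,
which the unit tests check against `stats::t.test`).

Classes: MB (male-biased) requires BH-adjusted p < 0.05 **and** a raw
mean-TPM ratio ≥ 2 (means floored at 0.1 TPM to avoid division by
zero); FB symmetrically.  Genes expressed in exactly one sex with
adjusted p < 0.05 are sex-specific.  Genes on a sex-linked exclusion
list are excluded before testing, mirroring removal of
PCR-validated sex-linked genes.  The reported `log2fc` is the log2 of
the floored raw-mean ratio, so every FB/MB call satisfies
|log2fc| ≥ 1 by construction.

Summary fractions divide FB/MB counts by the *mean* of the two sexes'
expressed-gene counts, with fold-change strata at 2–15× and >15×.

## Ortholog sets

From an orthogroup table, pairwise single-copy orthologs (PSOs) are
rows with exactly one gene in each of the two species.  Multi-species
sets (DSOs over the dioicous species, ASOs over all species) also
accept rows missing at most one species (1:1:1:0) and rows where
exactly one species carries exactly two genes mutually aligned over
*more than* 60% of their length — read strictly, with the longer
duplicate kept and ties (or absent length data) resolved
lexicographically for determinism.  A duplicate row with a
simultaneously missing species is excluded; the set sizes partition
exactly into strict + one-missing + qualifying-duplicate rows, which
the tests assert.

## The ΔX statistic

For one ortholog and one dioicous sex,

d = (mean X_dio − mean X_mono) / mean X_dio,
r = (max X_dio − min X_dio) / mean X_dio,  ΔX = d / r,

with X in TPM.  Only the dioicous replicates enter r — the monoicous
replicate spread is ignored by the statistic's definition, which
surprises users and is therefore stated prominently.  ΔX is undefined
when the dioicous replicates are all equal (r = 0) or the dioicous
mean is 0; such records are flagged and never classified as shifted.
A shift requires |ΔX| > 1 and a between-species mean-TPM fold change
≥ 1.5 (the boundary is inclusive, reading "a minimum of 1.5").  d > 0
reads as "down in the monoicous species".  ΔX is invariant to scaling
all TPMs by a positive constant, a property the tests exercise.

Class-wise enrichment (FB or MB versus unbiased) uses the two-sided
Fisher exact test, defined as the sum of tables at fixed margins with
point probability not exceeding the observed — the convention of
`stats::fisher.test`, which the suite verifies against a
hypergeometric enumeration for every table with n ≤ 12.

## Ancestral states, intersections, contrasts, PGLS

Sex-bias classes (FB/MB/unbiased) are reconstructed on the dioicous
species tree under a single-rate (equal-rates) Mk model.  ER was
chosen over all-rates-distinct because a 4-tip tree cannot identify
six rates.  The pruning likelihood uses the closed-form ER transition
probability; the rate is optimized by Brent search on log q in
[log 1e-8, log 1e3] to tolerance 1e-8, deterministically.  Marginal
state probabilities at every node come from a standard two-pass
(below/above) algorithm with a uniform root prior; MAP states define
per-branch events (unbiased→MB is an MB gain, FB↔MB is one loss plus
one gain).  Missing species in 1:1:1:0 rows are treated as missing
data (partial likelihood 1), which is the reason the reconstruction is
implemented in-package rather than through `ape::ace`; `ace` remains
the cross-check oracle in the tests (note it reports the likelihood
without the uniform 1/k root prior, an offset of log 3).

A gene is *ancestrally sex-biased* when the root MAP state is FB or MB
**and** its marginal probability exceeds 1/2.  The probability
requirement is a package decision: per-gene ML rates on four tips
diverge for saturated patterns, leaving near-uniform root marginals
whose argmax is a tie-breaking artefact; without the threshold the
ancestral fraction is inflated roughly ten-fold.

The multi-set intersection test computes, exactly, the probability
that independent uniform subsets of the observed sizes intersect in at
least the observed number of elements.  The running intersection size
forms a hypergeometric chain (each new set intersects the current
intersection hypergeometrically), so an exact dynamic program is
available for *any* number of sets — not only for three or fewer — and
is the default; a seeded Monte-Carlo mode exists as a cross-check.

PICs use `ape::pic` (Felsenstein's standardized contrasts); genes are
summarized by their mean |contrast| and classes compared with a
two-sided Mann–Whitney test.  PGLS regresses a phenotypic-dimorphism
proxy (absolute female−male mean cell-length difference, µm) on
sex-biased gene fractions under a Brownian covariance from the tree.
It is implemented as explicit whitened OLS (inverse Cholesky of
`ape::vcv`), because optimizer-based GLS fails on noise-free inputs
(an exact linear relation is a legitimate test case); `nlme::gls` with
`ape::corBrownian` is the independent oracle in the tests.  The
adjusted r² compares whitened residuals with the whitened
intercept-only model.

## Similarity and convergence

Similarity indexes are Pearson correlations of log2(TPM + 1) mean
profiles over a gene subset (sex-biased or unbiased PSOs).  Comparing
r(mono, female) with r(mono, male) **on the same gene set** is a
dependent-overlapping correlation comparison (the monoicous profile is
shared): Dunn & Clark's z with the Silver–Hittner–May modification
(the covariance term uses the backtransformed mean of the two Fisher
transforms).  Comparisons across different gene sets use Fisher's z
for independent correlations.  The dependent statistic numerically
approaches the independent one as the between-profile correlation
tends to zero, which is regression-tested.

Convergence calling fits, per ASO, the fixed-effects linear model
log2(TPM+1) ~ sexual_system + pair over all samples (vectorized OLS
across orthologs), BH-adjusts the two-sided system-effect p, and
additionally requires the per-pair (monoicous − dioicous) shifts to
share one strict sign across *all* pairs.  The dioicous side of each
shift is the mean of per-sex replicate means, so male and female
replicates weigh equally.  Orthologs missing any pair are skipped with
a warning.  This replaces a count-model shrinkage contrast with an
operational, testable definition of "conserved pattern across all
monoicous species"; the engine sits behind one function boundary and
could be swapped.

The permutation test permutes sexual-system labels among samples
independently within each pair — the null of no systematic
monoicous–dioicous difference with samples exchangeable within pairs —
and recomputes the convergent count with the identical machinery;
p = (1 + #{count* ≥ observed}) / (n_perm + 1).  Note that under a
*global* null the observed count is almost surely 0, in which case the
permutation p equals 1 by construction: the null p distribution is
sub-uniform (a valid, conservative p with an atom at 1), and the
calibration tests assert exactly that one-sided property rather than
exact uniformity, which is unattainable for a discrete count
statistic.  The permutation default follows the method description
(100,000); the test suite and the acceptance script use 10,000 or
fewer, which changes only the resolution of the p-value, and the
problem sizes were chosen so every suite completes on a single CPU in
minutes.

PCA ordination is centred, per-gene unit-scaled PCA of log2(TPM+1)
over complete orthologs, with constant genes dropped and reported.

## Sequence divergence

dN/dS per ortholog pair uses Nei–Gojobori (1986) counting: per-codon
synonymous site fractions from the nine single-nucleotide neighbours
(mutations to stops are nonsynonymous), differences averaged with
equal weight over minimal mutational pathways (pathways through stop
codons excluded; if every pathway is blocked, all are used with stop
steps counted nonsynonymous), and Jukes–Cantor correction
d = −(3/4)ln(1 − 4p/3).  Codon columns containing gaps, ambiguity
characters (any non-ACGT, per the stated convention) or stops in
either sequence are dropped.  Records are valid when both corrections
are defined and 0 < dS < 2, strictly.  A codon-ML estimator (F3x4)
would be the heavier alternative; counting is self-contained,
desk-scale and sufficient for the class-wise contrasts the pipeline
tests, and an external ML engine can be substituted at the same
interface.  Class comparisons use permutation t-tests (Welch
statistic, label permutation), with exact enumeration whenever
`choose(n, nA)` does not exceed the permutation budget.

## The synthetic-data generator

The generator emits the full input bundle with planted truth.  Its
defaults are the emulated study conditions and are not tuning knobs:

| parameter | default | reason |
|---|---|---|
| pairs / replicates | 4 pairs; 3,2,3,3 replicates | four clades, one pair with duplicate sampling |
| baseline log2 TPM | N(4, 2²) per orthogroup | realistic spread of expression levels |
| per-(orthogroup, pair) offset | N(0, 0.5²) | between-clade expression divergence (the "pair" effect) |
| replicate noise | multiplicative, sd 0.2 log2 | replicate r² ≈ 0.98 on log scale, the concordant end of the reported 0.89–0.99 band, typical of deep RNA-seq; also the level at which a moderated test at 2–3 replicates retains power for 2-fold effects |
| sex-biased fractions | 13/20/26/33 % per dioicous species | spans the reported 12.71–33.17% range |
| effect sizes | 1.25 + Exp(0.8) log2 units | heavy-tailed, all ≥ the 2-fold minimum with margin for the threshold noise |
| sex-specific / sex-linked | 2% / 1% of genes | emitted single-sex plus exclusion-listed |
| convergent fraction | 0.61, shift 1.5 + Exp(0.5) log2, shared sign | the convergence level under study |
| orthogroup patterns | 20% one-missing, 8% duplicated (coverage U(0.3,1)), 4% excluded patterns | exercises every assembly rule |
| ω per class | FB 0.2, unbiased 0.3, MB 0.8 | MB > unbiased ≥ FB ordering |
| codon simulation | 150 codons, Jukes–Cantor proposals, nonsynonymous acceptance ω, until the synonymous-substitution count reaches the dS target (U(0.1, 1.2)) | rank-recoverable ω classes at desk scale; κ = 1, no indels |

Structural choices worth knowing: the monoicous mean profile is the
partner's female profile times the planted convergent shift — the
"monoicy from ancestral females" structure — which means male-biased
genes automatically carry male-versus-monoicous ΔX shifts
(de-masculinization) without separate planting.  Convergent shifts are
planted only on orthogroups without single-sex genes, because a
multiplicative shift of a female-silent gene cannot appear in the
emitted matrices; this keeps the planted fraction realizable.  Noise
is multiplicative lognormal rather than count-level negative binomial
because the pipeline consumes TPM; consequently the generator does not
emulate count overdispersion, library-size artefacts, mapping noise,
or correlated gene modules, and passing recovery tests demonstrates
the statistical machinery, not robustness to those real-data features.
Everything is derived from one integer seed; the same seed yields a
byte-identical bundle.

## Numerical conventions

- Quantiles: R type 7 (linear interpolation) everywhere.
- Welch test degeneracies: identical groups give p = 1; two exactly
  constant but different groups give p = 0.
- Mk rate search bounded in [1e-8, 1e3] on a log scale, tolerance 1e-8;
  reconstructions are memoized per tip-state pattern.
- Random stages derive their seeds from the global seed by a stable
  per-stage fingerprint (`stage_seed`), so single stages re-run in
  isolation reproduce full-run results; all seeds stay below 2^31.
- Fisher two-sided convention: sum of tables with point probability ≤
  observed (with the customary 1+1e-7 tolerance for ties).

## Limitations

- TPM-level inference: no count-model dispersion or fold-change
  shrinkage; the moderated-t engine is the TPM-appropriate substitute.
- Pairwise counting dN/dS only; branch and branch-site codon-ML models
  on the full tree are out of scope.
- The Mk model is ER with three states; ordered or asymmetric-rate
  models are not fitted.
- The dependent-correlation test assumes the compared sets share the
  sample dimension; comparisons across different gene sets fall back
  to the independent test.
- Orthology inference, alignment curation and expression
  quantification are upstream: the package consumes their outputs.
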