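---
title: "Methods: quantifying transcriptome-translatome uncoupling"
author: "uncoupleR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying transcriptome-translatome uncoupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uncoupleR)
```

## The question the package addresses

Profiling total cellular mRNA (the transcriptome) and polysome-associated
mRNA (the translatome) in the same cells, before and after a stimulus,
yields two paired differential-expression readouts per gene. If translation
passively followed transcript abundance, the two readouts would agree. This
package quantifies how much they do not: it classifies genes into coupled
and uncoupled regulation classes, compares the biological themes each level
regulates, and tests formally whether the two sets of changes behave as
statistically independent.

All computations run equally on real paired expression matrices (TSV in,
TSV/JSON out) and on synthetic data with known planted structure, which is
how the package verifies itself.

## Differential expression: rank product with permutation pfp

For one RNA level, control and treated replicate arrays are compared in
`K = min(n_control, n_treated)` disjoint pairings (control replicate *k*
against treated replicate *k*). In each pairing genes are ranked by log2
fold change in one direction (rank 1 = strongest); the rank product of a
gene is the geometric mean of its *K* ranks, computed separately for up-
and downregulation. Because only ranks enter, the statistic is unaffected
by monotone rescaling of intensities.

Significance uses the percentage of false prediction (pfp). The null is
generated by shuffling gene labels independently within each pairing's
ranking and recomputing rank products; for a gene at position *r* of the
observed ordering,

pfp(r) = E[# permuted rank products <= observed] / r,

an expected-false-predictions-per-prediction quantity (an FDR analogue, not
a p-value; it may exceed 1). A cumulative maximum down the ranking enforces
monotonicity. The default calling threshold is pfp < 0.2, and the default
1000 permutation rounds keep its Monte-Carlo error well below that
threshold at the problem sizes used here.

**Why disjoint pairings.** An all-pairs design (every control against every
treated replicate) makes a null gene's fold-change ranks correlated across
pairings, because pairings share arrays. A permutation null that shuffles
each ranking independently then has a much lighter tail than the observed
null statistics, and the pfp becomes strongly anti-conservative — on a
2000-gene simulation with 92 planted effects it admitted hundreds of false
calls. With disjoint pairings the per-pairing noise is independent, the
permutation scheme matches the observed null distribution exactly, and on
null data the caller returns (almost) nothing. This calibration is asserted
in the test suite.

Two caller details worth knowing: ties receive average ranks, so when many
genes share one exact fold change (the noiseless simulation limit) their
tied rank appears in the permutation pool and their pfp has a small floor
of roughly `n_genes * (n_tied / n_genes)^K`; and the two directions are
combined per gene by the minimum pfp, with the direction of the minimum
reported.

The alternative caller is a per-gene pooled-variance two-sample t-test with
Benjamini-Hochberg step-up. The pooled (rather than Welch) form is exact
under equal group variances, which matters at the 2-4 replicates typical of
these designs; zero-variance genes get p = 1 when means agree and a floored
standard error otherwise.

## Coupling classes and uncoupling degree

Given both levels' calls, each gene falls in exactly one class: `coupled`
(significant at both levels, same direction), `antidirectional` (both
levels, opposite directions), `transcriptome_only`, `translatome_only`, or
`unchanged`. The uncoupling degree is the percentage of DEGs (unchanged
genes excluded) in the three uncoupled classes. Direction comes from the
caller's per-gene direction, not the sign of the averaged fold change, in
the rare cases they disagree. A threshold sweep (default grid 0.01-0.5)
re-runs the classification across significance cutoffs to show the summary
is threshold-stable.

Translational enhancement/buffering counts compare the two fold changes per
gene with strict inequalities; exactly tied fold changes are reported
separately rather than being forced into either class. The default scope is
the union of DEGs, with the all-genes variant also reported, since the gene
scope of this statistic is a genuine free choice.

## Term enrichment

Over-representation of a DEG list in a term's annotation set is scored by
the one-sided hypergeometric tail within the measured universe (all genes
surviving the expression filters at that level — the background actually
assayed), with BH control at FDR 5%. The EASE-style variant (overlap minus
one) is available behind a flag and is deliberately more conservative; the
plain Fisher/hypergeometric form is the default. Enrichment p-values are
checked against full enumeration of DEG draws on universes of up to 12
genes.

The overlap of the two levels' enriched-term sets is summarized as common /
transcriptome-specific / translatome-specific counts with integer-rounded
(half away from zero) percentages of their union — the convention that
reproduces printed summary percentages from raw counts. The network
specificity degree generalizes the same idea to any function-to-network
association table: (translatome - transcriptome) / total associated
networks, in [-1, 1], keeping only functions with more than five
associations.

## Graph-based semantic similarity and specificity

Identical-term overlap understates agreement between term lists when lists
contain near-synonymous terms. The package therefore uses an
aggregate-semantic-value similarity that depends only on the ontology
graph, not on annotation corpora: each ancestor *t* of a term *a* carries
an S-value, the maximum over ascending paths of the product of edge
weights, with S(a) = 1; the similarity of *a* and *b* is the sum of both
terms' S-values over common ancestors divided by the sum over all their
ancestors. Default weights are 0.8 per `is_a` edge and 0.6 per `part_of`
edge — the conventional choices for this construction — and are
configurable. The implementation is validated against an exhaustive
path-enumeration oracle on small DAGs.

The semantic translatome specificity of a dataset pair is one minus the
mean, over the *m* translatome-enriched terms, of each term's maximum
similarity to any of the *n* transcriptome-enriched terms; the
transcriptome specificity swaps the roles. Both lie in [0, 1] and vanish
for identical lists. When one list is empty the result is undefined and
carries an explicit reason rather than a number. Terms from different
namespaces score similarity 0 by default (configurable to an error).

For context, each dataset's within-pair specificity can be placed against a
reference distribution: the specificities between its transcriptome list
and the transcriptome lists of the other datasets, which for heterogeneous
experiments represent "unrelated" comparisons. The position (below the
median, below the minimum) is reported descriptively; no p-value is
invented for this comparison. GOslim-style roll-ups compute, per term, the
fraction of datasets in which it is level-specifically over-represented
among those where it is over-represented at all, then take medians within
slim categories; a per-dataset normalized difference
(translatome-only − transcriptome-only counts over their sum, in [-1, 1])
summarizes each dataset's balance.

## Independence tests

Three complementary tests operate on the binary DEG indicator vectors over
the N-gene universe (n1 transcriptome DEGs, n2 translatome DEGs, overlap
k):

1. **Likelihood ratio on counts.** Two binomial draws over the same
   universe; the null shares one proportion (n1+n2)/(2N), the alternative
   keeps two. G = 2(l1 − l0) is referred to chi-square with 1 df. The
   likelihood form is the simplest one consistent with asking whether the
   two DEG *numbers* differ.
2. **Random overlap.** n1 and n2 genes are drawn without replacement from
   the universe, the intersection recorded, and the add-one-corrected
   upper tail of the observed overlap reported:
   p = (#{random ≥ k} + 1)/(B + 1). The sampling population is all
   measured genes (drawing from a DEG-only pool would leave the overlap
   ill-defined); the exact hypergeometric tail is computed alongside as an
   oracle, and the test suite checks agreement within Monte-Carlo error
   over a parameter grid.
3. **Mutual information.** Plug-in MI of the 2x2 joint table in bits
   (0 log 0 = 0), with a bootstrap null that reassigns the n1 and n2
   labels to random genes, and two reference values: the MI of maximally
   disjoint lists (overlap max(0, n1+n2−N)) and the MI of fully
   overlapping lists of size floor((n1+n2)/2), which equals the marginal
   entropy H((n1+n2)/(2N)) up to the floor. The midrange position
   (MI − min)/(max − min) locates the observed dependence inside that
   interval.

**A caveat on the MI "bounds".** MI is U-shaped in the overlap k: it is
(near) zero at the independence point k = n1·n2/N and rises towards both
k = 0 (exclusion) and maximal overlap. The zero-overlap reference is
therefore *not* a lower bound for tables close to independence — observed
MI can fall slightly below it, and midrange positions can be mildly
negative. Under positive association (overlap at or above its independence
expectation, the regime of co-regulated DEG lists) the observed MI does lie
inside the interval, and that is the regime in which the feasibility check
is asserted. The units are bits; typical values at realistic DEG
frequencies are a few hundredths of a bit, so a log-base flag is
unnecessary.

All bootstrap p-values use the add-one correction and hence are never
exactly zero. Seeds are explicit everywhere; the pipeline derives distinct
stage seeds from one master seed by fixed offsets.

## The synthetic generator

`generate_paired_dataset()` emulates a replicated two-group log2-intensity
study at both RNA levels: per-gene baselines uniform on [6, 14] (a typical
microarray dynamic range), i.i.d. Gaussian replicate noise, and planted
signed effects of one magnitude, with the sign drawn per gene. Class counts
follow the configured fractions by largest-remainder apportionment, so
planted counts are deterministic given n_genes. Truth labels record exact
planted effects, not post-hoc significance, enabling parameter-recovery
tests. The default conditions are 2000 genes, 3 replicates, effect 2.0,
noise sd 0.3, and a class mix anchored to an observed growth-factor
response (about 4.6% DEGs; within DEGs roughly 5% coupled, 0.5%
antidirectional, 9% transcriptome-only, 85% translatome-only — about nine
purely-translatome DEGs per purely-transcriptome one).

What the generator does *not* emulate: probe-level spatial artifacts, dye
and scanner effects, intensity-dependent variance, correlated noise between
the two RNA fractions of the same biological replicate, and realistic
annotation structure (the toy ontology is a small random DAG). Passing the
recovery tests therefore demonstrates the pipeline's statistical
correctness under its stated noise model, not robustness to every artifact
of real arrays.

`generate_toy_ontology()` builds a single-rooted DAG (balanced backbone
tree with `is_a`/`part_of` edges plus occasional extra `part_of` edges),
annotations covering every term, and a slim map from each term to its
child-of-root lineage. `annotate_planted_terms()` overlays
differential-expression structure: chosen terms draw a configurable
fraction (default 0.7) of their genes from the planted DEGs of one level,
emulating themes regulated specifically at that level.

## Numerical choices and degenerate inputs

- Quantile normalization: rank-wise means with ties receiving the mean of
  the tied ranks' target values; applied jointly across all arrays of all
  four groups so cross-level fold changes are comparable. Missing values
  are refused by name rather than silently imputed.
- Low-signal filter: a feature is removed when called absent in more than
  `majority_fraction` (default 0.5, a strict majority) of the arrays in
  *every* level/condition group; present-in-one-group rescues a feature.
  Without detection calls the filter is a logged pass-through.
- Probe collapse: arithmetic mean over a gene's probes; a probe mapping to
  two genes is an error, unmapped probes are dropped and counted.
- pfp: rank ties broken "first" for the divisor rank; step-down cumulative
  maximum; counts compared with a 1e-12 slack to absorb floating-point
  ties in log space.
- (n1+n2)/2 for the MI maximum: floored when odd.
- Percentages of enriched-term overlaps: integer rounding, half away from
  zero.
- Empty DEG lists: enrichment returns an empty (valid) table; semantic
  specificity returns an undefined result with a reason; the independence
  stage is skipped with a log entry when both levels have zero DEGs.

## Problem sizes used in the shipped checks

The test suite and acceptance script run entirely on synthetic data at
desk scale, chosen to keep each statistical check's Monte-Carlo error well
inside its assertion margin: the end-to-end recovery run uses 2000 genes,
3 replicates and 1000 pfp permutations; bootstrap-versus-exact overlap
comparisons use 1e5 iterations over 20 parameter configurations; null
calibrations use 1000 likelihood-ratio simulations, 200 MI-bootstrap
simulations (500 resamples each) and 200 null t-test datasets; exhaustive
oracles cover a 5-gene, 2-pairing rank-product instance ((5!)^2
permutations) and ontologies of up to 8 terms.

## Known limitations

- The rank-product caller assumes exchangeable replicates within each
  group; batch structure is not modeled.
- pfp calibration relies on the disjoint-pairing design; an all-pairs
  variant would need an array-level permutation scheme instead.
- Semantic similarity weights are conventions, not fitted quantities;
  comparisons across ontologies with different edge-type mixes are
  qualitative.
- The reference-distribution comparison is descriptive by design; with few
  datasets its min/median/max are noisy.
- Detection-call filtering expects Boolean present/absent calls; no
  intensity-based filtering is provided.
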