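# uncoupleR

Paired analysis of transcriptome (total mRNA) and translatome
(polysome-associated mRNA) expression profiles. Upon a stimulus, changes in
transcript abundance and changes in polysomal engagement need not agree;
`uncoupleR` quantifies that disagreement gene by gene, theme by theme, and
with formal tests of statistical independence. It is aimed at
transcriptomics analysts working with polysome-profiling (or similar
two-fraction) designs: two conditions, replicated arrays or comparable
log2-intensity matrices, measured at both RNA levels.

## What it computes

- **Differential expression per level** — a rank-product caller: with
  `K` disjoint control/treated replicate pairings, each gene's statistic is
  `RP = (∏ₖ rₖ)^(1/K)`, the geometric mean of its per-pairing fold-change
  ranks, assessed by a permutation-based *percentage of false prediction*
  (`pfp(r) = E[#permuted RP ≤ observed] / r`, called at `pfp < 0.2`), plus
  a pooled-variance t-test with Benjamini–Hochberg correction as an
  alternative caller.
- **Coupling classification** — each gene becomes `coupled`,
  `antidirectional`, `transcriptome_only`, `translatome_only` or
  `unchanged`; the uncoupling degree is the percentage of DEGs in the three
  uncoupled classes, with a significance-threshold sweep and translational
  enhancement/buffering counts (strict fold-change comparisons).
- **Term enrichment and semantic specificity** — hypergeometric
  over-representation at FDR 5%; overlap summaries of the two levels'
  enriched terms; a graph-based term similarity (max-path-product
  S-values; `sim(a,b) = Σ_{t∈common}(Sₐ(t)+S_b(t)) / (ΣSₐ+ΣS_b)`) feeding
  the semantic specificities
  `1 − meanᵢ maxⱼ sim(termᵢ, termⱼ)` of each level against the other,
  cross-dataset reference distributions, and GOslim-style specificity
  degrees.
- **Independence tests** — a two-binomial likelihood ratio test on DEG
  counts (χ², 1 df); a random-overlap bootstrap with its exact
  hypergeometric tail as oracle; and plug-in mutual information (bits) of
  the two DEG indicator vectors with zero-overlap / full-overlap reference
  values and a label-reassignment bootstrap.
- **Synthetic data** — a generator of paired expression sets with planted
  coupling classes and toy DAG ontologies, so the entire pipeline is
  testable end to end without external data.

## Worked example

```r
library(uncoupleR)

# a study-scale simulated dataset: 2000 genes, 3 replicates/condition/level,
# log2 effect 2.0, noise sd 0.3, EGF-like planted class mix (~4.6% DEGs)
report <- run_pipeline(pipeline_config(
  synthetic = synthetic_config(n_genes = 2000, seed = 42),
  n_permutations = 1000, n_iter = 10000, seed = 42))
report
```

```
PipelineReport
  DEGs: 94 (uncoupled 94.7%, coupled 5.3%)
IndependenceResult: N=2000, n1=15, n2=85, overlap k=6
  LRT: G=55.344, p=1.01e-13
  overlap: bootstrap p=0.0003 (exact 1.82e-05)
  MI: 0.0068 bits in [0.0005, 0.1687], midrange 0.038, p=0.0001
```

Reading this output: of 94 genes called differentially expressed at either
level, 94.7% changed at only one level (or in opposite directions) — the
planted uncoupled fraction was 94.6%, so the pipeline recovered it almost
exactly; the translatome dominates (n2 = 85 vs n1 = 15 DEGs). The
likelihood ratio test rejects equal DEG counts between levels
(p ≈ 1e-13); the observed 6-gene overlap *is* larger than random
(bootstrap p ≈ 3e-4, consistent with the exact hypergeometric tail) because
coupled genes were planted; and the mutual information between the two
binary DEG labels is 0.0068 bits, only 3.8% of the way from its
zero-overlap to its full-overlap reference value — substantial uncoupling
despite the detectable residual dependence.

The numbered scripts under `analysis/` run the same workflow stepwise
(simulate → preprocess/call DEGs → coupling → enrichment/semantics →
independence), printing what each stage found and writing tidy tables
under `results/`.

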