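# tempodeg

Multi-timepoint differential-expression analysis for brain-injury
transcriptomics, built around the question *when* a gene responds to
injury, not just *whether* it does. The package implements, as a tested
and reusable pipeline: count preprocessing with median-of-ratios
normalization, a negative-binomial Wald test per two-group contrast, a
six-way temporal pattern classifier, cell-type attribution with the τ
specificity index, a dampened/accelerated treatment-effect classifier,
gene-set overrepresentation, and a signed weighted co-expression network
workflow. A negative-binomial simulator with planted ground truth makes
every stage testable end to end.

## The model

Counts for gene *g* in sample *j* are modeled as negative binomial with
mean `s_j · q_gj` and variance `μ + α μ²`, where `s_j` is the sample's
median-of-ratios size factor. For a two-group contrast the package tests
`log2FC = log2(q̄_B / q̄_A)` with a delta-method standard error and a
standard-normal Wald statistic; BH-adjusted FDR is reported alongside the
unadjusted p. A DEG requires `p ≤ 0.05` and `|log2FC| ≥ 1`.

Three contrasts anchor everything downstream — A: 1 day vs sham,
B: 1 week vs sham, C: 1 week vs 1 day. The significance triple (A, B, C)
assigns each gene one of six temporal patterns:

| A | B | C | pattern |
|---|---|---|---------|
| ✓ | · | · | Early |
| ✓ | · | ✓ | Transient |
| ✓ | ✓ | · | Persistent |
| ✓ | ✓ | ✓ | Intensified |
| · | ✓ | ✓ | Delayed |
| · | ✓ | · | Late |

The six patterns partition the sham-significant genes exactly
(`partition_check()` enforces this). With a treated arm
(T: treated vs sham), a gene is **dampened** when A is significant but T
is not, and **accelerated** when B and T are significant with the same
sign while A is not. Cell-type specificity uses
`τ = Σ(1 − x_i/max(x)) / (n − 1)` over a reference expression matrix
(specific at τ ≥ 0.8, enriched at τ ≥ 0.6). The co-expression workflow is
a signed bicor network (soft power β = 12), mean-denominator topological
overlap, average-linkage module detection with eigengene merging at
dissimilarity 0.15, and Wilcoxon/Bonferroni tests on eigengene scores.

## Worked example

```r
library(tempodeg)

sim  <- simulate_counts(simulation_spec())       # 2000 genes, 8/group, seed 20250409
exp  <- filter_genes(sim$experiment)             # < 50 counts in > 20 samples
s    <- size_factors(exp)
de_A <- wald_test(exp, s, c("sham", "injured_1d"))
de_B <- wald_test(exp, s, c("sham", "injured_1wk"))
de_C <- wald_test(exp, s, c("injured_1d", "injured_1wk"))
calls <- classify_temporal(de_A, de_B, de_C)
partition_check(calls)$table
```

```
              up down discordant
  Early        3    3          0
  Transient   36   27          0
  Persistent  64   40          0
  Intensified 34   26          0
  Delayed     54   43          0
  Late         5    4          0
```

Each row counts genes assigned to one temporal pattern by direction; the
table sums to the number of sham-significant DEGs (here 339; the
simulator planted 300 temporal and 100 treatment-trajectory genes, some
of which fall to the count filter or the significance thresholds). Planted Transient, Persistent,
Intensified and Delayed genes are recovered essentially completely;
Early and Late are intrinsically boundary patterns at the planted effect
size (their defining non-significance window collapses at |log2FC| = 2,
see the methods vignette), so much of their mass lands in the adjacent
patterns — visible above as the inflated Persistent/Intensified/Delayed
rows.

The full pipeline — normalization, outlier removal, four contrasts,
patterns, cell types, treatment calls, ORA, modules, manifest — runs as

```r
run_all(run_config(seed = 1), "out/")
```

and is bit-reproducible for a fixed config (checksums in
`out/manifest.json`).

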