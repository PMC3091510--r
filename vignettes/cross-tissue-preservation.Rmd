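---
title: "Cross-tissue module preservation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-tissue module preservation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(preservr)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the places where
the design was genuinely open and a choice had to be made.

## The analysis in one paragraph

Gene co-expression networks summarise which genes rise and fall together
across samples. In a weighted, *unsigned* network the connection strength
between genes i and j is `a_ij = |cor(x_i, x_j)|^β`: the absolute
correlation, soft-thresholded by a power β so that strong relationships
dominate without imposing a hard cutoff. Modules — clusters of densely
interconnected genes — are branches of an average-linkage dendrogram
built on `1 − TOM`, where the topological overlap TOM credits gene pairs
for shared neighbours as well as direct adjacency. Each module is
summarised by its eigengene (first principal component of the
standardized module expression), and each gene's module membership
`MM = cor(x_i, ME)` (kME) measures how central the gene is. The question
the package answers is whether a module defined in a *reference* tissue
is still a module, with the same wiring, in a *test* tissue — quantified
by a permutation Z statistic, `Zsummary`.

## The preservation statistic

Six statistics are computed for a module's gene set. Density statistics
ask whether the genes are still a tight cluster in the test data: the
mean off-diagonal adjacency, the proportion of variance the test-data
eigengene explains, and the mean |kME| against that eigengene.
Connectivity statistics ask whether the wiring pattern is reproduced:
the correlation (across module genes) between reference and test
intramodular connectivity, between reference and test kME vectors, and
between the vectorized upper triangles of the two gene–gene correlation
matrices. Each observed statistic is standardized against `n_perm`
random gene sets of the same size drawn without replacement from the
merged gene universe; `Zdensity` and `Zconnectivity` are the medians of
their three Zs, and `Zsummary` their mean. The conventional reading is:
below 2, no evidence of preservation; above 5, moderate; above 10,
strong.

Three design points deserve emphasis:

* **The permutation universe includes all merged genes, grey included.**
  This makes the null exchangeable — a "module" that is itself a random
  draw from the universe scores `Zsummary ≈ 0`. A consequence worth
  knowing: if a large fraction of the universe carries genuinely
  preserved signal, random draws inherit some of it and the connectivity
  null shifts upward, which *shrinks* connectivity Zs for true modules.
  This is a property of the statistic, not a bug; it is why the package's
  test scenarios keep planted modules a minority of the universe, as in
  real studies where most measured genes sit outside any preserved
  module.
* **Independent permutation streams per module.** Each module's stream is
  seeded deterministically from the master seed and a stable hash of the
  module label, so equal-sized modules never share draws and any run is
  reproducible to the last digit from `(data, seed)`.
* **Sign alignment before comparing kME.** Both eigengenes are oriented
  toward their own module mean profile before the kME–kME correlation,
  so a globally sign-flipped test dataset cannot spuriously destroy
  preservation in an unsigned network.

Calibration is checked, not assumed: `preservation_null_calibration()`
draws hundreds of random gene-set modules from a pure-noise two-tissue
simulation and verifies that each per-statistic Z has mean ≈ 0 and
standard deviation ≈ 1 (the acceptance suite requires |mean| ≤ 0.3 and
sd ∈ [0.7, 1.3] over 200 replicates).

## Tunable parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `beta` | 6 | soft-threshold power on the absolute correlation; the convention for unsigned networks. It is a free parameter here, not auto-selected, because the analyses this package supports fix it. |
| correlation method | `pearson` for networks, `bicor` for cross-dataset scatter summaries | the biweight midcorrelation zero-weights observations beyond nine (unnormalized) MADs from the median, protecting against outlying arrays; with zero MAD it falls back to Pearson with a warning. The denominator constant 9 follows the de-facto standard definition. |
| `cut_height` | 0.99 | absolute static cut on the `1 − TOM` dendrogram. Unrelated genes sit at dissimilarity ≈ 1, so only genuinely interconnected branches assemble below 0.99. This is a deterministic simplification of dynamic branch cutting; it recovers planted blocks essentially perfectly and leaves pure noise grey, but will not split nested sub-modules the way the dynamic hybrid method can. |
| `min_module_size` | 30 | smallest branch kept as a module; smaller branches are grey. |
| `n_perm` | 200 | permutations per module. The Monte-Carlo error of a Z estimate is roughly stable by 200 while keeping desk-scale runtime; the hard minimum is 50. |
| `mm_threshold` | 0.35 | combined-MM cut for preserved hubs, applied with strict inequality and sign consistency in both tissues; at the sample sizes this analysis targets it corresponds to a very small correlation-test p-value. |
| `bonferroni_n` | 50 | multiplier for reported Bonferroni-corrected p-values, the conventional test count of this pipeline's reports. |
| `outlier_z` | −3 | standardized mean inter-array correlation below which an array is dropped, a deterministic surrogate for visual dendrogram pruning. Single pass, no iteration. |

## The synthetic-data generator

`simulate_scenario()` emulates a multi-tissue expression study with a
single-factor model per module: in every tissue where module q is
preserved, member gene i is `x_i = r_i e_q + sqrt(1 − r_i²) ε_i`, with
`e_q` a per-tissue standard-normal eigengene profile and `r_i` the
gene's target kME drawn once, uniformly, from the module's `kme_range`.
Three consequences define what the generator does and does not emulate:

* gene–gene correlations within a module are `r_i r_j` in expectation
  (checkable at n ≥ 200 samples), exactly the structure that eigengene
  and kME analyses assume — higher-order (multi-factor) module structure
  is absent by design;
* `r_i` is shared across tissues where the module is preserved, so the
  cross-tissue kME and connectivity correlations the preservation
  statistics measure are real; per-tissue eigengene profiles are
  independent draws, because different tissues come from different
  individuals;
* a module absent from a tissue contributes pure noise for the same
  symbols, background genes are pure noise everywhere, and
  `anti_correlated` modules use the negative of their partner's
  eigengene, exercising the sign-flipping paths.

Heritability estimates are drawn, not estimated from simulated
relatives: a truncated normal with the higher mean for "preserved hub"
genes — members of a module preserved in at least two tissues whose
`r_i` is at or above the midpoint of the module's kME range — and the
lower mean otherwise. Marker ("CD-like") genes are extra grey genes
generated with high `r` against the first module preserved in every
tissue.

The default scenario (`default_scenario()`) uses two tissues of 100
samples; modules blue (100 genes), yellow (80) and green (60, negative
partner of blue) preserved in both tissues with kME uniform on 0.6–0.9;
a brain-only brown module (60); 1000 background genes, so
preserved-module genes are ≈ 18% of the universe — the minority-share
composition typical of cross-tissue studies; heritability means 0.32
(hubs) versus 0.23 (others) with estimation noise 0.1; five marker
genes; `noise_sd = 1`, which makes each target kME exact in expectation.
Passing tests on this generator show the pipeline recovers planted
factor structure; they do not show robustness to platform effects,
probe-level artefacts, non-Gaussian expression or correlated residuals,
none of which the generator produces.

## Numerical choices and degenerate inputs

* Diagonals: adjacency stores 1 on the diagonal but connectivity and the
  TOM neighbour sums exclude self-terms, matching the "all other genes"
  definition of connectivity.
* Eigengene orientation: the sign is anchored so
  `cor(ME, mean standardized module profile) ≥ 0`; orientation is
  otherwise arbitrary in an SVD.
* `correlation_test_p` returns exactly 0 only for |r| = 1; a p-value
  that underflows at |r| < 1 is returned as the smallest representable
  positive double flagged `underflow`.
* Module labels: branches are ranked by size (ties broken by the
  lexicographically smallest member symbol) and named from the standard
  ordered color list, so labels are reproducible and independent of gene
  input order.
* Degenerate cases error early and by name: constant genes in
  correlation or eigengene computations, probes missing from the
  annotation, batches with one sample (warn, left unchanged), modules
  under 3 genes in preservation, zero permutation sd (the statistic is
  excluded from its median with a warning).
* Probe collapsing uses the MaxMean rule — the representative probe is
  the one with the highest mean intensity, favouring well-measured
  probes — with ties to the smallest probe ID.

## Open design points, decided

* **Combined MM is grouped, not global.** Averaging MM across modules is
  only meaningful when their eigengenes have coalesced (correlate near
  ±1). The pipeline therefore groups preserved modules by absolute
  reference-tissue eigengene correlation (single linkage, |r| ≥ 0.6),
  combines within groups with automatic anchor-based sign flips, selects
  hubs per group at ±`mm_threshold` in both tissues, and unions the
  selections. Combining modules driven by independent latent factors
  would dilute every member's combined MM toward zero.
* **Static versus dynamic tree cut.** The static absolute-height cut was
  chosen for determinism and testability; the cut height and minimum
  size are exposed, and reference module assignments are replaceable
  inputs (any `gene, module` table can be supplied), so fidelity to any
  particular historical cut is not required.
* **Permutation count and statistic set.** The six statistics and the
  median/mean aggregation mirror the established composite Zsummary
  construction; the result object records which statistics fed each
  median, and `n_perm = 200` is the default the acceptance experiments
  use.

## Problem sizes

The test and acceptance experiments run at deliberately desk-scale sizes
chosen to make their claims sharp rather than expensive: null
calibration uses 200 random size-50 modules in two 1000-gene, 100-sample
noise tissues at 200 permutations; regime recovery uses a planted
100-gene module in a 1000-gene universe; structure recovery uses two
100-gene blocks plus 100 noise genes; the downstream heritability
contrast runs on the default scenario. The permutation engine
precomputes each dataset's standardized matrix and full correlation
matrix once, so every permutation is submatrix arithmetic and the whole
suite completes in minutes on one core.

## Known limitations

Signed networks, dynamic hybrid branch cutting with PAM, module merging
by eigengene similarity, consensus modules across datasets,
empirical-Bayes batch correction and cluster-quality statistics
(median rank and friends) are out of scope. The generator's single-factor
modules cannot express correlated-but-distinct module pairs within one
tissue except through exact anti-correlation; and, as noted above,
connectivity Zs are conservative when preserved signal saturates the
permutation universe.
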