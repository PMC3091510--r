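# preservr

Cross-tissue co-expression module preservation analysis in R.

When a gene co-expression module is found in one tissue (say, cortex), is
the same group of genes still co-expressed — with the same wiring — in
another tissue (say, blood)? That question matters whenever an accessible
tissue is used as a surrogate for an inaccessible one, e.g. when searching
for blood biomarkers of brain disease. `preservr` implements the weighted
gene co-expression network (WGCNA-style) machinery to answer it:
permutation-based module preservation statistics, module eigengene and
module membership (kME) analyses, preserved-hub-gene selection, and the
downstream heritability and marker-gene comparisons, together with a
synthetic multi-tissue data generator for validating the whole pipeline
against planted ground truth.

## The statistics at the core

* **Unsigned weighted network.** From gene expression profiles `x_i`, the
  adjacency is `a_ij = |cor(x_i, x_j)|^β` with soft threshold `β = 6` by
  default. Whole-network connectivity is `k_i = Σ_{j≠i} a_ij`; the
  topological overlap `TOM_ij = (Σ_{u≠i,j} a_iu a_uj + a_ij) /
  (min(k_i,k_j) + 1 − a_ij)` measures shared neighbourhoods, and
  `1 − TOM` is the clustering dissimilarity. Modules are branches of the
  average-linkage dendrogram below a static cut height (0.99 on the
  `1 − TOM` scale); unassigned genes are grey.
* **Module eigengene and kME.** The module eigengene `ME` is the first
  principal component of the module's standardized expression;
  `MM_qi = cor(x_i, ME_q)` (module membership, a.k.a. kME) measures how
  central gene i is to module q, with correlation-test p-values and
  Bonferroni correction.
* **Preservation Zsummary.** For a reference module evaluated in test
  data, three density statistics (mean adjacency, variance explained by
  the test-data eigengene, mean |kME|) and three connectivity statistics
  (cross-tissue correlations of intramodular connectivity, of kME, and of
  the gene–gene correlation matrices) are each standardized against a
  permutation null of random same-size gene sets:
  `Z = (obs − mean_perm)/sd_perm`. `Zsummary` is the mean of the median
  density Z and the median connectivity Z. Under no preservation it is
  approximately standard normal; `Zsummary < 2` means no evidence,
  `> 5` moderate and `> 10` strong preservation.
* **Preserved hubs and downstream.** Module membership is combined across
  coalescing modules (sign-aligned weighted average), genes with combined
  MM beyond ±0.35 in *both* tissues are preserved intramodular hubs, and
  hub sets are compared by exact hypergeometric overlap tests, one-way
  ANOVA / rank tests on heritability, and marker-gene/eigengene
  correlations. All robust correlations use the biweight midcorrelation.

## Worked example

```r
library(preservr)

study <- simulate_scenario(default_scenario(seed = 1))
pres <- module_preservation(
  ref = study$expression$brain, test = study$expression$blood,
  assignment = study$truth[, c("gene", "module")],
  n_perm = 200, seed = 2
)
pres
#> Module preservation (200 permutations, seed 2, universe 1305 genes)
#>
#> # A tibble: 4 × 6
#>   module  size Zdensity Zconnectivity Zsummary verdict
#>   <chr>  <int>    <dbl>         <dbl>    <dbl> <chr>
#> 1 blue     100    33.6          0.954    17.3  strong
#> 2 brown     60    -1.53        -2.62     -2.08 none
#> 3 yellow    80    27.7          0.809    14.2  strong
#> 4 green     60    23.9          0.910    12.4  strong
```

The default scenario plants four modules in a 1305-gene universe: blue,
yellow and green are preserved in both simulated tissues (green as the
negative partner of blue), brown exists only in "brain". The engine
recovers exactly that: the three preserved modules score deep in the
strong regime (`Zsummary` 12–17, far above the threshold of 10) while the
brain-only module shows no evidence of preservation (−2.1, below 2).
`autoplot(pres)` draws the horizontal Zsummary barplot with the 5 and 10
reference lines; `tidy(pres)` returns the per-statistic observed values,
permutation moments and Z scores.

The full staged analysis — outlier removal, symbol merging, network and
module construction, preservation per test tissue, combined-MM hub
selection, heritability ANOVA and marker correlations, with a
machine-readable `report.json` — runs from one configuration:

```r
cfg <- run_config(reference = "brain", out_dir = "run1",
                  scenario_seed = 1, seed = 2)
run_pipeline(cfg)
```

A thin command-line wrapper with `simulate | preprocess | network |
modules | preserve | downstream | report | run` subcommands is installed
at `system.file("scripts", "preservr.R", package = "preservr")`.

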