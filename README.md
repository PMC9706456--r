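# healthnet

Cross-species gene co-expression meta-analysis of health(span).

## What problem this solves

Many small transcriptomics experiments — worm, fly, mouse, rat, human —
annotate their samples with factors that imply a health status: age,
life-extending treatments, damaging knock-outs. No single experiment has the
power to nominate health genes reliably, and expression scales are not
comparable across studies. healthnet implements a meta-analysis that never
compares expression across experiments: each experiment is condensed,
*independently*, into ranked gene lists from health-associated co-expression
modules, and only the **identity** of genes (via human orthologs) is
intersected across species. Genes recurring in at least two species form the
consensus; permutation tests say how surprising that recurrence is.

The package is aimed at computational biologists running such meta-studies
on collections of GEO/ArrayExpress-style experiments, and it ships a
synthetic-data generator with planted ground truth so every stage of the
pipeline is testable.

## The method

Per experiment (WGCNA-style, unsigned):

1. **Health phenotype score** per sample from a declarative scorecard:
   young untreated wildtype = 1, old = 0, each health-improving /
   health-reducing treatment ±0.2 by default (knock-outs and variants count
   as treatments). Scores are only ever used within one experiment.
2. **Network**: adjacency `a_ij = |cor_ij|^β`, with β the smallest power in
   1–20 whose connectivity distribution is scale-free
   (log–log fit R² ≥ 0.80, negative slope); topological overlap
   `TOM_ij = (Σ_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 − a_ij)`;
   modules from average-linkage clustering of 1 − TOM with minimum module
   size 30; interactions filtered at a minimum score of 0.2.
3. **Selection**: modules whose eigengene (first PC of the standardized
   module matrix) correlates with the health score at p < 0.05 (Student-t
   transform) are retained; each yields the top-30 **hub genes** (soft
   connectivity `k_i = Σ_j a_ij`) and the top-30 **membership genes**
   (|kME| = |cor(gene, eigengene)|), each gene carrying a direction
   sign(kME)·sign(module–trait r).
4. **Interactions**: hub-gene pairs with adjacency above the experiment-wide
   95% quantile are exported; self-interactions from probeset collapse are
   dropped.

Across experiments: ortholog mapping to human symbols, consensus over ≥ 2
species with unanimous/mixed direction aggregation, a hub-and-connector
consensus graph with maximum-weight spanning-tree simplification, and two
permutation nulls (consensus-count redraws with the 14-entry quantile
report; degree rank-sum against an external interaction-degree table).

## Worked example

```r
library(healthnet)

# a synthetic 2-species collection with one planted conserved health module
col  <- simulate_collection(simulation_config(seed = 1))
meta <- run_meta(col, n_perm = 2000, seed = 1)
meta
#> <meta_study> 4 experiments analyzed, 0 excluded
#>   hub consensus: 33 genes (empirical p = 0)
#>   membership consensus: 33 genes (empirical p = 0)

head(meta$consensus_hub, 3)
#> # A tibble: 3 × 7
#>   human_symbol species   n_species n_experiments direction directions provenance
#>   <chr>        <chr>         <int>         <int> <chr>     <chr>      <chr>
#> 1 M1G001       human,rat         2             4 positive  human:pos… human_e01…
#> 2 M1G002       human,rat         2             4 positive  human:pos… human_e01…
#> 3 M1G003       human,rat         2             4 positive  human:pos… human_e01…

print(meta$null_hub)
#> <permutation_null> consensus gene count
#>   observed: 33  permutations: 2000  empirical p: 0
#>   0%  1%  5%  10% 25% 50% 75% 90% 95% 97.5%  99%  99.5%  99.9%  100%
#>   0   1   1   2   3   4   5   6   7   8      8    9      10     10
```

All 33 consensus symbols are genes of the planted conserved module
(`M1G...`): the pipeline recovers exactly the cross-species signal that was
simulated, and a random redraw of equally sized gene lists reaches 33
consensus genes in none of 2000 permutations (null median 4).

Individual stages are exported too: `score_samples()`, `build_network()`
(with `tidy()`/`glance()`/`autoplot()`), `select_modules()`,
`cross_species_consensus()`, `build_consensus_graph()`,
`spanning_tree_simplify()`, `consensus_count_null()`,
`degree_rank_sum_test()`. See the methods vignette
(`vignettes/healthnet-methods.Rmd`) for the model, parameter and design
discussion.

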