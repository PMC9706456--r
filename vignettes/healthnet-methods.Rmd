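---
title: "Cross-species co-expression meta-analysis of health-associated modules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species co-expression meta-analysis of health-associated modules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(healthnet)
library(dplyr)
```

## The analysis in one paragraph

healthnet implements a meta-analysis strategy for finding genes associated
with health(span) across species. Each expression experiment — a small
genes × samples matrix from microarray or RNA-seq, with sample-level factor
annotation — is analyzed independently with weighted gene co-expression
network analysis (WGCNA): genes are connected by powered absolute Pearson
correlations, grouped into modules via topological overlap, and each
module's eigengene is correlated with a per-sample *health phenotype score*
derived from the experiment's metadata. Modules passing the association
filter (p < 0.05) contribute two ranked gene lists: the 30 most connected
genes ("hub" genes, by soft connectivity) and the 30 genes correlating most
strongly with the module eigengene (by |kME|). After mapping every gene to
its human ortholog, genes appearing in lists from at least two species form
the cross-species consensus; permutation tests quantify how surprising the
consensus count is.

## The health phenotype score

The score is a within-experiment, unitless encoding of how healthy the
sampled individual is presumed to be. The convention: a young untreated
wildtype scores 1, an old individual scores 0, and each treatment reported
to improve or reduce health adds or subtracts 0.2 by default (per-rule
magnitudes can be adjusted to reflect effect strength). Knock-downs,
knock-outs, gene transfers and natural genetic variants are treated exactly
like treatments — a rule on the factor column that records them. Scores are
never compared between experiments, which is what licenses this otherwise
arbitrary scale: only the *within-experiment* correlation between a module
eigengene and the score matters.

Scorecards are declarative YAML/JSON config files rather than code so the
judgment calls stay auditable, with a custom-formula escape hatch
(`scorecard(formula = ...)`) for experiments whose score needs bespoke
arithmetic (e.g. inverting a damage scale). Deciding *whether* a treatment
improves health is the user's literature judgment, not the package's.

```{r}
score_samples(
  data.frame(sample_id = c("a", "b", "c"),
             age = c("young", "old", "young"),
             treatment = c("none", "none", "health-improving")),
  scorecard()
)
```

## Preprocessing

* **TPM** (`tpm_from_counts()`): counts are length-normalized and scaled so
  each sample sums to 10^6 — the entry point for count data quantified
  elsewhere; read filtering and alignment are out of scope.
* **Log transform** (`log_transform()`): log2(x + 1) unless the matrix
  maximum is ≤ 50, in which case the data are assumed to already be on log
  scale and returned untouched. The threshold is a heuristic: linear-scale
  intensities and TPMs exceed it by orders of magnitude, log-scale data do
  not. It is exposed as `logged_threshold` for unusual platforms.
* **Quantile normalization** (`quantile_normalize()`): optional; every
  sample's sorted values are replaced by the cross-sample mean of sorted
  values, ties receiving the mean of the reference values they span (the
  commonest published convention). The default pipeline leaves data as
  deposited: Pearson correlation is already invariant to gene-wise linear
  transforms, so shifts and Z-scoring do not change the network.
  Note the tie rule makes repeated application exactly idempotent only on
  tie-free matrices; with ties it is idempotent to within the tie-group
  averaging.
* **Outlier samples** (`remove_outlier_samples()`): average-linkage
  clustering on Euclidean sample distance, cut at a configurable height,
  keeping the largest cluster. The reference protocol sets this cut
  manually per experiment; a configurable automated cut keeps reruns
  reproducible. If ≤ 6 samples survive, the experiment is excluded — the
  study inclusion rule requires more than six samples.
* **Low-expression filter** (`filter_low_expression()`): genes must reach
  `min_value` in at least `min_fraction` of samples; applied to count
  platforms before the log transform.

## Network construction

The adjacency is unsigned, `a_ij = |cor_ij|^β`, keeping both positively and
negatively correlated partners connected — consistent with modules whose
eigengene may correlate with the health score in either direction. The
power β is chosen per experiment as the smallest integer in 1–20 whose
connectivity distribution is scale-free: connectivities are binned
(10 equal-width bins over the k range; empty bins dropped), and
log10 p(k) is regressed on log10 mean(k); β qualifies when R² ≥ 0.80 with a
negative slope. Equal-width binning is used because with equal-count bins
p(k) is constant by construction and the regression would be
uninformative. When no power qualifies the experiment is marked
"no modules found" and skipped — mirroring the manual scale-free check of
the reference protocol with a reproducible surrogate.

Topological overlap is the unsigned formula
TOM_ij = (Σ_{u≠i,j} a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 − a_ij),
diagonal 1, with k the soft connectivity (diagonal excluded). Gene pairs
are exported as interactions when their score passes the minimum
interaction score of 0.2; the score is the TOM by default with a switch to
threshold the adjacency instead, since the reference description does not
pin down which matrix the 0.2 applies to.

## Module detection

Genes are clustered by average linkage on 1 − TOM. Rather than the dynamic
hybrid tree cut of the reference protocol, healthnet uses an adaptive
height scan: every distinct merge height of the dendrogram defines a
candidate cut; the cut producing the most clusters of at least
`min_module_size` (default 30) genes wins, ties resolving to the finest
such cut, and undersized clusters are pooled into the unassigned label 0.
This keeps the two properties the downstream analysis relies on — a hard
minimum module size and an explicit unassigned label — while remaining a
few lines of auditable code; numerically tied merge heights are collapsed
(relative tolerance 1e-8) so a cut can never fall inside a block of
simultaneous merges. On planted-partition fixtures the scan recovers the
planted modules exactly (adjusted Rand index ≥ 0.9 in the test suite).

Module eigengenes are first principal components of the gene-standardized
module submatrix, unit-norm across samples, oriented to correlate
positively with the module's mean standardized expression (sign fixed by
the first nonzero coordinate in the fully ambiguous case). Soft
connectivity k_i = Σ_{j≠i} a_ij ranks hub genes; kME (correlation of each
gene with the eigengene) ranks module membership. Ranking by |kME| rather
than signed kME follows "correlating the strongest"; the signed value is
retained for direction calls. Ties in either ranking break
lexicographically by gene ID and are logged.

## Module selection and direction

A module is retained when its eigengene's Pearson correlation with the
phenotype score has two-sided p < 0.05 by the Student-t transform
(df = n − 2). No multiple-testing correction is applied across modules,
matching the raw-p filter of the reference analysis; `adjust = TRUE`
switches to Benjamini-Hochberg. A gene's direction of correlation with the
health score is sign(kME) × sign(module–trait r): a positively loading gene
in a negatively health-correlated module is reported *negative* (the
inverted direction), and experiments disagreeing on a gene's direction
aggregate to *mixed*.

## Cross-species consensus, graph, and permutation tests

Ranked lists are mapped to human symbols through a user-supplied ortholog
table (many-to-one and one-to-many allowed; each human symbol counts once
per experiment; unmapped genes are reported, not fatal). A symbol enters
the consensus report when it appears in lists from ≥ 2 distinct species —
species count, not experiment count, gates inclusion. Interactions among
the 30 hub genes with adjacency strictly above the experiment-wide 95%
linear-interpolation quantile of all off-diagonal adjacency values are
exported; self-interactions created by probeset collapse are removed. The
quantile is computed over all gene pairs (a switch restricts it to module
pairs, since the reference wording is ambiguous on this point).

The consensus graph keeps hub–hub edges and non-hub "connectors" adjacent
to at least two distinct hubs (evaluated on the merged cross-experiment
graph), merging parallel edges at the maximum weight with provenance
union. Two-hop neighborhoods support per-species views, and
`spanning_tree_simplify()` reduces a view to its maximum-weight spanning
forest — the reference describes a minimum-spanning-tree routine that
"retains the stronger of two alternative paths", which fixes the objective
as maximum weight (equivalently, minimum on 1 − weight). Weight ties break
lexicographically by edge name for determinism.

Two permutation nulls are provided. The consensus-count null redraws every
experiment's lists as uniform same-size gene sets from the species
universe (without replacement within a list, independently across lists),
reruns the consensus, and reports the 14-entry quantile table
(0–100%) plus the upper-tail empirical p — the plain fraction of
permutations at or above the observed count, with an optional
(b+1)/(n+1) correction that is off by default to match the reference's
plain-fraction definition. Whether the redraw size should be the top-list
size (30) or the full module size is ambiguous in the reference wording;
the top-list size is the default, with a switch. The degree rank-sum test
ranks all genes of an external interaction degree table ascending (average
ranks on ties), and reports the fraction of equal-size random selections
with a strictly higher rank sum; exact enumeration is available for small
instances.

## The synthetic-data generator

`simulate_collection()` emulates the structure of a multi-species GEO /
ArrayExpress collection: ≥ 2 species, a few experiments each, small sample
counts (default 12, always > 6 per the inclusion rule). Expression follows
a one-factor model per planted module, x_gs = λ_g f_ms + σ_g ε_gs — chosen
over network-based simulation because WGCNA eigengenes *are* factor
estimates, which makes parameter recovery analytic. Hubs are planted as
the largest |λ| (0.92–0.98; non-hubs span 0.55–0.88), because soft
connectivity under |cor|^β provably ranks high-|λ| genes first in this
model. Sample metadata (age, treatment) is generated first, scored with
the default scorecard, and the standardized score is the latent health
variable; health-module factors are constructed to hit their configured
factor–score correlation *exactly* in-sample (residualize-and-mix), so
recovery checks are sharp. Modules with `trait_cor = NA` instead draw a
free factor — their eigengene–score correlation follows the null sampling
distribution, which is what calibration tests need. The counts platform
layers Poisson sampling on a log-normal mean (per-gene base log2-mean
uniform on 3–8) — the simplest mean–variance inflation that exercises the
low-count filter.

Defaults: 2 species × 2 experiments, one conserved health module (40
genes, 5 hubs, target correlation 0.8), one non-conserved null module
(35 genes), 100 noise genes, 12 samples. These sizes keep every planted
module above the minimum module size of 30 while staying representative of
small published experiments. What the generator does *not* emulate:
probe-level artifacts, batch effects, library-size variation, or
read-level data — so passing tests certify the algorithmic pipeline, not
robustness to those real-data phenomena.

All randomness flows from the single config seed; per-experiment streams
are derived by stable string hashing of the experiment ID, so a collection
is reproducible and individual experiments are independent of one another.

```{r}
col <- simulate_collection(simulation_config(seed = 1))
col
```

## End-to-end run

`run_meta()` orchestrates the full meta-study. Experiments failing an
inclusion rule (≤ 6 samples, constant phenotype, no scale-free power)
become exclusion records rather than errors. Problem sizes in the test
suite and acceptance script — 175-gene experiments, 200-seed repetitions,
10^4-permutation nulls — were chosen so the whole validation remains a
few minutes of single-core compute while keeping Monte-Carlo error well
below the tolerances being asserted.

```{r}
meta <- run_meta(col, n_perm = 2000, seed = 1)
meta
head(meta$consensus_hub, 3)
glance(meta)
```

## Known limitations

* Signed / signed-hybrid networks, robust correlations (bicor), and
  block-wise decomposition for very large gene sets are not implemented.
* The adaptive height-scan cut is simpler than the dynamic hybrid tree
  cut; on real data with nested module structure it may merge or miss
  fine sub-modules that deepSplit tuning would separate.
* Ortholog tables, interaction-degree tables and annotation joins are
  consumed as user-supplied files; no live database queries.
* The scorecard engine encodes scoring rules; the per-experiment judgment
  of what improves or reduces health remains manual, by design.
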