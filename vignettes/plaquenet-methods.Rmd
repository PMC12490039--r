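---
title: "Methods: co-expression modules, eigengene networks and regulator consensus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-expression modules, eigengene networks and regulator consensus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plaquenet)
```

`plaquenet` implements a multi-stage network analysis for two-group
transcriptomic cohorts, built around the question that motivates it in
atherosclerosis: which co-expressed gene programs distinguish unstable
(hemorrhagic, rupture-prone) from stable carotid plaque, how do those
programs relate to each other causally at the module level, which
transcription factors drive the key program, and which drugs might reverse
it. Every stage is exercised end-to-end on synthetic cohorts with known
ground truth, so the package's claims about itself are claims the test suite
actually measures.

## The model behind the synthetic cohorts

The generator (`simulate_dataset()`) draws data from an explicit latent
factor model, because that is the statistical structure the downstream
pipeline assumes:

* Module activity. Each of $M$ modules has a latent factor $z_j$ per sample,
  following a linear-Gaussian structural equation model
  $z_j = \sum_{k \in pa(j)} b_{jk} z_k + \varepsilon_j$,
  $\varepsilon_j \sim N(0, \sigma_z^2)$. The factor DAG is what the
  eigengene Bayesian network stage should recover.
* Condition effect. In condition B (the "unstable" arm) selected modules
  receive an additive factor shift $\delta$, which propagates to DAG
  descendants, as a disease effect would.
* Genes. A gene in module $m$ is $x_g = \mu_g + \lambda_g z_m + N(0,
  \sigma_g^2)$ with loadings $\lambda_g \sim U[\lambda_{min},
  \lambda_{max}]$ and baselines $\mu_g \sim U[6, 10]$ on the log scale.
  Background genes are pure noise with unit standard deviation, giving them
  marginal variance comparable to module genes so the variability filter
  has honest work to do.
* Regulators. Inside the first module, a handful of genes act as
  transcription factors: their targets additionally receive
  $\sum_w w \, x_{TF}$ with half-normal (activating) weights. Half-normal
  rather than signed weights keeps the planted condition shift coherently
  signed across the module, matching the upregulated-module setting the
  pipeline is meant to detect; a target with a strong repressive weight
  would otherwise be planted as "shifted" while moving the other way.

Default conditions mirror the study design at desk scale: 1000 genes, five
modules of 250/150/100/70/50 genes (the 250-gene first module plays the
T cell-cluster role and carries the TF effects), 16 + 27 samples, factor
DAG 1→2, 1→3, 2→4, 3→5 with coefficients 0.4, $\sigma_z = 1$,
$\sigma_g = 0.3$, loadings on $[0.6, 1]$, and $\delta = 2$ on module 1.
The coupling coefficient 0.4 gives inter-module eigengene correlations
around 0.35-0.45 — strong enough that module separation is non-trivial,
weak enough that it is achievable at $n = 43$.

What the generator does **not** emulate: probe-level microarray structure,
batch effects, count noise, or cell-type deconvolution. Passing tests
demonstrate that the algorithms recover the structure they assume; they do
not certify performance on real arrays, where unmodelled correlation
structure (batches, cell-type composition) can mimic or mask modules.

## Co-expression network construction

The network follows the weighted co-expression recipe: unsigned adjacency
$a_{ij} = |cor(x_i, x_j)|^\beta$, topological overlap
$TOM_{ij} = (\ell_{ij} + a_{ij}) / (\min(k_i, k_j) + 1 - a_{ij})$ with
$\ell_{ij} = \sum_{u \neq i,j} a_{iu} a_{uj}$, average-linkage clustering of
$1 - TOM$, and eigengene merging at dissimilarity 0.25. Three numerical
choices deserve comment:

* Soft power. The scale-free criterion (`scale_free_fit()`, signed
  $R^2$ of the log-log degree regression over ten equal-width log-scale
  bins) is implemented and validated on planted power-law and
  Erdős–Rényi-style degree data. The pipeline default nevertheless pins
  $\beta = 6$ — the study's setting — rather than scanning, because
  block-factor synthetic data is not scale-free and the scan's fallback
  would pick an arbitrary argmax. Pass `power = NULL` to scan.
* Static tree cut. The dendrogram is cut at a fixed TOM-dissimilarity
  height, default 0.8, with clusters under 30 genes left unassigned. At
  $\beta = 6$, within-module joins sit below roughly 0.75 for gene
  correlations of 0.55 and up, while cross-module joins land at 0.9-0.997;
  0.8 separates the two regimes with margin on both sides. A relative cut
  at 0.99 of the maximum merge height was evaluated and rejected: the top
  joins of the tree are background-noise merges near 1.0, so a relative cut
  lands above the cross-module joins and fuses coupled modules. The
  recovery tests (adjusted Rand index against the planted membership)
  validate the choice across seeds rather than matching any reference
  implementation.
* Eigengenes. The module eigengene is the first principal component of the
  standardized module submatrix, unit-norm, sign-aligned to correlate
  positively with the module's mean profile so downstream network
  orientations are reproducible. A module containing a constant gene is an
  error, not a silent drop.

`module_proximity()` reproduces the relative-adjacency statistic: mean
adjacency from a focal module to each other module, divided by the mean
adjacency from the focal module to all non-focal genes, so the reference
group sits at exactly 1 by construction.

## Enrichment statistics

Overrepresentation (`gsoa()`) is the one-sided hypergeometric upper tail
with BH adjustment across sets; the universe is the preprocessed gene list,
not the whole annotation. The cluster enrichment score is
$CES = -\log_{10}(\min \text{adj } p)$, so $CES = 3$ is exactly "best
adjusted p below 0.001", the gate used for Bayesian-network inputs.

`gsea()` is the classic weighted running sum (hit increments
$|r_i|^p / \sum |r|^p$, uniform miss decrements, default $p = 1$) with a
gene-label permutation null (default 1000 permutations): the null re-draws
hit positions uniformly, $NES$ standardizes by the mean same-sign null
magnitude. At $p = 0$ the statistic reduces to the two-sample ECDF
(Kolmogorov–Smirnov-type) form, which the tests exploit as an independent
oracle; the weighted form is additionally cross-checked against the
`fgsea` implementation. When the maximum and minimum running-sum deviations
tie in magnitude, the positive one is reported.

Semantic similarity uses Lin's measure over the term DAG with information
content from cumulative annotation counts and best-match averaging
(Resnik's measure is available behind a flag); term pairs whose only common
ancestor is the root score 0.

The control-matched signature score bins genes by average expression (24
equal-count bins) and contrasts each signature gene with 100 bin-matched
controls. One property worth knowing: a shift applied uniformly across
*all* samples is absorbed by the matching (controls are matched on the
shifted average), so the score exposes *between-sample* contrasts — which
is precisely its job in the single-cell setting it imitates.

## Eigengene Bayesian networks

Structure learning is score-based hill climbing over add/delete/reverse
moves with a Gaussian BIC (natural-log units,
$\log L - \frac{|pa|+2}{2}\log n$ per node), deterministic lexicographic
move enumeration, and ten restarts by default — the first from the empty
graph, the rest alternating random starts with random perturbations of the
incumbent, which is what lets the search match the exhaustive-enumeration
oracle on all small test datasets. Residual variances are floored at
$10^{-12}$ so deterministic dependencies score finitely.

`bootstrap_network()` resamples samples with replacement, learns one DAG
per replicate, and reports per-edge strength (support in either direction)
and direction (orientation fraction among supporting replicates). The
averaged network keeps arcs with strength at or above the aggregate
threshold (default 0.85), oriented by majority, then drops arcs below the
strength floor (0.7). The alternative reading — thresholding the
direction-aware support $strength \times direction$ — is available as
`threshold_on = "support"`, but it is not the default: undirectable edges
(Markov-equivalent orientations) have direction near 0.5, so that rule
discards even perfectly supported skeleton edges, and on a planted
10-node SEM it retains nothing at 0.85. If thresholding leaves a cycle,
the weakest arc inside the cyclic component is dropped iteratively.

## Regulator consensus

Two independent engines rank candidate regulators for a target module:

* a tree-ensemble engine (`genie3_weights()`, extra-trees regression of
  each target on all regulators via `ranger`, $\sqrt{p}$ candidate splits,
  impurity importances normalized per target), and
* an information-theoretic engine (`mi_matrix()` + `dpi_prune()`):
  equal-frequency discretization with $\lceil n^{1/3} \rceil$ bins,
  Miller–Madow-corrected mutual information, and data-processing-inequality
  pruning. The cube-root bin rule was chosen over the common $\sqrt{n}$
  rule because at typical sample sizes the latter leaves a large positive
  bias even after correction (about 0.26 nats at $n = 1000$ versus about
  $2 \times 10^{-4}$ for cube-root on independent data).

Strict DPI (tolerance 0) removes the weakest edge of every triangle it
loses in. This is a precision filter, not a re-ranking: on a planted
20-regulator benchmark it deletes roughly half of the true edges via
sibling-target triangles while keeping false edges out. Edge-ranking
quality is therefore assessed on each engine's ranking — importances and
mutual information respectively — and the post-DPI survival rate is
reported alongside rather than hidden. Exact MI ties in a triangle are
resolved by removing the lexicographically smallest pair; fully tied
triangles are left intact, so continuous data behaves exactly like strict
DPI.

TFs are ranked by node degree (sum of weights into the module; the
module-restricted reading of the ranking, with the global alternative a
flag away), the top-100 lists of the two engines are intersected, and the
intersection is filtered by motif support at NES ≥ 3. Motif scanning
itself is upstream of this package: its output is consumed as a
(TF, target, NES) table, and the synthetic generator fabricates one with
planted coverage so the consensus contract — recover exactly the
motif-supported true drivers — is testable.

## Drug repurposing

The weighted connectivity score runs the $|score|$-weighted enrichment of
the query's up and down sets in each drug's ranking:
$wtcs = (ES_{up} - ES_{down})/2$ when the signs differ, 0 otherwise;
one-sided queries use the single ES. Scores are normalized per sign (divide
positives by the maximum positive, negatives by the absolute minimum) — the
simplest order-preserving map onto $[-1, 1]$, chosen because only one cell
line is screened so the full cell-line standardization machinery is out of
scope. Candidates are drugs strictly below −0.7 on the normalized scale.

## Problem sizes and reproducibility

All randomness flows from explicit seeds; every generator and every
stochastic stage is byte-identical under a fixed seed, which the suite
asserts. The validation suite runs at deliberately desk-scale sizes chosen
as the package's own test conditions: twenty 1000-gene, 43-sample cohorts
for module/eigengene/differential recovery; a 10-node, 200-sample SEM with
200 bootstrap replicates for the network stage; a 20-regulator, 200-target,
100-sample benchmark for edge ranking; twenty 300-gene cohorts for the
consensus contract; and 100-drug libraries over 600-gene universes for the
screen. The orchestration layer (`pipeline_config()` / `run_pipeline()`)
writes TSV/GMT/GraphML artifacts plus JSON manifests with input hashes, so
identical configurations reproduce identical files.

## Known limitations

* The static tree cut is a deliberate simplification of adaptive tree-cut
  procedures; modules with strongly heterogeneous internal correlation can
  fragment or swallow stray background genes (a few per cohort in the
  recovery tests).
* Observational eigengene networks identify structures only up to Markov
  equivalence; bootstrap direction confidence quantifies, not resolves,
  that ambiguity.
* Strict DPI trades recall for precision, as quantified above.
* The MI estimator's bin rule is tuned for $n$ in the tens-to-thousands
  range; very small cohorts (below ~30 samples) leave too few bins to
  detect moderate dependence.
* Gene-label permutation in GSEA ignores inter-gene correlation, as the
  classic statistic does; its p-values are anti-conservative under strong
  co-expression, which is one reason module calls rest on the
  overrepresentation route as well.
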