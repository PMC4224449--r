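---
title: "Discovering disease-relevant network modules from chemical-exposure expression data"
author: "fibronet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fibronet methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Toxicogenomics compendia such as DrugMatrix profile liver gene expression
after hundreds of chemical exposures, each a *condition*: one chemical at
one dose and duration, with matched vehicle controls and replicate arrays,
annotated with histopathology severity scores.  When a small subset of
conditions produces a disease phenotype — here the motivating case is
periportal liver fibrosis — the compendium can be mined for the molecular
machinery of that disease: which genes respond specifically to the
disease-producing exposures, and which part of the protein-interaction
network they form.

`fibronet` implements this end-to-end as a reusable pipeline:

1. non-specific probe filtering and a gene-by-condition log-ratio matrix;
2. per-condition differential expression by the rank-product statistic
   with a permutation FDR, aggregated over disease conditions;
3. co-expression clustering across *all* conditions with a dynamic tree
   cut, and selection of clusters activated in the disease conditions;
4. mapping of the combined disease gene set onto a protein-interaction
   network and extraction of maximally connected subnetworks with a
   node-exception budget;
5. overlapping module detection by maximal-clique agglomeration with
   extended modularity, module enrichment against curated gene sets, and
   module prioritization;
6. permutation significance, leave-one-quarter-out robustness,
   condition-specificity and time-course profiling, and correlation with
   external studies.

A synthetic-data module generates studies of this shape with recorded
ground truth, so every stage can be benchmarked for planted-truth
recovery.

## Log-ratios and filtering

The pipeline contract starts at a normalized log2 intensity table (probes
x samples); array normalization and outlier-array removal are upstream
concerns.  Three non-specific filters are applied in order: probes without
a gene annotation; probes whose inter-quartile range (IQR) across
treated-condition mean intensities falls below a quantile (default the
median) of the probe-IQR distribution; and probes present (all replicates
flagged) in fewer than 25% of conditions.  The quantile is converted once
to an absolute IQR threshold that is recorded with the output, so
re-filtering an already-filtered table is a no-op — a re-estimated
quantile would otherwise keep shaving the distribution in half.

For every treated condition the log-ratio is the mean over treated
replicates minus the mean over its matched control replicates (log2
scale).  When several probes map to one gene, the probe with the highest
IQR across conditions is kept, ties breaking to the lexicographically
smallest probe identifier.

Disease conditions are those with histopathology severity strictly
greater than 1.  Because a treatment can fail — replicates
indistinguishable from controls — candidates pass a replicate-clustering
quality check: treated and control replicates are clustered (distance
1 − Pearson r of gene-centred intensity profiles, average linkage), the
dendrogram is cut into two groups, and a condition whose treated
replicates all fall into the control-dominated group is excluded.  The
profiles are gene-centred first because the per-gene baseline intensity
otherwise dominates the correlation and hides treatment structure.

## Rank-product differential expression

For one condition with $n_T$ treated and $n_C$ control replicates, all
$K = n_T n_C$ pairwise log-ratios are formed and genes are ranked per
comparison (descending for up-regulation, ascending for down; ties get
average ranks).  The rank product of gene $g$ is the geometric mean
$RP_g = (\prod_k r_{g,k})^{1/K}$: a small $RP$ means consistently extreme
fold changes.  Significance is permutation-based: each null replicate
draws an independent uniform rank permutation per comparison, and with
$E(g)$ the expected count of null rank products at or below $RP_g$ and
$p$ the position of $g$ in the RP-sorted list, the proportion of false
positives is $\mathrm{pfp} = E(g)/p$, made monotone along the sorted list
by the usual step-up adjustment.

A caveat worth knowing: the $K$ comparisons share replicate arrays, so
their ranks are positively correlated, and the independent-rank null is
mildly anti-conservative at the extreme tail.  `rank_product_test()`
therefore also offers `null_method = "array"`, which permutes gene labels
per array and recomputes rank products; this null preserves the
shared-replicate correlation and is calibrated in pure-noise simulations.
The rank null remains the default because it is the cited method's
convention; the damage is limited in practice because a gene only enters
the disease DEG set when it passes FDR < 0.05 in at least two of the
disease conditions, which compounds the per-condition error rate
quadratically.

## Co-expression clusters and the activation score

Genes are clustered on their log-ratio profiles across *all* conditions
(distance 1 − Pearson r, average linkage) so that clusters reflect
general co-regulation rather than the disease contrast.  The dendrogram
is cut adaptively: a branch splits as long as both children hold at least
`min_size` genes (default 16); a branch that can no longer split becomes
a cluster built around its core.  The core is found by descending the
dominant child while shedding sub-minimum side branches — average linkage
chains loosely correlated genes onto the top of a branch, and keeping
them would dilute the cluster — and shed branches are reattached only if
they joined within `attach_frac` (default 0.25) of the height span
between the core and the dendrogram root.  Everything else is unassigned
(cluster 0).  Genes are sorted by identifier before clustering, so the
partition is invariant to input order.  A PAM-style reassignment of
unclustered genes to the nearest cluster is deliberately not performed.

Linking clusters to disease uses two normalizations.  First each gene's
log-ratios are standardized across all $N$ conditions,
$Z_{ij} = (x_{ij} - \mu_i)/\sigma_i$ (SD with denominator $n-1$;
zero-variance rows are dropped and counted).  Then the activation score
of a gene set $c$ over the disease conditions $F$ is the plain mean

$$A_c = \frac{1}{N_c N_F} \sum_{i \in c} \sum_{j \in F} Z_{ij},$$

with $N_c$ the genes that have expression rows and $N_F = |F|$.  Two
consequences are used as hard identity tests: every $Z$ row has mean 0
and SD 1 to machine precision, and $A$ over the *complete* condition set
is exactly 0 for any gene set.  Clusters with $|A_c| > 2$ (strict, the
95th percentile of the score's null spread) are selected, and their genes
are united with the DEG lists to form the disease-relevant gene set.
Note that $A$ is measured in per-gene SD units: a response only scores
highly if it stands out against the gene's variability across all other
exposures, so the disease fraction of conditions must stay small for
high scores to be reachable.

## Subnetwork extraction with node exceptions

The disease gene set is translated to network nodes through an ortholog
map; ambiguous entries (several targets per source) and unmapped genes
are excluded and counted.  For each of the four query lists (up/down ×
DEG/co-expressed) the extractor seeks a connected induced subgraph
containing as many query nodes as possible while admitting at most $K$
non-query *exception* nodes (default 100 per run, mirroring the
node-exception budget of keyword-miner style tools; case exceptions are
fixed at zero, so "active" simply means "in the query").

The solver is a deterministic greedy: components of the query-induced
subgraph are joined, starting from a seed component, by whichever
affordable move gains the most active nodes per exception spent — either
a minimum-exception-cost path to another component (path cost = non-query
nodes it adds; found with Dijkstra on half-endpoint edge weights) or a
*hub move* adding a single non-query node adjacent to the current
subnetwork and to one or more remaining components.  The growth restarts
from several seed components and keeps the best result.  A local
improvement pass then adds non-query nodes adjacent to at least two
active nodes while budget remains, and finally removes exception nodes
whose removal keeps the subgraph connected.  Hub moves and multi-start
matter: with pairwise path joins alone the solver misses star-shaped
optima where one exception connects three or four singleton query nodes.
On random 12-node instances with five query nodes and $K = 2$ the greedy
matches an exhaustive-search optimum in 99 of 100 instances and never
exceeds it.  An optional seeded stochastic refinement (`refine = TRUE`)
perturbs the exception set and keeps the best solution; it is off by
default since determinism aids reproducibility.  The four subnetworks are
merged by node union with edges induced from the parent network; the
union need not be connected.

## Overlapping modules and prioritization

Module detection follows the clique-agglomeration scheme of the EAGLE
family.  Seed communities are the maximal cliques of size ≥ 3 (smaller
seeds are trivial), after discarding *subordinate* cliques — cliques all
of whose members already occur in some larger retained clique — plus
singletons for uncovered nodes.  Communities are merged greedily by the
modularity-matrix similarity

$$S(C_1, C_2) = \frac{1}{2m} \sum_{v \in C_1, w \in C_2}
  \left(A_{vw} - \frac{k_v k_w}{2m}\right)$$

until one community remains, and the dendrogram level maximizing the
extended modularity

$$EQ = \frac{1}{2m} \sum_C \sum_{v,w \in C} \frac{1}{O_v O_w}
  \left(A_{vw} - \frac{k_v k_w}{2m}\right)$$

is returned, where $O_v$ counts the modules containing $v$ — modules may
overlap.  Both sums run over ordered node pairs including $v = w$
(with $A_{vv} = 0$); any consistent convention selects the same level,
and the test suite recomputes $EQ$ from the returned modules with an
independent double loop.  All ties break lexicographically.

Modules are characterized by (a) their activation score, after
back-translating nodes to expression genes, and (b) one-sided
hypergeometric enrichment $P(X \ge x)$ against curated disease gene sets,
with Benjamini–Hochberg correction across modules within each set.  The
enrichment background defaults to the full network's node count, which
reproduces, at printed precision, the bulk of the enrichment statistics
reported for this analysis's motivating study when fed their printed
counts against the 14,230-node human high-confidence interaction
network.  Modules are ranked by the number of curated sets significantly
enriched, then activation score, then size, then identifier.

## Significance, robustness and specificity

Two permutation nulls ask whether the prioritized module's cohesion could
arise by chance, both comparing the observed largest-connected-component
(LCC) node and edge counts of the module-induced subgraph with 1,000 null
replicates; the empirical p is the fraction of null statistics at or
above the observed (a `(count+1)/(reps+1)` correction is available behind
a flag).  The *random-sampling* null draws equally many nodes uniformly.
The *rewiring* null shuffles the network by double-edge swaps (10
attempted swaps per edge; swaps creating self-loops or multi-edges are
rejected), which preserves the full degree sequence — a construction
stricter than preserving only the average degree — and is asserted per
replicate.  Under degree-preserving rewiring a dense module's *nodes*
stay largely connected (they keep their high degrees), so the edge count
is the discriminating statistic there; both are reported.

Robustness follows a leave-one-quarter-out design: replicate samples are
partitioned into four folds, stratified by condition so every condition
keeps at least one treated and one control replicate per fold removal;
the whole pipeline is re-run without each fold and the overlap fraction
of the re-run's top-module nodes with the full-data top module is
reported.  Specificity profiles the top module's mean Z-score in every
condition with disease-condition ranks, conditions are clustered on the
module genes' log-ratios (1 − Pearson r, average linkage, flat clusters
by the silhouette-maximizing cut over k ∈ [2, 20] — the cut criterion is
otherwise unstated in this family of analyses), time-course profiles
average log-ratios per timepoint with genes called activated above a
strict 0.6 log2 threshold (≈1.5-fold), and external validation is the
Pearson correlation of matched per-gene log-ratios against an external
study.

## The synthetic study generator

`generate_study()` emulates the compendium shape: per-gene baseline log2
intensities (mean 8, SD 1.5), treated and control replicates per
condition (default 3 + 3), replicate-level Gaussian noise
(`noise_sd = 0.4` log2 units), and per-gene condition effects of scale
`effect_sd = 0.2` for unresponsive background genes.  Structure is
planted on top:

* **DEGs** — 100 genes (50 up, 50 down) shifted by ±1.0 log2 units in
  treated samples of the 4 disease conditions (of 100), applied at
  replicate level.  Responsive genes also vary more across the *other*
  exposures (`responsive_effect_sd = 0.3`) — this is the premise of
  IQR-based non-specific filtering, and it is what lets planted genes
  survive a median-IQR cutoff.  Their disease-condition response is
  exactly the configured shift plus background-level variation, so the
  planted effect size is what the configuration states.
* **Co-expression blocks** — 8 blocks of 30 genes share a latent
  per-condition factor with loading
  $a^2 = \frac{\rho}{1-\rho}(\sigma_e^2 + \sigma_m^2)$, where
  $\sigma_m^2$ is the measurement-noise variance of a condition
  log-ratio; this calibration makes the *observed* pairwise correlation
  within a block ≈ `block_correlation` (default 0.6) after noise.  Block
  1 is the disease block: its factor is pinned at
  `disease_block_amplitude = 4` in disease conditions, so its genes are
  both strongly co-expressed and genuinely up-regulated there (and are
  counted in the up ground truth).  Background blocks are constructed
  orthogonal to the disease contrast (factor 0 in disease conditions) so
  the planted DEG ground truth is exhaustive — otherwise factor-driven
  coherent shifts would create unplanted true positives and make
  precision against the planted truth ill-defined.
* **Presence flags** — Bernoulli(0.9) per cell for expressed genes; a 5%
  "absent" subset (drawn outside the planted genes) gets Bernoulli(0.1),
  exercising the present-call filter.

`generate_network()` grows a preferential-attachment background graph
(1,500 nodes, 3 edges per new node — heavy-tailed degrees), wires a
60-node module with internal edge probability 0.3 on top, and emits
curated sets (sizes 26 and 95, mirroring the literature and
database-derived reference sets such analyses use) drawing half of each
set from the module, plus an ortholog map with ~5% unmapped and ~3%
ambiguous entries.  Passing the study ground truth couples the module to
the planted up-regulated disease genes, enabling end-to-end recovery
benchmarks; the generator seed fixes every draw.

What the generator does **not** emulate: probe-level array artifacts,
batch effects, dose–response kinetics, correlated measurement noise,
biologically structured networks (the background is scale-free but
otherwise random), or partial orthology structure beyond flat
unmapped/ambiguous fractions.  Passing recovery tests therefore
demonstrates internal consistency of the pipeline under its own model of
the data, not performance on real compendia.

## Numerical choices and degenerate inputs

Tolerances: Z-row identities at 1e−12, the all-conditions activation
identity at 1e−10, TSV round-trips at better than 1e−12 (values written
with 17 significant digits).  Constant log-ratio rows are dropped before
standardization with a logged count; a single condition is an error
(σ undefined).  Empty-vs-empty set recovery has Jaccard 1 by convention
with precision/recall flagged missing.  Edgeless graphs yield singleton
modules with EQ 0; an empty graph is an error.  All clustering,
extraction and agglomeration tie-breaks are lexicographic on sorted
identifiers, making every deterministic stage invariant to input order;
the only seeded stages are the generator, the permutation nulls, the
rank-product null, the fold assignment and the optional refinement.

## Test-suite problem sizes

The unit suite exercises reduced-scale studies (300 genes, 40
conditions, 250-node networks) for speed, with brute-force oracles at
toy sizes: explicit-loop rank products on 20 genes, exhaustive
rank-permutation pfp on 5 genes, exhaustive subnetwork search on 12-node
graphs, subset-enumeration maximal cliques on 10 nodes, and double-loop
EQ recomputation.  The acceptance tests run the full default-scale study
(2,000 genes × 100 conditions, 1,500-node network) once and assert
planted-truth recovery, null-model significance, condition clustering,
specificity and 4-fold stability on it.

## Known limitations

* The default rank-permutation pfp is anti-conservative at the extreme
  tail for the all-pairs design (see above); use
  `null_method = "array"` when calibrated per-condition FDR matters more
  than fidelity to the classical convention.
* The subnetwork extractor is a heuristic; its optimality is verified
  only at small instance sizes, and the exception budget is per
  extraction run, not shared across the four runs.
* Clique agglomeration is quadratic in the number of seed communities
  and keeps a dense modularity matrix; it is intended for extracted
  subnetworks (hundreds of nodes), not full interactomes.
* Activation scores inherit the Z-score's dependence on the condition
  panel: adding or removing conditions changes every gene's μ and σ and
  hence every score.
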