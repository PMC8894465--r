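---
title: "Community architecture: segregation, overlap, and what they buy a network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Community architecture: segregation, overlap, and what they buy a network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(commarch)
```

## The two-axis picture

`commarch` characterizes an undirected, unweighted network along two
complementary axes of community architecture:

* **Segregation** — how cleanly the network splits into non-overlapping
  modules. We quantify it as the Newman–Girvan modularity
  $Q = \sum_c \left[ L_c/m - \gamma (d_c/2m)^2 \right]$ of the best
  partition found by Louvain optimization at resolution $\gamma = 1$
  (`segregation_score()`). $Q$ compares the fraction of edges inside each
  community with the expectation under a degree-preserving random model.
* **Overlap** — how much those modules share nodes. Communities of *edges*
  (link communities) induce overlapping node memberships: each node belongs
  to every community that claims one of its incident edges. The **overlap
  score** (`overlap_score()`) is the mean number of memberships per node.
  For group comparisons the score is divided by the mean score of
  degree-preserving random nulls (`normalized_overlap_score()`), so 1 means
  "no more overlap than the degree sequence alone explains".

The point of the two-axis view is that the axes are not redundant: across
planted-partition networks, overlap is a *bell-shaped* function of
segregation, peaking at moderate segregation rather than at either extreme
(`sweep_architecture()`). A network can therefore "maintain its segregated
structure" — at least as many overlapping communities as planted modules,
`maintains_segregated_structure()` — while still being overlap-rich.

## Link communities and the partition-density cut

Two edges sharing a node $k$, with non-shared endpoints $i$ and $j$, get
similarity $|n^+(i) \cap n^+(j)| / |n^+(i) \cup n^+(j)|$, where
$n^+(x)$ is $x$ plus its neighbors. Non-adjacent edge pairs have
similarity 0 and can only end up together through chains of merges. Edges
are agglomerated by single linkage and the dendrogram is cut where the
partition density

$$D = \frac{2}{m} \sum_c \frac{m_c\,(m_c - (n_c - 1))}{(n_c - 2)(n_c - 1)}$$

is maximal ($m_c$ edges spanning $n_c$ nodes in community $c$). Numerical
choices, all deterministic:

* Because positive similarity implies adjacency, single linkage is computed
  in Kruskal/union-find form over the adjacent-pair list sorted by
  descending similarity; ties are processed in lexicographic edge order, and
  equal-similarity merges count as one dendrogram level, so cuts are only
  taken between levels.
* Communities spanning two nodes (single edges) contribute 0 to $D$; they
  are *kept* as communities and count toward node memberships. This is a
  documented convention, not a theorem: dropping single-edge communities
  would lower overlap scores, and the choice is isolated in
  `link_community_cover()`.
* Ties between cuts break toward fewer communities (the later cut). On
  trees every cut has $D = 0$ and the tie rule merges each component into
  one community, giving overlap exactly 1.
* Isolated nodes receive one fresh singleton membership so that every node
  belongs to at least one community; on rosters without isolated nodes this
  clause never fires.

A practical consequence worth knowing: on sparse Erdős–Rényi graphs the
maximum of $D$ is typically attained only at the fully merged cut, so the
overlap score of a random graph is 1. That makes the null normalization
well behaved (ratios hover at 1 for random inputs) and makes overlap > 1 an
actual structural signal.

## Nulls, generators, and the sweep

Degree-preserving nulls use double-edge-swap rewiring (10 attempted swaps
per edge by default), rejecting swaps that create self-loops or
multi-edges, and — because the rewired graph should stay one communicating
system — swaps that disconnect the graph. The latticized variant
additionally accepts a swap only when it does not increase the total ring
distance of the swapped edges under the fixed circular node ordering. The
connectivity test short-circuits: an edge whose endpoints still share a
neighbor is not a bridge, so the full search runs only for the rare
remaining cases.

`generate_modular(N, M, p_in, p_out)` plants $M$ equal modules;
`generate_er(N, λ)` draws $G(N, p)$ with $p = λ/(N-1)$. The architecture
sweep varies $p_{in}$ over $[0.7, 1]$ and $p_{out}$ over $[0.01, 0.35]$
(0.02 steps at full resolution; the bundled analyses use 0.06 steps with 5
replicates per cell, which already resolves the bell shape), averaging
segregation and overlap per cell and optionally rescaling overlap by its
sweep maximum. Disconnected draws are scored on their largest component and
counted.

## Topological reinforcement and communication readouts

`tr_step()` implements a Hebbian-flavored rewiring: half the nodes
(degree $\notin \{0, N-1\}$) each propose one new link to the non-neighbor
with the most common neighbors (topological overlap), proposals are scored
against the pre-step graph and inserted as one batch, and an equal number
of randomly chosen links is deleted, resampling any deletion that would
disconnect the graph (retry budget 100 per deletion). Ties among equally
good partners break uniformly at random from the seeded stream. Density and
node count are conserved exactly; 60 steps from an ER start
($N = 164$, $λ = 16$, i.e. 10% density) is the standard depth at which
modularity emerges.

Per step the trajectory records routing-based efficiency (global efficiency:
mean inverse shortest-path length; local efficiency: the same within each
node's neighbor subgraph, degree < 2 contributing 0) and a diffusion-based
readout: the steady-state activated fraction of a linear threshold process
(`linear_threshold()`). There, each active node exerts $1/\deg(v)$ influence
on a neighbor $v$ — *receiver*-side weighting, so incoming influence sums
to 1 — and an inactive node activates once summed influence reaches
$\theta$ ($\geq$ by default; `strict_threshold` flips to $>$, which matters
on even-degree nodes at $\theta = 0.5$). Standard settings: $\theta = 0.5$,
seed fractions 5–50%, 32% for trajectory readouts, 20 random seed sets per
measurement.

In our ensembles the activated-node ratio peaks close to the overlap peak
along TR evolution, as does global efficiency's plateau; local efficiency,
by contrast, keeps rising essentially monotonically as clustering
accumulates, so its argmax sits late in the trajectory rather than at the
overlap peak. We report the argmax offsets as computed rather than
smoothing them away; on 10-network ensembles the efficiency curves are
plateau-like and their argmax is accordingly noisy.

## Dynamic flexibility

Sliding-window Pearson correlation turns a nodes × time panel into an
$N \times N \times W$ connectivity tensor; with a 30-s window at 0.72-s
sampling the window is 42 samples, and a full 4,800-sample scan shifted one
sample gives $W = 4759$. Each window's positive correlations are clustered
with weighted Louvain ($\gamma = 1$), and labels are aligned across
consecutive windows by a maximum-overlap one-to-one assignment on the
community contingency table (exact by enumeration when the smaller side has
at most 7 communities — always the case in our regimes — greedy beyond).
A node's **flexibility** is the fraction of consecutive-window transitions
at which its matched label changes; the mean over nodes is the network's
dynamic reconfiguration rate. Matching is what makes the measure
permutation-proof: without it, label churn would masquerade as flexibility.
This per-window-detect-then-track construction is one reconstruction of
"dynamic community detection"; a genuine multilayer optimization with
inter-layer coupling is a known alternative and deliberately out of scope —
the matching step is isolated behind one interface so it could be swapped.

Cohort-scale analyses step the window by half its length (15 s) rather than
one sample; flexibility is a per-transition rate, so coarser stepping trades
variance for speed without biasing cross-subject comparisons. Full-resolution
stepping remains available via `step_seconds`.

## The synthetic cohort

`generate_cohort()` stands in for an imaging cohort. Per subject:

1. **Structure.** A planted-partition network at exactly 10% density on 164
   nodes. The sweep's $(p_{in}, p_{out})$ ranges are infeasible at that
   density, so the generator instead samples a between-module mixing
   fraction $\mu \sim U(0.10, 0.60)$ and solves $p_{in}, p_{out}$ from the
   edge-budget constraint, then trims/adds a handful of uniform edges to hit
   the budget exactly. This spans low-to-high segregation at fixed density.
2. **Dynamics.** A 50-node panel whose latent module partition switches at
   Poisson-distributed times; the expected switch count is
   $2 + 8 \cdot \text{overlap percentile}$, planting a positive
   structure–dynamics coupling. Within a stationary segment each node is its
   module's shared unit-variance signal (fresh draw per sample) plus
   $\mathcal{N}(0, 0.8^2)$ noise, giving within-module correlations near
   0.6 — a typical sliding-window regime.
3. **Behavior.** Three scores (pattern-completion-, card-sorting-,
   flanker-like) drawn as $\rho\, z(\text{overlap}) + \sqrt{1-\rho^2}\,
   \varepsilon$ with $\rho = 0.26$ by default, in the middle of the small
   positive correlations such studies report. The couplings are planted on
   the raw overlap score: at fixed $N$ and density the null mean is nearly
   constant across subjects, so normalization is a per-cohort rescaling
   that leaves correlations unchanged.

What the generator does *not* emulate: hemodynamics, parcellation error,
head motion, heavy-tailed degree structure, spatial embedding, or any
weighted connectivity. Passing recovery tests therefore shows the pipeline
is consistent and unbiased on block-structured inputs — not that the
planted effect sizes are attainable in real imaging data.

## Problem sizes and reproducibility

The bundled validation runs use: an 0.06-step sweep grid with 5 replicates
(36 cells, $N = 100$, $M = 5$); TR ensembles of 10 networks × 60 steps;
20 cohort replicates of 100 subjects with 1,200-sample panels; 20 ER
instances × 10 nulls for self-normalization. These sizes resolve every
qualitative claim while keeping a full run in minutes on one core. Every
stochastic entry point takes a `seed` and restores the caller's RNG state
(`withr::with_seed`); sub-seeds are drawn once from the master seed, so
results are bit-reproducible end to end, and `run_pipeline()` stamps every
output table with a hash of its configuration.

## Known limitations

* Louvain is a greedy heuristic; `n_runs` restarts (default 10) make small
  instances reliably optimal but give no guarantee at scale.
* The overlap score inherits the single-edge-community convention; report
  it alongside `n_communities` when comparing against other
  implementations.
* Latticization only ever accepts cost-non-increasing swaps and can stall
  in local minima, as all swap-based latticizers do.
* On graphs whose line graph has many equal-similarity ties the dendrogram
  is deterministic but convention-dependent (lexicographic edge order).
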