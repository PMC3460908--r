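---
title: "Rich-club organization in directed brain networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rich-club organization in directed brain networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`richclubnet` analyses binary directed connectomes — square 0/1 matrices in
which `a[i, j] = 1` records an anatomical projection from region *i* to
region *j* — with the question: are the network's hubs interconnected more
densely than their degrees alone would predict, and what does that imply
for communication along shortest paths? This vignette documents the models
and conventions the package implements, the choices made where the
methodology is genuinely open, and what the synthetic test bed does and
does not establish.

## The rich-club statistic and its null

Node degree is throughout the *total* degree `k = k_in + k_out`. For a
threshold `k`, the rich-club coefficient

$$\Phi(k) = \frac{E_{>k}}{N_{>k}\,(N_{>k}-1)}$$

is the directed density of the subgraph induced by nodes with degree
`> k`. High-degree nodes are densely linked even in random graphs, so
Φ(k) is calibrated against a population of degree-preserving randomized
networks: `phi_norm(k) = phi(k) / mean(phi_random(k))`. Per threshold the
package computes a one-sided permutation p-value with add-one correction,
`p = (1 + #{null >= observed}) / (1 + n_null)`, which cannot be exactly
zero and is honest about Monte-Carlo resolution. Benjamini–Hochberg
correction (via `stats::p.adjust`) at `q = 0.05` controls the false
discovery rate across the swept thresholds.

Rich-club *levels* are read off the longest contiguous run of significant
thresholds — the rich-club regime. Within the regime, consecutive
thresholds that select the same node set collapse into one level, and the
levels form a strictly nested hierarchy, innermost (highest threshold)
first. Isolated significant thresholds outside the regime — typically
density fluctuations of very small top-degree subgraphs — stay flagged in
the returned curve but do not define levels. Because the nulls preserve
the degree sequence exactly, the node set at each threshold is identical
across null members; only edge counts differ, which is what makes the
sweep cheap (one pass over each member's edges).

Given a club, edges classify as *rich-club* (both endpoints inside),
*feeder* (exactly one), or *local* (none) — an exhaustive partition used
by the path and cost analyses.

## Null models

Both null models rest on one Markov chain of double-edge swaps
`(a->b, c->d) => (a->d, c->b)`, rejecting swaps that would create
self-loops or duplicate edges; every accepted swap conserves each node's
in- and out-degree exactly. The default of 10 attempted swaps per edge is
a package choice for chain mixing; acceptance counts are returned so
mixing can be monitored. The *latticized* model adds an acceptance rule:
under a node ordering drawn at random per instantiation, a swap is kept
only if the combined distance of the two edges from the matrix diagonal
does not increase (optionally: strictly decreases), concentrating edges in
a band — a cost-efficient approximate ring lattice. Ensembles derive
member sub-seeds from one master seed by multiplicative hashing, so they
are reproducible member by member.

## Global metrics

Directed clustering follows the symmetrized-triangle form: with
`S = A + t(A)`, `t_i = (S^3)_ii / 2` and
`C_i = t_i / (k_i (k_i - 1) - 2 k_i^rec)`, where `k_i^rec` counts
reciprocal neighbours; the denominator removes the "false triangles" a
reciprocal dyad would otherwise contribute. Characteristic path length is
the mean finite directed hop distance (breadth-first, via igraph); global
efficiency the mean inverse distance; local efficiency the global
efficiency of each node's neighbourhood subgraph (union of in- and
out-neighbours). The small-world indices are

* `gamma = C / <C_rand>`, `lambda = L / <L_rand>`, `sigma = gamma/lambda`
  (randomized calibration), and
* `omega = <L_rand>/L - C/<C_latt>`, which is near 0 for small worlds,
  negative toward lattices, positive toward random graphs.

## Community structure and node roles

Directed modularity
`Q = (1/m) * sum_ij (a_ij - k_i^out k_j^in / m) * delta(c_i, c_j)` is
optimized spectrally: recursive bisection on the leading eigenvector of
the symmetrized modularity matrix `(B + t(B))/2` with a Kernighan–Lin
style sign-flip refinement at each split, followed by a global refinement
that interleaves greedy single-node moves (to any module) with module
merges, and five seed-controlled perturb-and-refine restarts that keep the
best Q. The restarts exist because recursive bisection alone demonstrably
stalls in local optima on block-structured networks. Results are
deterministic given the seed.

Node roles use total degree: participation
`P_i = 1 - sum_s (kappa_is / k_i)^2` over modules `s`, and a within-module
degree z-score standardized per module (singleton modules get z = 0, with
a warning). Connector hubs are nodes with `z > 2` and `P > 0.5`.

## Centrality

Four measures: betweenness (fractions of shortest paths through a node as
intermediate), closeness (mean of in- and out-closeness; inverse mean
distance on strongly connected inputs, harmonic mean of inverse distances
otherwise), vulnerability (drop of global efficiency after node deletion,
recomputed over the remaining nodes — peripheral nodes can legitimately go
negative and are not clipped) and dynamical importance (relative drop of
the dominant adjacency eigenvalue after deletion; the eigenvalue is taken
from a dense eigendecomposition, the appropriate tool at a few hundred
nodes). The global centrality score counts, per node, the measures in
which it reaches the 90th percentile (quantile with midpoint
interpolation; threshold ties are all included).

## Triad motifs and stars

The census enumerates every weakly connected induced 3-node subgraph and
classifies it among the 13 directed triad classes — induced counting, so a
fully reciprocal triangle is one class-13 instance. For 3-node digraphs
the sorted multiset of per-node (out-degree, in-degree) pairs is a
complete isomorphism invariant, which both the classifier and its
brute-force test oracle exploit. Class ids are assigned by edge count
ascending, then lexicographically by that signature; `motif_dictionary()`
ships the full id-to-edge-set table so the numbering is auditable. The
three *apex* classes — one node adjacent to two mutually unconnected
leaves — land at ids 4 (reciprocal + outgoing leaf), 6 (reciprocal +
incoming leaf) and 9 (doubly reciprocal), and the apex ratio of a node is
the fraction of its apex-class instances in which it occupies the apex.
Class counts are compared against both null models by z-score and
empirical p-value; classes with zero null spread are flagged rather than
scored.

A *star* is a centre reciprocally connected to leaves with no edges among
the leaves; finding the largest one is a maximum-independent-set problem
over the centre's reciprocal neighbours. The heuristic adds neighbours
greedily in ascending-degree order and keeps the best of 20 random-order
restarts; on small graphs it matches exhaustive search.

## Shortest-path analytics

All path counting rests on one identity of unweighted digraphs: a walk
whose length equals the endpoint distance is automatically a simple path,
and every shortest path arises this way. Hence
`sigma_st = (A^d(s,t))[s, t]`, and positional quantities factor through
matrix powers: the number of shortest s–t paths with node v at position p
is `A^p[s, v] * A^(L-p)[v, t]`. This yields, without enumeration:

* per-edge and per-node usage and betweenness (per-source dynamic
  programming over the distance matrix);
* club participation by complement — paths avoiding club nodes are counted
  in the graph with club rows/columns removed from the interior steps,
  paths avoiding club edges in the graph minus club–club edges, both at
  unchanged path length;
* degree distributions, club-touch probabilities per position and
  club-edge-travel probabilities per step, for each path length between
  non-club endpoints;
* entry and exit events at each club node (every boundary crossing
  counts), whose difference and normalized ratio
  `(in - out) / (in + out)` express net directional flow.

Flow significance is an empirical two-sided p-value against a
degree-preserving randomized ensemble, add-one corrected, computed on the
absolute deviation from the null mean. It is evaluated both for the ratio
and for the raw count imbalance; the flag uses the count statistic because
the ratio saturates at ±1, where occasional ±1 null ratios tie the
observation and make its p-value conservative no matter how strong the
asymmetry. Flags are reported uncorrected at α = 0.01, as is conventional
for this exploratory per-node screen.

Communication cost multiplies each edge's usage by the Euclidean distance
between its endpoint centroids (coordinates are taken as millimetres and
not rescaled); analyses restrict to the coordinate-covered subnetwork, and
class comparisons use one-sided Wilcoxon rank-sum tests.

## The synthetic test bed

Real tract-tracing connectomes cannot be redistributed with the package,
so every stage is validated on a generator with planted ground truth.
The default emulates a macaque-cortex-scale network: 242 nodes, five
equal modules with within/between directed densities 0.191/0.037 (overall
≈ 0.068), edge-wise reciprocity 0.507, a broad exponential-like degree
distribution, and a nested planted core — a 12-node club wired at density
0.64 inside a 46-node shell whose pair density interpolates linearly down
to 0.43 at the shell edge, with club members spread over all five
modules. Coordinates place each module in a 3D Gaussian cluster (4 mm
within-module spread, ~25 mm between centres), so module-spanning core
edges are long.

Design choices that deserve explanation:

* **Reciprocity is built in at the dyad level.** Each unordered pair
  receives both edges with probability `rho*d` and a single edge in either
  direction with probability `d*(1 - rho)` each, hitting the target
  directed density `d` and reciprocity `rho` exactly in expectation —
  simpler and more exact than post-hoc edge pairing with repair swaps.
* **The core is nested, not a bare club.** At club-level degrees a
  degree-preserving null already concentrates edges among the club
  (the no-multi-edge constraint saturates high-degree dyads), leaving a
  boundary z-score near 2 that cannot survive FDR on its own. Empirical
  connectomes show the same structure — a marginal innermost level carried
  by a hierarchy of outer shells — so the generator plants the hierarchy.
* **Club propensities are absolute and laddered; shell propensities are
  capped.** An absolute club level (3.1 on the bulk-propensity scale,
  with a 6% descending ladder) keeps club degrees, and hence the null
  density at the club boundary, stable across seeds; the ladder gives the
  club a reproducible internal degree order so degree-threshold subsets of
  the club are fixed sets rather than luck-selected ones; the shell cap
  (1.2) keeps shell degrees below club degrees so thresholds separate the
  tiers. These values were calibrated so that the generator meets its
  contract — the innermost detected level recovers the planted club — at
  the default study scale; the recovery remains intrinsically marginal,
  as it is in real data, and occasional boundary misses of one to two
  nodes are expected.
* **Core dyad states are drawn with exact counts** (largest-remainder
  apportionment per nesting rank), so planted densities are realized with
  minimal seed-to-seed fluctuation and detectability is governed by the
  design rather than by sampling luck.
* **Baseline block densities are rescaled** (separately for within- and
  between-module pairs) so the *realized* block densities, core included,
  match their targets — mirroring how empirical block densities subsume
  the core. At small network sizes the core can exceed a block's budget;
  the baseline is then floored and the realized density overshoots, which
  the generated object flags.

What the generator does **not** emulate: overlapping or hierarchical
parcellations (regions contained in other regions), spatial wiring costs
shaping the non-core connectivity, heterogeneous module sizes, and any
weighting of projections. Passing the planted-recovery tests therefore
shows that the machinery detects nested rich-club structure of realistic
strength at realistic scale under a known truth — not that any particular
empirical network has such structure.

## Problem sizes and tolerances

The test-suite and acceptance settings are package choices balancing
Monte-Carlo resolution against runtime: 500-member randomized ensembles
for rich-club recovery (p resolution 1/501), 200 members for type-I
checks and flow asymmetry (the smallest attainable two-sided add-one p,
2/201, sits just under the 0.01 flag threshold — fewer members cannot
flag anything), 100 + 100 members for small-world and motif calibration,
and exhaustive-enumeration cross-checks on 1000 random digraphs of up to
6 nodes. Brute-force oracles in the tests (Floyd–Warshall, explicit path
enumeration, permutation-matching triad classification, exhaustive
set-partition and independent-set search) share no code with the package.

## Known limitations

* Reported analyses are binary; projection weights, when available, carry
  information the package ignores by design.
* Euclidean centroid distance is a lower bound on fibre length, so
  communication-cost shares understate long curved pathways.
* The spectral modularity optimizer is deterministic given its seed but,
  like all modularity maximizers, offers no global-optimality guarantee;
  on the synthetic block networks it matches or exceeds the planted
  partition's Q.
* Degree-preserving randomization can mix poorly on dense or highly
  constrained degree sequences; acceptance ratios should be checked when
  the method is applied to networks much denser than ~0.1.
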