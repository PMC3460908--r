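# richclubnet

Graph-theoretical analysis of binary **directed** connectomes — networks of
brain regions and their anatomical projections — centred on statistically
validated **rich-club detection**: do the network's hubs connect to one
another more densely than their degrees alone would predict, and how much of
the network's shortest-path communication do they carry?

The package is written for connectomics researchers working with
tract-tracing-style data (directed, binary, a few hundred regions), but all
of it applies to any directed binary graph.

## What it computes

For a network with total degrees `k = k_in + k_out`, the rich-club
coefficient at threshold *k* is the directed density of the subgraph of
nodes with degree > *k*:

    Phi(k)      = E_{>k} / (N_{>k} (N_{>k} - 1))
    Phi_norm(k) = Phi(k) / < Phi_random(k) >

calibrated against an ensemble of degree-preserving randomized networks
(Markov double-edge swaps), with one-sided permutation p-values per
threshold and Benjamini–Hochberg FDR across thresholds. Significant
thresholds yield a nested hierarchy of rich-club levels; edges classify as
rich-club / feeder / local.

Around that core the package provides, for directed binary graphs:

* **Null models** — degree-preserving randomization and latticization
  (band-concentrating variant), as seeded reproducible ensembles;
* **Small-world metrics** — Fagiolo-style directed clustering, path length,
  global/local efficiency, and the indices gamma, lambda, sigma, omega;
* **Community structure** — spectral optimization of directed modularity
  with refinement, block densities, participation coefficients,
  within-module degree z-scores, connector hubs;
* **Centrality** — betweenness, in/out closeness, vulnerability, dynamical
  importance, and a top-decile consistency score;
* **Motifs** — exact 13-class directed triad census with per-node apex
  statistics and z-scores against both null models, plus heuristic
  largest-star search (`motif_dictionary()` ships the class numbering);
* **k-core decomposition** with subshell (detachment-order) ranks;
* **Shortest-path analytics** — exact counts of all shortest paths,
  per-edge/per-node usage, rich-club path participation (touch/travel),
  degree profiles along paths, directional flow into and out of the club
  with permutation significance, cross-module involvement, and Euclidean
  communication cost;
* **A synthetic generator** (`generate_network()`) producing
  macaque-cortex-scale networks with planted modules and a planted nested
  rich club, so the whole pipeline is testable against known truth.

## Worked example

The `analysis/` directory is a numbered workflow over the package. Stage 1
simulates the default study network; later stages analyse it. A condensed
session:

```r
library(richclubnet)

gen <- generate_network(synthetic_spec(seed = 1))
net <- gen$net
net
#> <connection_matrix> 242 nodes, 4022 directed edges (density 0.0690)

reciprocity(net)
#> [1] 0.5166584

rand <- build_ensemble(net, "randomized", 500, seed = 1001)
rc <- rich_club_curve(net, rand)
rc
#> <richclub_result> 116 k values swept, 70 significant, 56 unique levels
#>   level sizes (innermost first): 14 16 17 19 21 23 24 25 27 31 ...

inner <- rc$levels[[1]]
length(intersect(inner, gen$truth$rc_nodes)) / length(union(inner, gen$truth$rc_nodes))
#> [1] 0.8571429    # innermost level recovers the planted 12-node club

part <- optimize_modularity_directed(net, seed = 303)
part
#> <modular_partition> 5 modules, Q = 0.3526, sizes: 50 47 50 47 48

pp <- rc_participation(net, gen$truth$rc_nodes)
round(100 * c(touch = pp$frac_touch_node, travel = pp$frac_travel_edge), 1)
#> touch travel
#>  60.8   12.7
```

Reading the numbers: the network is sparse (7% density) with half its
projections reciprocated; detection finds a nested hierarchy whose
innermost level is the planted club plus two boundary nodes; modularity
recovers the five planted modules (Q ≈ 0.35); and although the club holds
5% of the nodes, 61% of all shortest paths between non-club regions pass
through it and 13% travel on club-internal edges — the signature of a
communication core. Stage 6 additionally shows club edges carrying ~3x
their density share of Euclidean communication cost, and the degree
profile of length-3 paths rising then falling (median degrees
23 → 72 → 71 → 23).

Run the full workflow with:

    for f in analysis/0*.R; do Rscript "$f"; done

Tables land in `results/`.

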