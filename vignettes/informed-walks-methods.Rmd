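---
title: "Informed walks: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Informed walks: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(informedwalks)
```

# The model

A co-expression network alone tells a random walker nothing about function:
a walk guided purely by topology reproduces the topology. The informed-walk
model therefore gives walkers a second graph to consult — a *pathway map*
in which pathways are nodes and two pathways are linked when they share
genes, with the shared-gene count as edge weight. Walkers move on the gene
network, but decide *where to head next* by looking up the members of their
current pathway, and decide *which pathway to hold* by a biased Monte-Carlo
draw on the map. A heavy-tailed Lévy mechanism occasionally relocates the
walker wholesale, preventing entrapment in dense, heavily-weighted
neighbourhoods.

Each walker round is one movement event, so the total number of edge
traversals decomposes exactly over rounds:

1. *Lévy decision.* Draw `s ~ P(s) ∝ s^-mu` on `{1, ..., levy_max_steps}`.
   If `s >= levy_trigger`, perform `s` greedy steps, each along the
   incident edge of maximum weight whose far node has not been visited
   within this flight (tie-break: lexicographic node order; if every
   neighbour was visited, the maximum-weight neighbour regardless, which
   can re-traverse an edge). Otherwise the decision is a no-op.
2. *Informed step* (no-op flights only). Candidate targets are the members
   of the walker's current pathway present in the network, excluding the
   current gene. The walker relocates along the full shortest path to the
   candidate at minimum distance, recording every edge on the path, then
   redraws its pathway: with probability `p_informed` among map neighbours
   proportionally to shared-gene weight, otherwise uniformly over all
   pathways (including the current one and pathways sharing no genes).
   If the pathway offers no present, reachable candidate, the pathway is
   redrawn up to 10 times, after which the round falls back to one Lévy
   decision. The cap guarantees termination on maps with many pathways
   that are empty relative to the network.

Summing traversals over all walkers yields the passage-frequency network,
whose node set equals the input network's. Its top-K edges (count
descending, then lexicographic) induce the highlighted subnetwork.

# Parameters

| parameter | default | meaning |
|---|---|---|
| `n_walkers` | 300 | independent restarts; each walker draws its own uniform starting gene and pathway |
| `n_iterations` | 1000 | movement rounds per walker |
| `p_informed` | 0.7 | probability of the shared-gene pathway-transition branch; the complement (0.3) samples uniformly over all pathways |
| `levy_exponent` (mu) | 2.0 | power-law exponent of the flight-length distribution (dimensionless; smaller = heavier tail) |
| `levy_trigger` | ceil(ln N) | minimum sampled length that fires a flight |
| `levy_max_steps` | ceil(sqrt N) | support cap of the length distribution |
| `distance_mode` | `inverse_weight` | shortest-path edge length 1/w; `hop_count` uses unit lengths |
| `seed` | 1 | master seed; one L'Ecuyer-CMRG substream per walker |

The walker/iteration/branch defaults are the published operating point of
the model; the Lévy constraints are tied to the gene count N, which the
source description states only as "N defines the thresholds and
constraints" — the concrete forms ⌈ln N⌉ and ⌈√N⌉, the exponent 2, and the
greedy max-weight flight semantics are this package's documented
interpretation, all exposed as configuration.

Upstream inference defaults: the k-nearest-neighbour MI estimator with
k = 3 (the estimator's customary small-k choice, trading variance for
bias), and an exact threshold scan in the connectivity filter. The filter's
`resolution` parameter reproduces percentage-grid filtering when wanted,
but the exact scan — equivalent to the maximum-spanning-tree bottleneck —
dominates any grid and is the default.

# Design choices where the description was open

* **"Restarts" are walker multiplicity.** 300 restarts are read as 300
  independent walkers rather than in-walk teleportation, matching the
  equation of restarts with walkers and making per-walker parallelism
  trivial: results are invariant to execution order because each walker
  owns an RNG substream.
* **Weight-proportional, not argmax, informed transitions.** "Favouring
  pathways with more common genes" is operationalised as sampling
  neighbours proportionally to the shared-gene weight. An argmax would
  make the informed branch deterministic and re-create the entrapment
  problem the model exists to avoid.
* **The uniform branch includes the current pathway** and isolated
  pathways, which is why isolated pathways remain map nodes after
  construction and restriction.
* **Pathway graph rebuilt after restriction.** Walkers can only use genes
  present in the network, so sets are intersected with the node set first
  and the map is rebuilt on the restricted sets (`rebuild = FALSE`
  behaviour, building the map before restriction, can be emulated by
  calling `build_pathway_graph()` on the unrestricted sets directly).
* **Path ties.** Distance ties among candidate genes break uniformly at
  random (seeded); among equal-length shortest paths to the chosen
  candidate, the lexicographically-first path is taken, reconstructed
  greedily from the precomputed distance matrix. This makes runs
  reproducible while keeping the target choice stochastic.
* **Every intermediate edge of a multi-edge relocation is counted once.**
  The alternative — crediting only the endpoints — would disconnect the
  frequency network from the traversal process and break the conservation
  identity (sum of counts = total traversals) that the tests verify
  exactly.
* **MRNETB.** The MRMR objective `J(S,Y) = sum relevance − mean pairwise
  redundancy`, backward elimination from all positive-relevance
  predictors, then sequential replacement. Two details are deliberate:
  removals that leave J unchanged are accepted (so fully irrelevant
  predictor sets collapse to the empty set, and an all-zero MI matrix
  yields an empty network), and the per-direction relevance-minus-
  redundancy edge scores are clamped at zero so the output is a valid
  nonnegative similarity network. Backward elimination plus
  size-preserving swaps is a *local* search: it provably contains every
  edge of the exhaustive MRMR optimum on the small instances we test, but
  can retain extra edges at redundant local optima — from the full
  predictor set no single removal may improve J, and no swap exists. This
  is a property of the published schedule itself, not of this
  implementation.
* **MI conventions.** Estimates are in nats; small negative kNN estimates
  (possible for independent pairs) are clamped at zero; the diagonal is
  zero by convention; constant rows under the Gaussian estimator get MI 0
  with a warning rather than NaN.

# Numerical details

Shortest paths under `inverse_weight` use edge length `1/max(w, 1e-12)` so
zero-weight edges (possible after MRNETB clamping) act as near-infinite
distances instead of dividing by zero. Path reconstruction accepts a
neighbour as on-path when `|len + d(y,t) − d(x,t)| <= 1e-9 * max(1, d)`;
candidate-distance ties use a relative `1 + 1e-12` band. Duplicate edges in
input edge lists must agree within `1e-9`; the TSV writer emits 10
significant digits so write-read round-trips are stable under these
tolerances. The walk engine precomputes the all-pairs distance matrix and
an edge-id lookup, both O(N²) memory — the intended regime is desk-scale
networks (N up to a few thousand), not the ~10⁷-edge scale of full
transcriptome networks, which the engine's contracts (per-walker streams,
additive count accumulation) are nonetheless designed to survive.

Degenerate inputs: a disconnected network is an error in
`connectivity_filter()` (take the largest component first) and a warning in
`run_informed_walks()` (walkers cannot leave their component);
`centrality_rankings()` swaps closeness for harmonic centrality on
disconnected graphs and flags it; gene sets emptied by restriction are
dropped with a warning, and an entirely empty restriction is an error
because no informed move is possible.

# The synthetic study system

`generate_expression()` plants co-expressed modules with the one-factor
model `x_i = sqrt(r) f + sqrt(1−r) e_i`, giving expected within-module
Pearson correlation exactly `r` with a single parameter.
`generate_gene_sets()` builds a pathway collection in which a stated
fraction of pathways are supersets of planted modules and the remaining
pathways chain through a fixed member-overlap fraction, so the pathway
graph is connected by construction whenever the overlap is positive.
`generate_walk_network()` provides scale-free and small-world topologies
plus `planted_dense_blocks`: high-weight cliques joined to a sparse
low-weight background — the dense-neighbourhood entrapment scenario the
Lévy mechanism targets.

What the generators deliberately do *not* emulate: empirical expression
marginals, batch or library-size effects, realistic pathway-size
distributions, or transcriptome-scale networks. Green tests therefore
demonstrate algorithmic correctness (conservation, closure, oracle
agreement, branch calibration, module recovery at desk scale), not
biological performance on real cohorts.

Problem sizes used by the test-suite study conditions, chosen as the
smallest instances at which each property is informative: oracle suites on
4–20-node graphs (where exhaustive enumeration is exact), MI calibration
at 2000 samples against the Gaussian closed form, conservation over 100
random sub-40-gene configurations, branch calibration over 10⁵
transitions, and module-enrichment runs on 300-gene block networks with
50 walkers × 200 iterations across 10 seeds (a scaled-down analogue of the
published 300 × 1000 operating point).

# Known limitations

* The Lévy sub-model (exponent, trigger, cap, greedy semantics) is an
  interpretation; different choices change how often walkers escape dense
  regions, though all are configurable.
* MRNETB inherits the local-optimum behaviour discussed above.
* Gene identifiers are matched as exact, case-sensitive strings; no alias
  or identifier mapping is attempted, and `restrict_to_network()` reports
  the per-pathway retained fractions so mismatches surface rather than
  silently shrinking the map.
* The O(N²) distance precomputation trades memory for per-round speed and
  caps practical network size; swapping in on-demand single-source
  shortest paths is the natural extension for larger graphs.
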