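# informedwalks

Pathway-informed random walks with restarts and Lévy flights over gene
co-expression networks, for highlighting disease-relevant gene subnetworks.

## The problem and the model

Plain random walks on a co-expression network report little more than the
network's topology, and tend to get trapped in dense neighbourhoods. This
package implements *informed walks*: walkers move on a mutual-information
co-expression network, but their moves are steered by an auxiliary
**pathway map** — a graph whose nodes are pathways and whose edges connect
pathways sharing genes, weighted by the shared-gene count.

Each of `n_walkers` independent walkers (restarts; default 300) starts at a
uniformly random gene and pathway and performs `n_iterations` rounds
(default 1000). Every round:

1. **Lévy decision.** A step length *s* is drawn from a discrete power law
   P(s) ∝ s^−μ (default μ = 2) on {1, …, ⌈√N⌉}. If s ≥ ⌈ln N⌉, the walker
   takes *s* greedy maximum-weight steps (avoiding within-flight revisits),
   a heavy-tailed jump that escapes dense neighbourhoods. N is the number
   of genes in the network.
2. **Informed step** (when the flight is a no-op). The walker finds the
   members of its current pathway in the network and relocates along the
   full shortest path (edge length 1/w, so strong association = short
   distance) to the nearest member. The current pathway then updates by a
   Monte-Carlo decision: with 70% probability the next pathway is sampled
   among pathway-graph neighbours proportionally to the shared-gene count;
   with 30% probability it is sampled uniformly over all pathways —
   possibly one sharing no genes with the current one, or the same pathway
   again.

Every edge any walker traverses is counted. The accumulated counts form the
**passage-frequency network**, and the top-K edges (K = 500 by default)
induce the highlighted subnetwork of prioritised genes.

Upstream, the co-expression network itself is reconstructed from an
expression matrix: pairwise mutual information (Kraskov–Stögbauer–
Grassberger k-nearest-neighbour estimator, in nats), **MRNETB**
maximum-relevance minimum-redundancy edge selection (backward elimination
plus sequential replacement), and a connectivity-preserving filter that
keeps only edges at or above the largest threshold for which the network
still spans all genes as one component (the maximum-spanning-tree
bottleneck). Downstream, degree / betweenness / closeness rankings provide
the conventional centrality baseline, and overlap analysis reports common
and exclusive genes across subnetworks.

All randomness flows through seeded, per-walker L'Ecuyer-CMRG streams:
results are byte-reproducible and invariant to walker execution order.

## Worked example

Everything below runs on synthetic data with known ground truth: a
300-gene network with two planted 25-gene high-weight modules, and a
10-pathway collection in which 40% of pathways wrap the planted modules.

```r
library(informedwalks)

net <- generate_walk_network(300, "planted_dense_blocks", seed = 1)
blocks <- attr(net, "blocks")                    # ground-truth modules

spec <- synth_spec(n_genes = 300, n_modules = 2, module_size = 25,
                   n_pathways = 10, pathway_size_range = c(10, 20),
                   pathway_overlap_fraction = 0.5,
                   fraction_pathways_aligned_to_modules = 0.4, seed = 1)
gs <- generate_gene_sets(spec, modules = dplyr::rename(blocks, module = block))

run <- run_informed_walks(net, gs$sets,
                          walk_config(n_walkers = 50, n_iterations = 200,
                                      seed = 1))
run
#> Informed walks: 50 walkers x 200 iterations, 28752 traversals over 465 edges (300 nodes)

glance(run)
#>   n_walkers n_iterations total_traversals n_edges_traversed n_flights informed_fraction
#> 1        50          200            28752               465       840         0.6959607

head(tidy(run), 5)
#>   from  to    count
#> 1 G043  G257   1153
#> 2 G043  G170   1094
#> 3 G164  G215   1084
#> 4 G050  G192   1072
#> 5 G154  G238   1065
```

`informed_fraction` is the realised share of pathway transitions resolved
by the informed (shared-gene) branch — close to the configured 0.7. The
top-count edges concentrate inside the planted modules; extracting the
top-100 subnetwork and testing the induced genes against the planted
module genes:

```r
sub <- top_k_edges(run$frequency, k = 100)
nodes <- subnetwork_nodes(sub)
q <- length(intersect(nodes, blocks$gene))
phyper(q - 1, nrow(blocks), 300 - nrow(blocks), length(nodes),
       lower.tail = FALSE)
#> 9.48e-12      (89 induced genes, 36 of them from the planted modules)
```

so the walkers enrich the planted modules far beyond the uniform-sampling
expectation. `autoplot(run)` shows the heavy-tailed passage-count
distribution with the top-K cut marked.

A command-line wrapper over the same functions ships at
`inst/cli/informedwalks.R` (subcommands `synth`, `infer`, `filter`, `walk`,
`topk`, `overlap`, `centrality`, `signature`), writing a JSON run manifest
per invocation; `iw_main()` is the same entry point as an R function.

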