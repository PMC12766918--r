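# netkin

Annotation of undirected networks by community detection and
overrepresentation analysis — for systems biologists (and network
scientists generally) who have a graph (a protein–protein or genetic
interaction network, a citation network, ...) and a term→members table
(GO Biological Process, CORUM, KEGG, or any flat gene-set collection) and
want to know **which regions of the network are enriched for which
functions**, with publication-ready contour-overlay figures.

## What it computes

1. **Communities.** Louvain (seeded multi-restart), label propagation,
   greedy modularity agglomeration, and Markov Clustering natively;
   Leiden, Walktrap and Spinglass through a pluggable backend registry.
   All partitions are canonical (cluster ids `0..k-1` by smallest member)
   and deterministic for a fixed seed. Modularity with resolution:

   *Q* = Σ<sub>c</sub> [ e<sub>c</sub>/m − γ (d<sub>c</sub>/2m)² ]

2. **Overrepresentation.** For every (cluster, term) pair with counts
   k (annotated in cluster), n (cluster size), K (annotated in universe),
   N (universe size): hypergeometric tail P(X ≥ k), binomial tail,
   one-sided Pearson chi-squared, or a permutation test under the
   node-label-shuffle null with the add-one estimator
   p = (1 + #{k<sub>r</sub> ≥ k<sub>obs</sub>})/(1 + R). All R permutations
   are evaluated for **all** pairs in one sparse vectorized pass
   (O(R·nnz); no dense N×T×R array), which is what lets the chi-squared
   and hypergeometric paths scale to networks of 500 000 edges. BH,
   Bonferroni or no multiple-testing correction.

3. **Domains.** Clusters with at least one term below α are retained and
   labelled by their best terms; a shared-node rule counts the "unique"
   clusters that survive removing nodes claimed by several significant
   clusters.

4. **Evaluation.** Compactness (mean pairwise member distance),
   separation (minimum centroid distance) and silhouette scores on a
   seeded 2-D layout, plus an exact/tie-corrected Mann–Whitney U test for
   comparing two clusterings.

5. **Synthetic benchmarks.** Scale-free networks with exactly 2n − 3
   edges at m = 2 (twice as many edges as nodes), heavy-tailed null
   annotation tables (1000 terms, power-law sizes), and a planted
   stochastic-block-model fixture with coherent signal terms for
   ground-truth recovery tests.

## Worked example

```r
library(netkin)

pl   <- gen_planted(seed = 42)          # 4 blocks x 25 nodes, signal terms
net  <- pl$network
part <- louvain(net, seed = 42)
part
#> <netkin_partition> 100 nodes in 4 clusters (louvain)

tab <- run_overrep(pl$annotations, part, test = "hypergeom", correction = "bh")
head(tab[order(tab$adj_p), c("cluster","term","k","n","K","N","p","adj_p")], 5)
#>    cluster          term  k  n  K   N        p    adj_p
#> 17       0 signal_block0 20 25 20 100 9.91e-17 1.98e-15
#> 38       1 signal_block1 20 25 20 100 9.91e-17 1.98e-15
#> 59       2 signal_block2 20 25 20 100 9.91e-17 1.98e-15
#> 80       3 signal_block3 20 25 20 100 9.91e-17 1.98e-15
#> 12       0       decoy12  6 25  9 100 7.03e-03 1.13e-01

dm <- build_domains(tab, alpha = 0.01)
dm
#> <netkin_domains> 4 significant cluster(s) at alpha = 0.01
#>   cluster 0: signal_block0 (p = 1.98e-15)
#>   ...
unique_clusters(dm, part, pl$annotations)
#> [1] 0 1 2 3

xy <- layout_coords(net, seed = 42)
evaluate_partition(xy, part)
#> <netkin_eval> 4 clusters; mean compactness = 1.496, separation = 4.287, silhouette = 0.6324
modularity_score(net, part)
#> [1] 0.6499

render_network(net, xy, dm, part, plot_spec(format = "svg"), "figure.svg")
```

Each of the four planted blocks is recovered as one cluster; its signal
term (which covers 20 of the block's 25 nodes, and 20 nodes network-wide)
has the smallest possible overlap p-value, while the best decoy term stays
two orders of magnitude behind and is discarded by the BH-adjusted 0.01
threshold. The silhouette (~0.63) reflects well-separated modules in the
spring embedding; numbers of this kind are layout-seed-dependent and are
always reported together with their seed.

The full pipeline — import, cluster, test, label, evaluate, render, plus a
provenance manifest — is one call, `run_pipeline(run_config(...))`, or one
shell command via the thin CLI wrapper:

```sh
Rscript inst/cli/netkin.R run --config run.yaml
```

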