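---
title: "netkin: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{netkin: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netkin)
```

# Overview

`netkin` annotates undirected networks by (i) detecting communities, (ii)
testing every (cluster, term) pair of a node-by-term annotation table for
overrepresentation, (iii) filtering and labelling the significant clusters,
(iv) scoring clustering quality on a 2-D embedding, and (v) rendering the
result with kernel-density contour overlays. A synthetic benchmark module
generates scale-free networks and heavy-tailed annotation tables so that the
whole pipeline — including its statistical calibration — is testable without
any external data.

This vignette records the statistical model behind each stage, the defaults
and why they were chosen, the numerical conventions, and the limitations a
user should know about.

# The canonical network

All inputs (Cytoscape JSON, edge lists, GraphML, serialized objects) are
normalized to one canonical form: node identifiers sorted in C-locale order,
self-loops dropped, parallel and anti-parallel edges collapsed with weights
summed, directed inputs symmetrized. Symmetrization rather than rejection is
deliberate: citation-style networks are directed, but community membership
and overrepresentation are questions about mutual association, for which an
edge in either direction is evidence. Every downstream matrix — annotation
membership, cluster indicators — derives its row order from the canonical
node order, which is what makes results bit-reproducible across input
orderings and locales.

# Community detection

The modularity of a partition $c$ at resolution $\gamma$ is

$$Q = \sum_c \left[ \frac{e_c}{m} - \gamma\left(\frac{d_c}{2m}\right)^2 \right]$$

with $e_c$ the intra-cluster edge mass, $d_c$ the total strength of the
cluster's nodes, and $m$ the total edge weight. `modularity_score()`
implements this directly (and the test suite cross-checks it against an
independent implementation on random weighted graphs at several $\gamma$).

* **Louvain** (`louvain()`): multi-level local moves and aggregation. A
  single pass is sensitive to the node visit order, so the function runs
  `nstart = 5` seeded restarts and keeps the best-$Q$ partition; on tiny
  random graphs where the global optimum can be found by enumerating all
  partitions, a single pass matches the optimum roughly 84% of the time and
  five restarts roughly 94%. The restart count, resolution and seed are
  recorded in the returned partition.
* **Label propagation**: each node adopts the plurality label among its
  neighbours until a fixed point; seeded update order gives reproducibility.
  Labels cannot cross disconnected components.
* **Greedy modularity** (`greedy_modularity()`): agglomerative merging while
  the best merge gain $\Delta Q = 2(e_{ab} - \gamma a_a a_b)$ is positive,
  with ties broken by the smallest cluster-id pair. This native
  implementation exists chiefly because it must honour the resolution
  parameter; its dense bookkeeping makes it suitable for networks up to a
  few thousand nodes, not for the largest inputs.
* **Markov Clustering** (`markov_clustering()`): the transition matrix of
  the graph with unit self-loops is column-normalized, then expansion
  (matrix power, default 2) and inflation (entrywise power, default 2,
  followed by renormalization) alternate until the iterate is stable.
  Entries below `prune_threshold` ($10^{-5}$) are dropped each round to
  preserve sparsity; convergence is declared when the successive max-abs
  difference falls below `tol` ($10^{-8}$), and non-convergence within
  `max_iter` is an error that reports the last residual. Rows with positive
  diagonal (attractors) define cluster supports; attractors that attract
  each other are merged into one attractor system, and a node supported by
  several systems is assigned to the lowest cluster id (reported via a
  message). Larger inflation sharpens flow and can only fragment clusters,
  never merge them.
* **Leiden, Walktrap, Spinglass** are dispatched through a backend registry
  (`register_cluster_backend()`); default backends ship, and deregistering
  one turns the algorithm into an informative capability error. ForceAtlas2
  layout uses the same mechanism.

Every algorithm returns the same canonical partition object: contiguous
cluster ids `0..k-1` numbered by each cluster's smallest node id, so
partition equality is insensitive to the order in which an algorithm emits
communities.

# Overrepresentation statistics

For a cluster of size $n$ and a term annotating $K$ of the $N$ universe
nodes, with $k$ annotated nodes inside the cluster, the 2×2 table is
$a = k$, $b = n-k$, $c = K-k$, $d = N-n-K+k$. The universe defaults to all
network nodes; `universe = "annotated"` restricts it to nodes carrying at
least one membership (both conventions are used in the enrichment
literature; the choice is recorded with the matrix).

* **Hypergeometric**: $p = P(X \ge k)$, $X \sim \mathrm{Hyp}(N, K, n)$ —
  the exact tail under sampling without replacement.
* **Binomial**: upper tail of $\mathrm{Bin}(n, K/N)$ — the
  with-replacement approximation.
* **Chi-squared**: Pearson statistic on the 2×2 table, one degree of
  freedom, no continuity correction. The enrichment-direction p is the
  full upper $\chi^2_1$ tail when $ad > bc$, and 1 otherwise; note the
  full tail is reported (not halved), so mild positive association can
  yield $p > 0.5$ even though the direction flag is positive. Degenerate
  tables (a zero margin) return stat 0, p 1 with a warning.
* **Permutation**: the null is a uniform shuffle of the annotation
  matrix's node rows, which preserves every term size and every cluster
  size and makes the single-pair null distribution exactly hypergeometric
  — a property the tests exploit by requiring the Monte-Carlo p to fall
  within three standard errors of the analytic tail. The estimator is
  add-one, $p = (1 + \#\{k_r \ge k_{obs}\})/(1+R)$, so p is never zero.
  All $R$ shuffles are evaluated for **all** clusters and terms in one
  sparse pass (`t(C) %*% A[perm, ]` per replicate): total work scales with
  $R \cdot \mathrm{nnz}(A)$ and no dense $N \times T \times R$ array ever
  exists. A naive per-pair loop over the identical permutation stream
  reproduces the vectorized results bit-exactly, which is asserted in the
  tests.

Multiple testing is corrected across all (cluster, term) pairs with
Benjamini–Hochberg by default; `correction = "none"` reproduces the
raw-threshold convention ($p < .01$) used in permutation-test reports, and
Bonferroni is available. Depletion (lower-tail) p-values are computed on
request and off by default.

## Discreteness and conservativeness

Exact tests on discrete tables are conservative: $P(p < \alpha) \le \alpha$
with strict inequality whenever $\alpha$ falls between two attainable tail
values. With heavy-tailed term sizes (many terms of size 5–10) this gap is
large — under the package's null benchmark the attained rate of
"$p < 0.05$" is near 0.023, not 0.05. The calibration test therefore
compares the observed significant-pair rate against the *exact attained
level*, computed analytically from the hypergeometric mass function per
pair, rather than against the nominal $\alpha$; the nominal-level check is
also present and documents this conservativeness. Users comparing tools
should be aware that a correct exact test *should* sit below the nominal
false-positive rate.

# Significant domains

`build_domains()` keeps clusters with at least one term below `alpha`
(default 0.01 on the adjusted p, matching the common raw-permutation
threshold when no correction is applied) and labels each with its `top_k`
best terms, ties broken by term id so labels are reproducible. The
"unique cluster" count removes nodes claimed by two or more significant
clusters before deciding whether a cluster retains at least
`min_remaining` members. Because hard partitions are disjoint, the default
node sets are the network members of each cluster's significant terms —
which can overlap across clusters — while `mode = "partition"` applies the
plain rule to the cluster node sets themselves, the natural choice for
externally supplied, possibly overlapping clusterings.

# Evaluation metrics

All quality metrics operate on 2-D layout coordinates: compactness (mean
pairwise member distance, singleton clusters 0 by convention), separation
(minimum centroid distance), and silhouette
($s_i = (b_i - a_i)/\max(a_i, b_i)$, with $s_i = 0$ for singletons and
coincident points). They are invariant under rigid motions; compactness and
separation scale linearly with the coordinates and silhouette is
scale-free. Because the metrics depend on the embedding, the layout seed is
part of any reported number — silhouettes from different layout seeds are
not comparable, which is also why published silhouette values for specific
datasets cannot be pinned without the original embedding.

Two clusterings are compared with a Mann–Whitney U test on their
per-cluster compactness distributions. The p-value is exact (enumeration)
for pooled samples of at most 12 without ties, and otherwise uses the
normal approximation with the standard tie-corrected variance and no
continuity correction; fully tied samples return $U = n_x n_y / 2$, $p = 1$.

# The synthetic benchmark

`gen_scale_free(n, m = 2)` grows a preferential-attachment graph in which
node $i$ joins with $\min(m, i-1)$ edges, so the edge count is the closed
form $2n - 3$ — matching the design of benchmarking on scale-free networks
with twice as many edges as nodes. `gen_annotations()` draws term sizes
i.i.d. from a discrete power law (exponent 1.5, truncated to $[5, n/10]$ by
default) to emulate GO-Biological-Process-like membership distributions,
then fills terms uniformly at random, independent of topology: a pure null
model. The exponent and range are package defaults, stated rather than
fitted — real GO term-size distributions vary by organism and annotation
release, and the law is pluggable (`law = "lognormal"` included).

`gen_planted()` produces the ground-truth fixture: a stochastic block model
(default 4 blocks × 25 nodes, $p_{in} = 0.5$, $p_{out} = 0.02$) with one
signal term per block covering a seeded 80% subset, plus heavy-tailed decoy
terms. This fixture drives the recovery tests (adjusted Rand index of
Louvain and MCL against the planted blocks; BH-adjusted significance of the
four signal pairs).

What the generator deliberately does **not** emulate: degree-annotation
correlation (hub proteins are better annotated in real data), overlapping
or nested terms (GO is a DAG), assortativity and clustering-coefficient
structure beyond preferential attachment, and edge-weight heterogeneity.
Passing the calibration and recovery tests therefore shows the machinery is
correct under an idealized null and a strong planted signal; it does not
certify performance on any particular biological network.

Problem sizes used by the shipped tests were chosen to exercise each
contract at the smallest scale that is statistically meaningful: the null
calibration uses 2000-node networks with 1000 terms across 50 seeds, the
recovery benchmark 100 seeded replicates of the 100-node fixture, and one
scalability exercise runs the chi-squared path on a 250 000-node /
500 000-edge network with 1000 terms to demonstrate the sparse contract at
the scale the statistical module is designed for.

# Visualization

Layouts use seeded Fruchterman–Reingold embeddings (deterministic per
seed). Contours are Gaussian-KDE iso-density lines: per significant
cluster, a product-kernel density with Scott's bandwidth
($h_j = \hat\sigma_j n^{-1/6}$) is evaluated at the member points, the
density threshold is the $(1 - \mathrm{level})$ sample quantile of those
member densities (default level 0.67, so the contour encloses at least 67%
of members), and the iso-line is traced on an 80×80 grid padded by three
bandwidths. Clusters with fewer than three members or degenerate geometry
(coincident or collinear points) fall back to a buffered circle or capsule.
Domain colors follow palette order over cluster ids, cycling with a
brightness shift when domains outnumber colors; non-significant nodes are
grey. SVG output is byte-reproducible for identical inputs, which the
pipeline's determinism guarantee relies on.

# Pipeline and provenance

`run_pipeline()` validates its whole configuration before any stage runs
(unknown keys are errors), then chains the stages and writes
`partition.tsv`, `overrep.tsv`, `domains.tsv`, `report.json`, the figure,
and a manifest recording the configuration, seeds, package version and
input checksums. Any stage failure aborts with the stage name. Rerunning
one configuration reproduces the deterministic artifacts checksum-for-
checksum. A thin command-line wrapper (`inst/cli/netkin.R`) exposes each
stage and the one-shot `run` as subcommands.

# Known limitations

* Greedy modularity is dense and intended for small networks; use Louvain
  or MCL at scale.
* The permutation test's single-pair null equals the hypergeometric tail —
  its value over the analytic test lies in settings (weighted statistics,
  non-uniform nulls) beyond the uniform node-label shuffle shipped here.
* Silhouette/compactness/separation are embedding-dependent by design;
  graph-distance variants are out of scope.
* Annotation terms are flat sets; ontology ancestor propagation, if
  desired, must be applied before import.
* Spinglass requires a connected graph (a backend restriction surfaced as
  an error).
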