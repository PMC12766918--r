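test_that("modularity matches hand-derived values and igraph", {
  net <- two_k4_bridge()
  one <- as_partition(stats::setNames(rep(0, 8), net$nodes))
  expect_equal(modularity_score(net, one), 0)

  cliques <- as_partition(stats::setNames(rep(c(0, 1), each = 4),
                                          c(paste0("a", 1:4), paste0("b", 1:4))))
  expect_equal(modularity_score(net, cliques), 12 / 13 - 1 / 2, tolerance = 1e-12)

  tri <- make_network(data.frame(from = c("x", "y", "z"), to = c("y", "z", "x")))
  singletons <- as_partition(stats::setNames(0:2, c("x", "y", "z")))
  expect_equal(modularity_score(tri, singletons), -1 / 3, tolerance = 1e-12)

  expect_error(modularity_score(make_network(NULL, nodes = c("A", "B")), one),
               "empty")

  # cross-check against igraph on random weighted graphs, incl. resolution
  for (s in 1:5) {
    set.seed(s)
    g <- igraph::sample_gnp(20, 0.2)
    igraph::E(g)$weight <- runif(igraph::ecount(g), 0.5, 2)
    igraph::V(g)$name <- sprintf("v%02d", 1:20)
    net <- from_igraph(g)
    memb <- sample(0:3, 20, replace = TRUE)
    part <- as_partition(stats::setNames(memb, igraph::V(g)$name))
    for (gamma in c(0.5, 1, 2)) {
      expect_equal(modularity_score(net, part, gamma),
                   igraph::modularity(g, part$assignment[igraph::V(g)$name] + 1,
                                      weights = igraph::E(g)$weight,
                                      resolution = gamma),
                   tolerance = 1e-12)
    }
  }
})

test_that("louvain finds components and the two-clique optimum, deterministically", {
  net <- two_triangles()
  p <- louvain(net, seed = 7)
  expect_equal(p$k, 2L)
  expect_length(unique(p$assignment[c("a", "b", "c")]), 1L)

  net2 <- two_k4_bridge()
  p2 <- louvain(net2, seed = 7)
  expect_equal(modularity_score(net2, p2), 12 / 13 - 1 / 2, tolerance = 1e-12)

  expect_identical(louvain(net2, seed = 3)$assignment,
                   louvain(net2, seed = 3)$assignment)
  expect_error(louvain(make_network(NULL, nodes = "A")), "empty")
})

test_that("louvain Q dominates the singleton partition on random graphs", {
  for (s in 1:5) {
    set.seed(s)
    g <- igraph::sample_gnp(30, 0.15)
    igraph::V(g)$name <- sprintf("v%02d", 1:30)
    g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0))
    net <- from_igraph(g)
    p <- louvain(net, seed = s)
    singles <- as_partition(stats::setNames(seq_along(net$nodes), net$nodes))
    expect_gte(modularity_score(net, p), modularity_score(net, singles))
  }
})

test_that("louvain reaches the brute-force optimum on most tiny graphs", {
  hits <- 0L; total <- 0L
  for (s in 1:10) {
    set.seed(s)
    g <- igraph::sample_gnp(8, 0.35)
    if (igraph::ecount(g) == 0) next
    igraph::V(g)$name <- sprintf("v%d", 1:8)
    net <- from_igraph(g)
    best <- max(vapply(all_partitions(8), function(rgs) {
      modularity_score(net, as_partition(stats::setNames(rgs, net$nodes)))
    }, 0))
    q <- modularity_score(net, louvain(net, seed = s))
    total <- total + 1L
    if (q >= best - 1e-12) hits <- hits + 1L
  }
  expect_gte(hits / total, 0.9)
})

test_that("label propagation respects components and stars collapse", {
  p <- label_propagation(two_triangles(), seed = 1)
  expect_equal(p$k, 2L)

  ps <- label_propagation(star_k15(), seed = 5)
  expect_equal(ps$k, 1L)

  # plurality condition at convergence, and no cluster spans components
  for (s in 1:5) {
    set.seed(s)
    g <- igraph::sample_gnp(25, 0.12)
    igraph::V(g)$name <- sprintf("v%02d", 1:25)
    g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0))
    net <- from_igraph(g)
    p <- label_propagation(net, seed = s)
    comp <- igraph::components(as_igraph(net))$membership
    expect_true(all(tapply(comp[net$nodes], p$assignment[net$nodes],
                           function(x) length(unique(x))) == 1))
    adj <- igraph::as_adj_list(as_igraph(net))
    for (i in seq_along(net$nodes)) {
      labs <- p$assignment[names(adj[[i]])]
      if (length(labs) == 0) next
      counts <- table(labs)
      expect_true(counts[as.character(p$assignment[net$nodes[i]])] == max(counts))
    }
  }
})

test_that("greedy modularity agglomerates to the clique split", {
  expect_equal(greedy_modularity(two_triangles())$k, 2L)
  net <- two_k4_bridge()
  p <- greedy_modularity(net)
  expect_equal(modularity_score(net, p), 12 / 13 - 1 / 2, tolerance = 1e-12)
  expect_gte(modularity_score(net, p), 0)
})

test_that("MCL resolves components, pairs, and coarsens with lower inflation", {
  p <- markov_clustering(two_triangles())
  expect_equal(p$k, 2L)
  comp_a <- p$assignment[c("a", "b", "c")]
  expect_length(unique(comp_a), 1L)

  pair <- make_network(data.frame(from = "A", to = "B"))
  expect_equal(markov_clustering(pair)$k, 1L)

  ks <- vapply(c(1.5, 2, 4),
               function(r) markov_clustering(barbell(), inflation = r)$k, 0L)
  expect_true(all(diff(ks) >= 0))   # inflation never decreases cluster count

  expect_error(markov_clustering(pair, inflation = 1), "inflation")
  expect_error(markov_clustering(pair, expansion = 1), "expansion")
})

test_that("partitions are exhaustive, disjoint and canonically numbered", {
  net <- gen_scale_free(80, 2, seed = 2)
  for (alg in c("louvain", "labelprop", "greedy", "mcl")) {
    p <- cluster_network(net, alg, seed = 9)
    expect_setequal(names(p$assignment), net$nodes)
    expect_equal(sort(unique(unname(p$assignment))), 0:(p$k - 1))
    expect_true(all(cluster_sizes(p) > 0))
    # cluster id 0 must contain the lexicographically first node
    expect_equal(unname(p$assignment[net$nodes[1]]), 0L)
  }
})

test_that("dispatch is identity for natives and errors are informative", {
  net <- two_k4_bridge()
  expect_identical(cluster_network(net, "louvain", seed = 4)$assignment,
                   louvain(net, seed = 4)$assignment)
  expect_error(cluster_network(net, "density-peaks"), "unknown algorithm")

  old <- register_cluster_backend("spinglass", NULL)
  withr::defer(register_cluster_backend("spinglass", old))
  expect_error(cluster_network(net, "spinglass"), "native algorithms")
})

test_that("delegated backends produce valid partitions", {
  net <- gen_planted(seed = 3)$network
  for (alg in c("leiden", "walktrap", "spinglass")) {
    p <- cluster_network(net, alg, seed = 5)
    expect_setequal(names(p$assignment), net$nodes)
    expect_gte(p$k, 2L)
  }
})
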