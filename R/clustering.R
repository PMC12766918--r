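#' Newman-Girvan modularity with resolution
#'
#' Computes \eqn{Q = \sum_c \left[\frac{e_c}{m} - \gamma\left(\frac{d_c}{2m}\right)^2\right]}
#' where \eqn{e_c} is the total (weighted) edge mass inside cluster c,
#' \eqn{d_c} the total strength of its nodes, and m the total edge weight.
#' This is the objective optimized by the Louvain and greedy algorithms;
#' `gamma` rescales the degree-preserving null term (resolution).
#'
#' @param net a `netkin_network` with at least one edge
#' @param part a `netkin_partition` covering all nodes
#' @param gamma resolution parameter (default 1)
#' @return Q in `[-1, 1]`
#' @export
modularity_score <- function(net, part, gamma = 1) {
  stopifnot(inherits(net, "netkin_network"), inherits(part, "netkin_partition"))
  if (nrow(net$edges) == 0) stop("modularity undefined for an empty edge set")
  memb <- part$assignment[net$nodes]
  if (anyNA(memb)) stop("partition does not cover every network node")
  w <- net$edges$weight
  m <- sum(w)
  ci <- memb[net$edges$from]
  cj <- memb[net$edges$to]
  intra <- sum(w[ci == cj]) / m
  strength <- rowsum(c(w, w), c(net$edges$from, net$edges$to))
  d <- stats::setNames(rep(0, length(net$nodes)), net$nodes)
  d[rownames(strength)] <- strength[, 1]
  dc <- rowsum(unname(d), unname(memb))
  intra - gamma * sum((dc / (2 * m))^2)
}

check_nonempty <- function(net) {
  stopifnot(inherits(net, "netkin_network"))
  if (length(net$nodes) == 0) stop("empty graph: no nodes")
  if (nrow(net$edges) == 0) stop("empty graph: no edges")
  invisible(net)
}

#' Louvain community detection
#'
#' Multi-level modularity optimization (local moves + aggregation), run
#' `nstart` times with seed-derived node-visit orders, keeping the partition
#' with the highest Q (first run wins ties). Deterministic for a fixed seed;
#' the resulting Q never falls below the all-singletons partition's Q, since
#' each run starts from singletons and only accepts improving moves. Restarts
#' smooth out the heuristic's dependence on visit order; `nstart = 1`
#' recovers a single greedy pass.
#'
#' @param net a `netkin_network`
#' @param gamma resolution (default 1)
#' @param seed RNG seed controlling node-visit orders
#' @param nstart number of restarts (default 5)
#' @return a `netkin_partition`
#' @export
louvain <- function(net, gamma = 1, seed = 42L, nstart = 5L) {
  check_nonempty(net)
  if (nstart < 1) stop("nstart must be >= 1")
  g <- as_igraph(net)
  w <- igraph::E(g)$weight
  memb <- with_seed(seed, {
    best <- NULL; best_q <- -Inf
    for (i in seq_len(nstart)) {
      m <- igraph::membership(igraph::cluster_louvain(g, resolution = gamma))
      q <- igraph::modularity(g, m, weights = w, resolution = gamma)
      if (q > best_q + 1e-15) { best <- m; best_q <- q }
    }
    best
  })
  as_partition(stats::setNames(as.integer(memb), net$nodes),
               params = list(algorithm = "louvain", gamma = gamma, seed = seed,
                             nstart = nstart))
}

#' Label propagation community detection
#'
#' Each node iteratively adopts the plurality label among its neighbors until
#' no label changes; the seeded update order makes runs reproducible. Labels
#' cannot cross disconnected components.
#'
#' @inheritParams louvain
#' @return a `netkin_partition`
#' @export
label_propagation <- function(net, seed = 42L) {
  check_nonempty(net)
  g <- as_igraph(net)
  memb <- with_seed(seed, igraph::membership(igraph::cluster_label_prop(g)))
  as_partition(stats::setNames(as.integer(memb), net$nodes),
               params = list(algorithm = "labelprop", seed = seed))
}

#' Greedy modularity agglomeration
#'
#' Starts from singleton clusters and repeatedly merges the pair of clusters
#' with the largest positive modularity gain
#' \eqn{\Delta Q = 2(e_{ab} - \gamma a_a a_b)}, stopping when no merge gains.
#' Fully deterministic: ties are broken by the lexicographically smallest
#' (cluster id, cluster id) pair. Intended for small-to-medium networks; the
#' dense pairwise-gain bookkeeping is O(k^2) per merge.
#'
#' @inheritParams louvain
#' @return a `netkin_partition`
#' @export
greedy_modularity <- function(net, gamma = 1) {
  check_nonempty(net)
  n <- length(net$nodes)
  W <- sum(net$edges$weight)
  # E[i, j]: fraction of edge mass between current clusters i, j (i != j)
  i <- match(net$edges$from, net$nodes)
  j <- match(net$edges$to, net$nodes)
  E <- matrix(0, n, n)
  E[cbind(i, j)] <- E[cbind(i, j)] + net$edges$weight / (2 * W)
  E[cbind(j, i)] <- E[cbind(j, i)] + net$edges$weight / (2 * W)
  a <- rowSums(E)
  # cluster id = smallest original node index it contains
  memb <- seq_len(n)
  active <- rep(TRUE, n)
  repeat {
    gain <- 2 * (E - gamma * outer(a, a))
    gain[!active, ] <- -Inf
    gain[, !active] <- -Inf
    gain[lower.tri(gain, diag = TRUE)] <- -Inf
    best <- max(gain)
    if (!is.finite(best) || best <= 0) break
    hits <- which(gain == best, arr.ind = TRUE)
    pick <- hits[order(hits[, 1], hits[, 2])[1], ]  # smallest (i, j) pair
    p <- pick[1]; q <- pick[2]
    E[p, ] <- E[p, ] + E[q, ]
    E[, p] <- E[, p] + E[, q]
    E[p, p] <- 0  # self-mass tracked implicitly via Q, not needed for gains
    a[p] <- a[p] + a[q]
    active[q] <- FALSE
    memb[memb == q] <- p
  }
  as_partition(stats::setNames(memb, net$nodes),
               params = list(algorithm = "greedy", gamma = gamma))
}

#' Markov Clustering (MCL)
#'
#' Classic MCL on the column-stochastic transition matrix of the graph with
#' unit self-loops added: alternate expansion (matrix power `expansion`) and
#' inflation (entrywise power `inflation`, then column renormalization),
#' pruning entries below `prune_threshold`, until the iterate is stable
#' (successive max-abs difference below `tol`, i.e. idempotent within
#' tolerance). Attractor rows (positive diagonal) define cluster supports;
#' attractors that attract each other form one attractor system. Nodes
#' supported by several systems are assigned to the lowest cluster id (a
#' message reports how many); flow cannot cross disconnected components, so
#' clusters never span components. Edge weights are used as transition
#' masses.
#'
#' @param net a `netkin_network`
#' @param inflation entrywise power r > 1 (default 2); larger r gives finer
#'   clusters
#' @param expansion matrix power e >= 2 (default 2)
#' @param prune_threshold entries below this are dropped each iteration
#' @param max_iter iteration cap
#' @param tol convergence tolerance on the max-abs difference
#' @return a `netkin_partition`
#' @export
markov_clustering <- function(net, inflation = 2, expansion = 2L,
                              prune_threshold = 1e-5, max_iter = 100L,
                              tol = 1e-8) {
  check_nonempty(net)
  if (inflation <= 1) stop("inflation must be > 1")
  if (expansion < 2) stop("expansion must be >= 2")
  n <- length(net$nodes)
  M <- network_adjacency(net) + Matrix::Diagonal(n)
  M <- col_normalize(M)
  converged <- FALSE
  resid <- Inf
  for (it in seq_len(max_iter)) {
    Mold <- M
    for (e in seq_len(expansion - 1L)) M <- M %*% Mold
    # inflation
    M <- methods::as(M, "CsparseMatrix")
    M@x <- M@x^inflation
    M <- col_normalize(M)
    # prune tiny entries, renormalize
    M@x[M@x < prune_threshold] <- 0
    M <- Matrix::drop0(M)
    M <- col_normalize(M)
    resid <- max(abs(M - Mold))
    if (resid < tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop("MCL did not converge in ", max_iter,
         " iterations (last residual ", format(resid, digits = 4), ")")

  memb <- mcl_interpret(M)
  as_partition(stats::setNames(memb, net$nodes),
               params = list(algorithm = "mcl", inflation = inflation,
                             expansion = expansion,
                             prune_threshold = prune_threshold, tol = tol,
                             iterations = it))
}

col_normalize <- function(M) {
  M <- methods::as(M, "CsparseMatrix")
  cs <- Matrix::colSums(M)
  if (any(cs == 0)) {
    # restore an absorbing self-loop for emptied columns (can follow pruning)
    zero <- which(cs == 0)
    M <- M + Matrix::sparseMatrix(i = zero, j = zero, x = 1, dims = dim(M))
    cs <- Matrix::colSums(M)
  }
  scale_j <- rep.int(cs, diff(M@p))
  M@x <- M@x / scale_j
  M
}

# hard partition from a converged MCL matrix (column-stochastic, M[i, j] =
# flow from node j into node i)
mcl_interpret <- function(M) {
  n <- nrow(M)
  d <- Matrix::diag(M)
  attractors <- which(d > 0)
  if (length(attractors) == 0) attractors <- seq_len(n)  # degenerate fallback
  # attractor systems: attractors connected through each other's rows/columns
  sub <- M[attractors, attractors, drop = FALSE]
  sub <- (sub + Matrix::t(sub)) > 0
  g <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected", diag = FALSE)
  sys_of_attr <- igraph::components(g)$membership
  # each node joins the system(s) whose attractors receive its flow
  memb <- integer(n)
  overlaps <- 0L
  Mc <- methods::as(M, "CsparseMatrix")
  for (jcol in seq_len(n)) {
    rows <- Mc@i[seq.int(Mc@p[jcol] + 1L, length.out = Mc@p[jcol + 1L] - Mc@p[jcol])] + 1L
    hit <- sys_of_attr[match(intersect(rows, attractors), attractors)]
    if (length(hit) == 0) {
      # no attractor support (numerical edge case): follow the strongest flow
      best <- rows[which.max(Mc@x[seq.int(Mc@p[jcol] + 1L,
                                          length.out = Mc@p[jcol + 1L] - Mc@p[jcol])])]
      hit <- sys_of_attr[match(best, attractors)]
      if (is.na(hit)) hit <- 0L
    }
    uh <- unique(hit)
    if (length(uh) > 1) overlaps <- overlaps + 1L
    memb[jcol] <- min(uh)
  }
  if (any(memb == 0)) memb[memb == 0] <- max(memb) + seq_len(sum(memb == 0))
  if (overlaps > 0)
    message(overlaps, " node(s) attracted by several clusters; ",
            "assigned to the lowest cluster id")
  memb
}

# ---- backend registry for delegated algorithms --------------------------

the_backends <- new.env(parent = emptyenv())

#' Register or remove a clustering backend
#'
#' Algorithms beyond the native set (louvain, labelprop, greedy, mcl) are
#' dispatched through a backend registry. Backends for `leiden`, `walktrap`
#' and `spinglass` are registered at package load. A backend is a
#' `function(net, params)` returning a membership vector named by node id.
#'
#' @param name algorithm name
#' @param fun backend function, or `NULL` to deregister
#' @return invisibly, the previous backend (or `NULL`)
#' @export
register_cluster_backend <- function(name, fun) {
  old <- the_backends[[name]]
  if (is.null(fun)) {
    if (!is.null(old)) rm(list = name, envir = the_backends)
  } else {
    stopifnot(is.function(fun))
    assign(name, fun, envir = the_backends)
  }
  invisible(old)
}

register_default_backends <- function() {
  register_cluster_backend("leiden", function(net, params) {
    g <- as_igraph(net)
    gamma <- params$gamma %||% 1
    seed <- params$seed %||% 42L
    memb <- with_seed(seed, igraph::membership(igraph::cluster_leiden(
      g, objective_function = "modularity", resolution = gamma,
      n_iterations = 3L)))
    stats::setNames(as.integer(memb), net$nodes)
  })
  register_cluster_backend("walktrap", function(net, params) {
    g <- as_igraph(net)
    steps <- params$steps %||% 4L
    memb <- igraph::membership(igraph::cluster_walktrap(g, steps = steps))
    stats::setNames(as.integer(memb), net$nodes)
  })
  register_cluster_backend("spinglass", function(net, params) {
    g <- as_igraph(net)
    if (igraph::components(g)$no > 1)
      stop("spinglass backend requires a connected graph")
    seed <- params$seed %||% 42L
    memb <- with_seed(seed, igraph::membership(igraph::cluster_spinglass(
      g, spins = params$spins %||% 25L)))
    stats::setNames(as.integer(memb), net$nodes)
  })
}

#' Cluster a network
#'
#' Single dispatch front-end over the native algorithms and registered
#' backends; the algorithm name and parameters used are recorded in
#' `Partition$params`.
#'
#' @param net a `netkin_network`
#' @param algorithm one of `"louvain"`, `"labelprop"`, `"greedy"`, `"mcl"`,
#'   `"leiden"`, `"walktrap"`, `"spinglass"`
#' @param ... algorithm parameters (`gamma`, `seed`, `inflation`, ...)
#' @return a `netkin_partition`
#' @export
cluster_network <- function(net, algorithm = "louvain", ...) {
  params <- list(...)
  native <- c("louvain", "labelprop", "greedy", "mcl")
  delegated <- c("leiden", "walktrap", "spinglass")
  if (!algorithm %in% c(native, delegated))
    stop("unknown algorithm '", algorithm, "'; choose one of ",
         paste(c(native, delegated), collapse = ", "))
  if (algorithm %in% native) {
    part <- switch(algorithm,
      louvain = louvain(net, gamma = params$gamma %||% 1,
                        seed = params$seed %||% 42L,
                        nstart = params$nstart %||% 5L),
      labelprop = label_propagation(net, seed = params$seed %||% 42L),
      greedy = greedy_modularity(net, gamma = params$gamma %||% 1),
      mcl = markov_clustering(net,
                              inflation = params$inflation %||% 2,
                              expansion = params$expansion %||% 2L,
                              prune_threshold = params$prune_threshold %||% 1e-5,
                              max_iter = params$max_iter %||% 100L,
                              tol = params$tol %||% 1e-8))
    return(part)
  }
  backend <- the_backends[[algorithm]]
  if (is.null(backend))
    stop("no backend registered for '", algorithm,
         "'; native algorithms: ", paste(native, collapse = ", "))
  memb <- backend(net, params)
  as_partition(memb, params = c(list(algorithm = algorithm), params))
}
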