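#' Canonical undirected network
#'
#' A `netkin_network` stores an undirected, simple, optionally weighted graph
#' in a canonical form: node identifiers sorted in C-locale (radix) order,
#' edges as unordered pairs with `from < to`, parallel edges collapsed with
#' weights summed, and self-loops removed. All downstream matrices (annotation
#' membership, cluster indicators) index rows by this canonical node order, so
#' every result is reproducible independent of input file ordering or locale.
#'
#' @param edges a two- or three-column data.frame (`from`, `to`, optional
#'   `weight`) or a character matrix of endpoint pairs. May be empty.
#' @param nodes optional character vector of node ids; ids appearing only in
#'   `edges` are added automatically. Use this to retain isolated nodes.
#' @param coords optional numeric matrix (columns x, y) with rownames naming
#'   nodes, or a data.frame with columns `node`, `x`, `y`. If supplied it must
#'   cover every node with finite values.
#' @param labels optional named character vector of display labels.
#' @param directed if `TRUE` (or when duplicate reversed pairs are present)
#'   the input is symmetrized: an edge in either direction becomes one
#'   undirected edge, weights of the two directions summed.
#' @return an object of class `netkin_network` with elements `nodes`,
#'   `edges` (data.frame `from`, `to`, `weight`), `coords`, `labels`.
#' @examples
#' net <- make_network(data.frame(from = c("A", "B"), to = c("B", "C")))
#' network_size(net)
#' @export
make_network <- function(edges, nodes = NULL, coords = NULL, labels = NULL,
                         directed = FALSE) {
  if (is.matrix(edges)) edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  } else {
    if (ncol(edges) < 2) stop("edges must have at least two columns (from, to)")
    w <- if (ncol(edges) >= 3) as.numeric(edges[[3]]) else rep(1, nrow(edges))
    if (anyNA(w) || any(w < 0)) stop("edge weights must be non-negative numbers")
    edges <- data.frame(from = as.character(edges[[1]]),
                        to = as.character(edges[[2]]),
                        weight = w, stringsAsFactors = FALSE)
  }

  node_ids <- sort(unique(c(nodes, edges$from, edges$to)), method = "radix")
  if (length(node_ids) == 0 && nrow(edges) == 0 && is.null(nodes))
    stop("network has no nodes")

  loop <- edges$from == edges$to
  if (any(loop)) {
    warning(sum(loop), " self-loop(s) dropped during normalization")
    edges <- edges[!loop, , drop = FALSE]
  }

  # unordered pairs: orient from < to in canonical node order, then collapse
  # duplicates summing weight (integer pair keys keep this fast at 10^6 edges)
  if (nrow(edges) > 0) {
    i <- match(edges$from, node_ids)
    j <- match(edges$to, node_ids)
    lo <- pmin(i, j); hi <- pmax(i, j)
    key <- (lo - 1) * length(node_ids) + hi  # exact as double for n < 2^26
    ord <- order(key)
    key <- key[ord]
    w <- edges$weight[ord]
    first <- !duplicated(key)
    grp <- cumsum(first)
    wsum <- as.vector(rowsum(w, grp, reorder = TRUE))
    ukey <- key[first]
    ulo <- (ukey - 1) %/% length(node_ids) + 1
    uhi <- (ukey - 1) %% length(node_ids) + 1
    edges <- data.frame(from = node_ids[ulo], to = node_ids[uhi],
                        weight = wsum, stringsAsFactors = FALSE)
    rownames(edges) <- NULL
  }

  net <- structure(list(nodes = node_ids, edges = edges,
                        coords = NULL, labels = NULL),
                   class = "netkin_network")
  if (!is.null(coords)) net <- set_coords(net, coords)
  if (!is.null(labels)) {
    labels <- labels[intersect(names(labels), node_ids)]
    net$labels <- labels
  }
  net
}

#' @export
print.netkin_network <- function(x, ...) {
  cat("<netkin_network> ", length(x$nodes), " nodes, ", nrow(x$edges),
      " edges", if (!is.null(x$coords)) ", with coordinates", "\n", sep = "")
  invisible(x)
}

#' Node and edge counts
#' @param net a `netkin_network`
#' @return named integer vector `c(nodes =, edges =)`
#' @export
network_size <- function(net) {
  stopifnot(inherits(net, "netkin_network"))
  c(nodes = length(net$nodes), edges = nrow(net$edges))
}

#' Attach 2-D coordinates to a network
#'
#' @param net a `netkin_network`
#' @param coords numeric matrix (two columns) with rownames naming nodes, or a
#'   data.frame with columns `node`, `x`, `y`. Must cover every node; all
#'   values finite.
#' @return the network with `$coords` set (matrix in canonical node order).
#' @export
set_coords <- function(net, coords) {
  stopifnot(inherits(net, "netkin_network"))
  if (is.data.frame(coords)) {
    if (!all(c("node", "x", "y") %in% names(coords)))
      stop("coords data.frame needs columns node, x, y")
    m <- cbind(x = as.numeric(coords$x), y = as.numeric(coords$y))
    rownames(m) <- as.character(coords$node)
    coords <- m
  }
  if (is.null(rownames(coords))) stop("coords must have node rownames")
  missing <- setdiff(net$nodes, rownames(coords))
  if (length(missing) > 0)
    stop("coords missing for node(s): ", paste(utils::head(missing, 5), collapse = ", "))
  coords <- coords[net$nodes, 1:2, drop = FALSE]
  colnames(coords) <- c("x", "y")
  storage.mode(coords) <- "double"
  if (!all(is.finite(coords))) stop("coords contain non-finite values")
  net$coords <- coords
  net
}

#' Convert to an igraph object
#'
#' The igraph mirror carries the canonical vertex order in the vertex `name`
#' attribute and edge weights in `weight`.
#'
#' @param net a `netkin_network`
#' @return an undirected `igraph` graph
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "netkin_network"))
  g <- igraph::make_empty_graph(n = length(net$nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = net$nodes)
  if (nrow(net$edges) > 0) {
    idx <- rbind(match(net$edges$from, net$nodes),
                 match(net$edges$to, net$nodes))
    g <- igraph::add_edges(g, as.vector(idx))
    g <- igraph::set_edge_attr(g, "weight", value = net$edges$weight)
  }
  g
}

#' Convert an igraph object to a canonical network
#'
#' Directed graphs are symmetrized (documented behaviour for citation-style
#' inputs); vertex attributes `x`/`y`, if present, become coordinates.
#'
#' @param g an igraph graph
#' @return a `netkin_network`
#' @export
from_igraph <- function(g) {
  nm <- igraph::vertex_attr(g, "name")
  if (is.null(nm)) nm <- as.character(seq_len(igraph::vcount(g)))
  el <- igraph::as_edgelist(g, names = FALSE)
  w <- igraph::edge_attr(g, "weight")
  if (is.null(w)) w <- rep(1, nrow(el))
  edges <- data.frame(from = nm[el[, 1]], to = nm[el[, 2]], weight = w,
                      stringsAsFactors = FALSE)
  coords <- NULL
  va <- igraph::vertex_attr_names(g)
  if (all(c("x", "y") %in% va)) {
    coords <- cbind(x = as.numeric(igraph::vertex_attr(g, "x")),
                    y = as.numeric(igraph::vertex_attr(g, "y")))
    rownames(coords) <- nm
  }
  make_network(edges, nodes = nm, coords = coords)
}

# adjacency as a sparse symmetric dgCMatrix in canonical node order
network_adjacency <- function(net) {
  n <- length(net$nodes)
  if (nrow(net$edges) == 0)
    return(Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(n, n),
                                dimnames = list(net$nodes, net$nodes)))
  i <- match(net$edges$from, net$nodes)
  j <- match(net$edges$to, net$nodes)
  Matrix::sparseMatrix(i = c(i, j), j = c(j, i),
                       x = rep(net$edges$weight, 2), dims = c(n, n),
                       dimnames = list(net$nodes, net$nodes))
}
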