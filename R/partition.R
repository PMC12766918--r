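#' Node partitions
#'
#' A `netkin_partition` is a disjoint, exhaustive assignment of network nodes
#' to clusters. Cluster ids are the contiguous integers `0..k-1` in canonical
#' order: clusters are numbered by their smallest contained node id (smallest
#' in the network's canonical node order), so the numbering is invariant to
#' the order in which an algorithm emits communities.
#'
#' @param membership named vector: node id -> arbitrary cluster key
#' @param params list recording algorithm name and tuning parameters
#' @return a `netkin_partition`: list with `assignment` (named integer vector
#'   of 0-based cluster ids, in canonical node order), `k`, `params`
#' @export
as_partition <- function(membership, params = list()) {
  if (is.null(names(membership))) stop("membership must be named by node id")
  nodes <- sort(names(membership), method = "radix")
  keys <- as.character(membership[nodes])
  if (anyNA(keys)) stop("membership contains NA cluster keys")
  ids <- match(keys, unique(keys)) - 1L  # first-appearance order == smallest node id
  structure(list(assignment = stats::setNames(ids, nodes),
                 k = length(unique(ids)),
                 params = params),
            class = "netkin_partition")
}

#' @export
print.netkin_partition <- function(x, ...) {
  alg <- x$params$algorithm
  cat("<netkin_partition> ", length(x$assignment), " nodes in ", x$k,
      " clusters", if (!is.null(alg)) paste0(" (", alg, ")"), "\n", sep = "")
  invisible(x)
}

#' Cluster membership as a list of node-id vectors
#' @param part a `netkin_partition`
#' @return list indexed `1..k` (cluster id + 1) of node id vectors
#' @export
partition_clusters <- function(part) {
  stopifnot(inherits(part, "netkin_partition"))
  split(names(part$assignment), part$assignment)
}

#' Cluster sizes
#' @param part a `netkin_partition`
#' @return integer vector of length k, index = cluster id + 1
#' @export
cluster_sizes <- function(part) {
  stopifnot(inherits(part, "netkin_partition"))
  as.integer(tabulate(part$assignment + 1L, nbins = part$k))
}

# sparse N x k indicator aligned to a node order
partition_indicator <- function(part, nodes = names(part$assignment)) {
  idx <- part$assignment[nodes]
  if (anyNA(idx)) stop("partition does not cover node(s): ",
                       paste(utils::head(nodes[is.na(idx)], 5), collapse = ", "))
  Matrix::sparseMatrix(i = seq_along(nodes), j = as.integer(idx) + 1L, x = 1,
                       dims = c(length(nodes), part$k),
                       dimnames = list(nodes, as.character(seq_len(part$k) - 1L)))
}

#' Write / read a partition as two-column TSV (node, cluster)
#' @param part a `netkin_partition`
#' @param path file path
#' @return `path` (write) or a `netkin_partition` (read)
#' @export
write_partition <- function(part, path) {
  stopifnot(inherits(part, "netkin_partition"))
  utils::write.table(data.frame(node = names(part$assignment),
                                cluster = unname(part$assignment)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("node", "cluster") %in% names(df)))
    stop("format error: ", path, ": expected columns node, cluster")
  as_partition(stats::setNames(df$cluster, df$node),
               params = list(source = path))
}
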