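#' Per-cluster compactness
#'
#' Mean pairwise Euclidean distance between a cluster's nodes in the 2-D
#' layout (lower = tighter). Singleton clusters score 0 by convention.
#'
#' @param coords numeric matrix (x, y) with node rownames covering the
#'   partition's nodes
#' @param part a `netkin_partition`
#' @return named numeric vector, one value per cluster id
#' @export
compactness <- function(coords, part) {
  stopifnot(inherits(part, "netkin_partition"))
  coords <- check_coords(coords, part)
  clusters <- partition_clusters(part)
  vapply(clusters, function(members) {
    if (length(members) < 2) return(0)
    mean(stats::dist(coords[members, , drop = FALSE]))
  }, 0)
}

#' Separation between clusters
#'
#' Minimum Euclidean distance between cluster centroids in the layout.
#'
#' @inheritParams compactness
#' @return a single non-negative number
#' @export
separation <- function(coords, part) {
  stopifnot(inherits(part, "netkin_partition"))
  if (part$k < 2) stop("separation requires at least 2 clusters")
  coords <- check_coords(coords, part)
  cent <- t(vapply(partition_clusters(part),
                   function(members) colMeans(coords[members, , drop = FALSE]),
                   c(x = 0, y = 0)))
  min(stats::dist(cent))
}

#' Silhouette scores on layout coordinates
#'
#' Standard silhouette: for node i with mean intra-cluster distance
#' \eqn{a_i} (excluding itself) and \eqn{b_i} the smallest mean distance to
#' any other cluster, \eqn{s_i = (b_i - a_i)/\max(a_i, b_i)}. Nodes in
#' singleton clusters, and nodes with \eqn{a_i = b_i = 0} (coincident
#' points), score 0 by convention.
#'
#' @inheritParams compactness
#' @return list with `mean` and `per_node` (named numeric vector in
#'   canonical node order)
#' @export
silhouette_score <- function(coords, part) {
  stopifnot(inherits(part, "netkin_partition"))
  if (part$k < 2) stop("silhouette requires at least 2 clusters")
  coords <- check_coords(coords, part)
  nodes <- names(part$assignment)
  D <- as.matrix(stats::dist(coords[nodes, , drop = FALSE]))
  memb <- part$assignment
  sizes <- cluster_sizes(part)
  # mean distance of each node to each cluster, vectorized: D %*% indicator
  Cind <- as.matrix(partition_indicator(part, nodes))
  sums <- D %*% Cind                       # n x k total distance to cluster
  own <- memb + 1L
  s <- numeric(length(nodes))
  for (i in seq_along(nodes)) {
    ni <- sizes[own[i]]
    if (ni <= 1) { s[i] <- 0; next }
    a <- sums[i, own[i]] / (ni - 1)
    b <- min(sums[i, -own[i]] / sizes[-own[i]])
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  names(s) <- nodes
  list(mean = mean(s), per_node = s)
}

check_coords <- function(coords, part) {
  if (is.data.frame(coords)) {
    m <- cbind(x = coords$x, y = coords$y)
    rownames(m) <- coords$node %||% rownames(coords)
    coords <- m
  }
  nodes <- names(part$assignment)
  missing <- setdiff(nodes, rownames(coords))
  if (length(missing) > 0)
    stop("missing coordinates for node(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  m <- coords[nodes, 1:2, drop = FALSE]
  if (!all(is.finite(m))) stop("non-finite coordinates")
  m
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two samples. The p-value is exact (by enumeration
#' of rank assignments) when the pooled sample has at most 12 observations
#' and no ties; otherwise the normal approximation with the standard
#' tie-corrected variance is used (no continuity correction). U counts
#' pairs where x exceeds y (ties counted half). Two identical samples give
#' U = |x||y|/2 and p = 1.
#'
#' @param x,y numeric samples (non-empty)
#' @param alternative `"two-sided"` (default), `"less"`, or `"greater"`
#'   (`"greater"`: x tends larger than y)
#' @return list with `U` and `p`
#' @export
mann_whitney_u <- function(x, y, alternative = c("two-sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (length(x) == 0 || length(y) == 0) stop("both samples must be non-empty")
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  if (nx + ny <= 12 && !ties) {
    wt <- stats::wilcox.test(x, y, alternative = switch(alternative,
                                                        `two-sided` = "two.sided",
                                                        less = "less",
                                                        greater = "greater"),
                             exact = TRUE)
    return(list(U = unname(U), p = unname(wt$p.value)))
  }
  n <- nx + ny
  mu <- nx * ny / 2
  tie_tab <- table(c(x, y))
  tie_term <- sum(tie_tab^3 - tie_tab)
  sigma2 <- nx * ny / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (sigma2 <= 0) return(list(U = unname(U), p = 1))
  z <- (U - mu) / sqrt(sigma2)
  p <- switch(alternative,
              `two-sided` = 2 * stats::pnorm(-abs(z)),
              greater = stats::pnorm(z, lower.tail = FALSE),
              less = stats::pnorm(z))
  list(U = unname(U), p = min(p, 1))
}

#' Evaluate one partition on a layout
#'
#' @inheritParams compactness
#' @return a `netkin_eval` list: `per_cluster_compactness`, `separation`
#'   (NA when k < 2), `silhouette_mean`, `silhouette_per_node`
#' @export
evaluate_partition <- function(coords, part) {
  comp <- compactness(coords, part)
  sep <- if (part$k >= 2) separation(coords, part) else NA_real_
  sil <- if (part$k >= 2) silhouette_score(coords, part)
         else list(mean = NA_real_, per_node = NULL)
  structure(list(per_cluster_compactness = comp,
                 separation = sep,
                 silhouette_mean = sil$mean,
                 silhouette_per_node = sil$per_node),
            class = "netkin_eval")
}

#' @export
print.netkin_eval <- function(x, ...) {
  cat("<netkin_eval> ", length(x$per_cluster_compactness), " clusters; ",
      "mean compactness = ", format(mean(x$per_cluster_compactness), digits = 4),
      ", separation = ", format(x$separation, digits = 4),
      ", silhouette = ", format(x$silhouette_mean, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Compare two partitions on the same layout
#'
#' Evaluates both partitions and applies a two-sided Mann-Whitney U test to
#' their per-cluster compactness distributions.
#'
#' @param coords layout coordinates covering both partitions' nodes
#' @param part_a,part_b two `netkin_partition`s over the same node set
#' @return list with `report_a`, `report_b`, `mwu` (list `U`, `p`)
#' @export
compare_partitions <- function(coords, part_a, part_b) {
  if (!setequal(names(part_a$assignment), names(part_b$assignment)))
    stop("partitions cover different node sets")
  ra <- evaluate_partition(coords, part_a)
  rb <- evaluate_partition(coords, part_b)
  mwu <- mann_whitney_u(ra$per_cluster_compactness,
                        rb$per_cluster_compactness, "two-sided")
  list(report_a = ra, report_b = rb, mwu = mwu)
}
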