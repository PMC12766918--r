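# fixtures built in code, plus independent brute-force oracles used to
# freeze expected values

two_triangles <- function() {
  make_network(data.frame(from = c("a", "a", "b", "x", "x", "y"),
                          to = c("b", "c", "c", "y", "z", "z")))
}

# two K4 cliques joined by one bridge edge (m = 13)
two_k4_bridge <- function() {
  k4 <- function(v) t(utils::combn(v, 2))
  make_network(rbind(k4(paste0("a", 1:4)), k4(paste0("b", 1:4)),
                     c("a1", "b1")))
}

star_k15 <- function() {
  make_network(data.frame(from = "hub", to = paste0("leaf", 1:5)))
}

# barbell: two K5 joined by a path of 3 nodes
barbell <- function() {
  k5 <- function(v) t(utils::combn(v, 2))
  make_network(rbind(k5(paste0("a", 1:5)), k5(paste0("b", 1:5)),
                     c("a1", "p1"), c("p1", "p2"), c("p2", "b1")))
}

# small annotation fixture over a given network
toy_annotation <- function(net, mapping, min_size = 1L) {
  build_matrix(mapping, net, min_size = min_size, max_size = length(net$nodes))
}

# ---- oracles -------------------------------------------------------------

# upper-tail hypergeometric by enumerating every size-n draw from N items
# of which the first K are annotated
oracle_hyper_enum <- function(k, n, K, N) {
  draws <- utils::combn(N, n)
  mean(apply(draws, 2, function(d) sum(d <= K) >= k))
}

# upper-tail binomial by direct summation of the mass function
oracle_binom_enum <- function(k, n, p) {
  if (k <= 0) return(1)
  sum(vapply(k:n, function(i) choose(n, i) * p^i * (1 - p)^(n - i), 0))
}

# naive per-pair permutation loop, drawing the same permutation stream as
# the vectorized pass (one sample.int(N) per replicate, outside pair loops)
oracle_perm_naive <- function(ann, part, R, seed) {
  A <- ann$matrix
  nodes <- rownames(A)
  memb <- part$assignment[nodes]
  cluster_idx <- split(seq_along(nodes), memb)
  term_idx <- lapply(ann$term_ids, function(t) which(A[, t] > 0))
  k_obs <- sapply(term_idx, function(ti)
    vapply(cluster_idx, function(ci) length(intersect(ci, ti)), 0L))
  exceed <- matrix(0L, length(cluster_idx), length(term_idx))
  set.seed(seed)
  for (r in seq_len(R)) {
    perm <- sample.int(length(nodes))
    for (ci in seq_along(cluster_idx)) {
      hit_nodes <- perm[cluster_idx[[ci]]]
      for (ti in seq_along(term_idx)) {
        k_r <- length(intersect(hit_nodes, term_idx[[ti]]))
        if (k_r >= k_obs[ci, ti]) exceed[ci, ti] <- exceed[ci, ti] + 1L
      }
    }
  }
  (1 + exceed) / (1 + R)
}

# double-loop metric oracles
oracle_compactness <- function(coords, part) {
  sapply(partition_clusters(part), function(members) {
    if (length(members) < 2) return(0)
    tot <- 0; cnt <- 0
    for (i in seq_along(members)) for (j in seq_along(members)) if (i < j) {
      tot <- tot + sqrt(sum((coords[members[i], ] - coords[members[j], ])^2))
      cnt <- cnt + 1
    }
    tot / cnt
  })
}

oracle_separation <- function(coords, part) {
  cls <- partition_clusters(part)
  cent <- lapply(cls, function(m) colMeans(coords[m, , drop = FALSE]))
  best <- Inf
  for (i in seq_along(cent)) for (j in seq_along(cent)) if (i < j)
    best <- min(best, sqrt(sum((cent[[i]] - cent[[j]])^2)))
  best
}

oracle_silhouette <- function(coords, part) {
  nodes <- names(part$assignment)
  memb <- part$assignment
  s <- numeric(length(nodes))
  for (i in seq_along(nodes)) {
    di <- function(j) sqrt(sum((coords[nodes[i], ] - coords[nodes[j], ])^2))
    own <- which(memb == memb[i] & seq_along(nodes) != i)
    if (length(own) == 0) { s[i] <- 0; next }
    a <- mean(vapply(own, di, 0))
    b <- Inf
    for (cl in setdiff(unique(memb), memb[i])) {
      oth <- which(memb == cl)
      b <- min(b, mean(vapply(oth, di, 0)))
    }
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  stats::setNames(s, nodes)
}

# exact two-sided Mann-Whitney p by enumerating all rank assignments
oracle_mwu_enum <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  u_of <- function(idx) {
    xs <- pooled[idx]; ys <- pooled[-idx]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_obs <- u_of(seq_len(nx))
  assigns <- utils::combn(nx + ny, nx)
  us <- apply(assigns, 2, u_of)
  mu <- nx * ny / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# all set partitions of 1..n as restricted-growth strings
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxid) {
    if (length(prefix) == n) { out[[length(out) + 1L]] <<- prefix; return() }
    for (v in seq_len(maxid + 1L)) rec(c(prefix, v), max(maxid, v))
  }
  rec(integer(0), 0L)
  out
}

# ray-casting point-in-polygon
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly) - 1  # closed polygon: last point repeats first
  inside <- FALSE
  for (i in seq_len(n)) {
    x1 <- poly$x[i]; y1 <- poly$y[i]
    x2 <- poly$x[i + 1]; y2 <- poly$y[i + 1]
    if ((y1 > py) != (y2 > py) &&
        px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
      inside <- !inside
  }
  inside
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
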