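#' Contingency counts for one (cluster, term) pair
#'
#' @param ann a `netkin_annotation`
#' @param part a `netkin_partition` over the same nodes
#' @param cluster_id integer cluster id (0-based)
#' @param term_id term identifier
#' @return a `netkin_counts` list: `k` annotated nodes inside the cluster,
#'   `n` cluster size, `K` annotated nodes in the universe, `N` universe
#'   size. The implied 2x2 table is a = k, b = n - k, c = K - k,
#'   d = N - n - K + k.
#' @export
count_table <- function(ann, part, cluster_id, term_id) {
  stopifnot(inherits(ann, "netkin_annotation"), inherits(part, "netkin_partition"))
  if (!term_id %in% ann$term_ids) stop("unknown term id: ", term_id)
  if (!cluster_id %in% (seq_len(part$k) - 1L)) stop("unknown cluster id: ", cluster_id)
  uni <- overrep_universe(ann)
  col <- ann$matrix[uni, term_id]
  inside <- names(which(part$assignment[uni] == cluster_id))
  ct <- list(k = as.integer(sum(col[inside])),
             n = length(inside),
             K = as.integer(sum(col)),
             N = length(uni))
  class(ct) <- "netkin_counts"
  ct
}

overrep_universe <- function(ann) {
  if (identical(ann$universe, "annotated"))
    rownames(ann$matrix)[Matrix::rowSums(ann$matrix) > 0]
  else rownames(ann$matrix)
}

validate_counts <- function(ct) {
  with(ct, {
    if (k < 0 || k > min(n, K) || n > N || K > N)
      stop("invalid count table: k=", k, " n=", n, " K=", K, " N=", N)
  })
  invisible(ct)
}

#' Upper-tail hypergeometric overrepresentation p-value
#'
#' \eqn{p = P(X \ge k)} for \eqn{X \sim} Hypergeometric(N, K, n): the chance
#' that a uniformly drawn size-n subset of the universe contains at least k
#' of the K annotated nodes. Computed via `phyper` (stable in log space for
#' large N).
#'
#' @param ct a `netkin_counts` (or list with `k`, `n`, `K`, `N`)
#' @return p in (0, 1]
#' @export
hypergeom_p <- function(ct) {
  validate_counts(ct)
  stats::phyper(ct$k - 1, ct$K, ct$N - ct$K, ct$n, lower.tail = FALSE)
}

#' Upper-tail binomial overrepresentation p-value
#'
#' Approximates sampling with replacement: \eqn{p = P(X \ge k)} for
#' \eqn{X \sim} Binomial(n, K/N).
#'
#' @inheritParams hypergeom_p
#' @return p in (0, 1]
#' @export
binomial_p <- function(ct) {
  if (ct$K == 0 && ct$k > 0) stop("impossible table: k > 0 with K = 0")
  validate_counts(ct)
  stats::pbinom(ct$k - 1, ct$n, ct$K / ct$N, lower.tail = FALSE)
}

#' One-sided chi-squared overrepresentation test
#'
#' Pearson statistic on the 2x2 table, 1 df, no continuity correction:
#' \eqn{X^2 = N(ad - bc)^2 / [(a+b)(c+d)(a+c)(b+d)]}. The enrichment-direction
#' p is the upper chi-squared tail when the association is positive
#' (`a*d > b*c`) and 1 otherwise. A zero margin yields the degenerate result
#' (stat 0, p 1) with a warning.
#'
#' @inheritParams hypergeom_p
#' @return list with `stat` and `p`
#' @export
chisq_p <- function(ct) {
  validate_counts(ct)
  a <- ct$k; b <- ct$n - ct$k; c <- ct$K - ct$k; d <- ct$N - ct$n - ct$K + ct$k
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) {
    warning("degenerate 2x2 table (zero margin); returning stat 0, p 1")
    return(list(stat = 0, p = 1))
  }
  stat <- ct$N * (a * d - b * c)^2 / prod(margins)
  p <- if (a * d > b * c) stats::pchisq(stat, df = 1, lower.tail = FALSE) else 1
  list(stat = stat, p = p)
}

# exceedance counts for ALL (cluster, term) pairs under the node-label
# shuffle null: one vectorized pass, O(R * nnz) sparse work, never a dense
# N x T x R array. A: sparse N x T membership; C: sparse N x k indicator.
perm_exceedances <- function(A, C, R, seed, direction = "enrichment") {
  k_obs <- as.matrix(Matrix::crossprod(C, A))
  exceed <- matrix(0L, nrow(k_obs), ncol(k_obs))
  N <- nrow(A)
  with_seed(seed, {
    for (r in seq_len(R)) {
      perm <- sample.int(N)
      k_r <- as.matrix(Matrix::crossprod(C, A[perm, , drop = FALSE]))
      hit <- if (direction == "enrichment") k_r >= k_obs else k_r <= k_obs
      exceed <- exceed + hit
    }
  })
  dimnames(exceed) <- dimnames(k_obs)
  exceed
}

#' Permutation overrepresentation p-value
#'
#' Monte-Carlo p under the node-label-shuffle null: node rows of the
#' annotation matrix are uniformly permuted, preserving every term size and
#' every cluster size, and the add-one estimator
#' \eqn{p = (1 + \#\{r : k_r \ge k_{obs}\})/(1 + R)} is returned so p is
#' never zero. All permutations are evaluated for all clusters and terms in
#' one vectorized sparse pass; this accessor extracts the requested pair
#' (the permutation stream depends only on N and `seed`, so the value is
#' bit-identical to the corresponding entry of [run_overrep()]).
#'
#' @inheritParams count_table
#' @param R number of permutations (>= 1)
#' @param seed RNG seed
#' @param null_model only `"node-label-shuffle"` is defined
#' @return p in (0, 1]
#' @export
permutation_p <- function(ann, part, cluster_id, term_id, R = 1000L,
                          seed = 42L, null_model = "node-label-shuffle") {
  stopifnot(inherits(ann, "netkin_annotation"), inherits(part, "netkin_partition"))
  null_model <- match.arg(null_model)
  if (R < 1) stop("R must be >= 1")
  if (!term_id %in% ann$term_ids) stop("unknown term id: ", term_id)
  uni <- overrep_universe(ann)
  A <- ann$matrix[uni, term_id, drop = FALSE]
  C <- partition_indicator(part, uni)[, as.character(cluster_id), drop = FALSE]
  exceed <- perm_exceedances(A, C, R, seed)
  (1 + exceed[1, 1]) / (1 + R)
}

#' Overrepresentation table for every (cluster, term) pair
#'
#' Computes the contingency counts for all pairs with one sparse
#' cross-product, applies the chosen test, adjusts p-values across all pairs,
#' and flags rows significant when the adjusted p (raw p if
#' `correction = "none"`) falls below `alpha`.
#'
#' @inheritParams count_table
#' @param test `"hypergeom"`, `"permutation"`, `"chisq"` or `"binom"`
#' @param alpha significance threshold in (0, 1)
#' @param correction `"bh"` (Benjamini-Hochberg, default), `"bonferroni"`,
#'   or `"none"`
#' @param R permutations (permutation test only)
#' @param seed RNG seed (permutation test only)
#' @param direction `"enrichment"` (default) or `"depletion"` (lower tail /
#'   complementary exceedance)
#' @return a `netkin_overrep` data.frame with columns `cluster`, `term`,
#'   `k`, `n`, `K`, `N`, `stat` (chisq only, else NA), `p`, `adj_p`,
#'   `significant`; attributes `test`, `alpha`, `correction`, `direction`.
#' @export
run_overrep <- function(ann, part, test = c("hypergeom", "permutation",
                                            "chisq", "binom"),
                        alpha = 0.05, correction = c("bh", "bonferroni", "none"),
                        R = 1000L, seed = 42L,
                        direction = c("enrichment", "depletion")) {
  stopifnot(inherits(ann, "netkin_annotation"), inherits(part, "netkin_partition"))
  test <- match.arg(test)
  correction <- match.arg(correction)
  direction <- match.arg(direction)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")

  uni <- overrep_universe(ann)
  A <- ann$matrix[uni, , drop = FALSE]
  C <- partition_indicator(part, uni)
  Nn <- length(uni)
  kmat <- as.matrix(Matrix::crossprod(C, A))      # k x T observed overlaps
  n_cl <- as.integer(Matrix::colSums(C))
  K_t <- as.integer(Matrix::colSums(A))

  nr <- nrow(kmat); nt <- ncol(kmat)
  k <- as.vector(kmat)
  n <- rep(n_cl, times = nt)
  K <- rep(K_t, each = nr)
  stat <- rep(NA_real_, length(k))

  if (test == "hypergeom") {
    p <- if (direction == "enrichment")
      stats::phyper(k - 1, K, Nn - K, n, lower.tail = FALSE)
    else stats::phyper(k, K, Nn - K, n, lower.tail = TRUE)
  } else if (test == "binom") {
    p <- if (direction == "enrichment")
      stats::pbinom(k - 1, n, K / Nn, lower.tail = FALSE)
    else stats::pbinom(k, n, K / Nn, lower.tail = TRUE)
  } else if (test == "chisq") {
    a <- k; b <- n - k; cc <- K - k; d <- Nn - n - K + k
    num <- (a * d - b * cc)
    den <- (a + b) * (cc + d) * (a + cc) * (b + d)
    stat <- ifelse(den > 0, Nn * num^2 / den, 0)
    onesided <- if (direction == "enrichment") num > 0 else num < 0
    p <- ifelse(onesided & den > 0,
                stats::pchisq(stat, df = 1, lower.tail = FALSE), 1)
  } else {  # permutation
    if (R < 1) stop("R must be >= 1")
    exceed <- perm_exceedances(A, C, R, seed, direction)
    p <- (1 + as.vector(exceed)) / (1 + R)
  }

  adj <- stats::p.adjust(p, method = switch(correction, bh = "BH",
                                            bonferroni = "bonferroni",
                                            none = "none"))
  tab <- data.frame(
    cluster = rep(seq_len(nr) - 1L, times = nt),
    term = rep(colnames(A), each = nr),
    k = k, n = n, K = K, N = Nn,
    stat = stat, p = p, adj_p = adj,
    significant = adj < alpha,
    stringsAsFactors = FALSE)
  tab <- tab[order(tab$cluster, tab$term, method = "radix"), ]
  rownames(tab) <- NULL
  structure(tab, class = c("netkin_overrep", "data.frame"),
            test = test, alpha = alpha, correction = correction,
            direction = direction, R = if (test == "permutation") R else NA,
            seed = if (test == "permutation") seed else NA)
}

#' Write an overrepresentation table as TSV
#' @param tab a `netkin_overrep`
#' @param path file path
#' @export
write_overrep <- function(tab, path) {
  stopifnot(inherits(tab, "netkin_overrep"))
  out <- as.data.frame(tab)
  out$stat <- NULL
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
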