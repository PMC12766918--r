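#' Significant clusters and their domain labels
#'
#' Retains clusters with at least one term below `alpha` (on the table's
#' adjusted p, which equals the raw p when no correction was applied) and
#' labels each retained cluster with its `top_k` best terms, sorted
#' ascending by p with ties broken by term id. The display label of a
#' domain is its single best term.
#'
#' @param tab a `netkin_overrep` table
#' @param alpha significance threshold in (0, 1)
#' @param top_k number of label terms kept per cluster (>= 1)
#' @return a `netkin_domains`: list with `significant_clusters` (integer
#'   ids), `labels` (cluster id -> data.frame `term`, `p`), `alpha`
#' @export
build_domains <- function(tab, alpha = 0.01, top_k = 3L) {
  stopifnot(inherits(tab, "netkin_overrep"))
  if (nrow(tab) == 0) stop("empty overrepresentation table")
  if (!(alpha > 0 && alpha < 1) && alpha != 1) stop("alpha must be in (0, 1]")
  if (top_k < 1) stop("top_k must be >= 1")
  sig <- tab[tab$adj_p < alpha, , drop = FALSE]
  clusters <- sort(unique(sig$cluster))
  labels <- lapply(clusters, function(cl) {
    rows <- sig[sig$cluster == cl, , drop = FALSE]
    rows <- rows[order(rows$adj_p, rows$term, method = "radix"), , drop = FALSE]
    utils::head(data.frame(term = rows$term, p = rows$adj_p,
                           stringsAsFactors = FALSE), top_k)
  })
  names(labels) <- as.character(clusters)
  structure(list(significant_clusters = clusters, labels = labels,
                 alpha = alpha),
            class = "netkin_domains")
}

#' @export
print.netkin_domains <- function(x, ...) {
  cat("<netkin_domains> ", length(x$significant_clusters),
      " significant cluster(s) at alpha = ", x$alpha, "\n", sep = "")
  for (cl in names(x$labels))
    cat("  cluster ", cl, ": ", x$labels[[cl]]$term[1],
        " (p = ", format(x$labels[[cl]]$p[1], digits = 3), ")\n", sep = "")
  invisible(x)
}

# generic shared-node rule: given named list of node sets, drop nodes present
# in >= 2 sets; a set is "unique" if >= min_remaining nodes survive
unique_sets <- function(sets, min_remaining = 1L) {
  all_nodes <- unlist(sets, use.names = FALSE)
  shared <- unique(all_nodes[duplicated(all_nodes)])
  keep <- vapply(sets, function(s) length(setdiff(s, shared)) >= min_remaining,
                 TRUE)
  names(sets)[keep]
}

#' Unique significant clusters after removing shared nodes
#'
#' For each significant cluster, nodes appearing in at least two significant
#' clusters' node sets are removed; a cluster is "unique" if at least
#' `min_remaining` nodes survive. With `mode = "term-members"` (default) a
#' cluster's node set is the union of the network members of its significant
#' label terms — these sets can overlap even though a hard partition is
#' disjoint. `mode = "partition"` uses the plain cluster node sets, the
#' natural rule for externally supplied (possibly overlapping) clusterings.
#'
#' @param dm a `netkin_domains`
#' @param part a `netkin_partition`
#' @param ann a `netkin_annotation` (required for `mode = "term-members"`)
#' @param mode `"term-members"` or `"partition"`
#' @param min_remaining minimum surviving nodes (default 1)
#' @return integer vector of unique cluster ids (subset of the significant
#'   clusters)
#' @export
unique_clusters <- function(dm, part, ann = NULL,
                            mode = c("term-members", "partition"),
                            min_remaining = 1L) {
  stopifnot(inherits(dm, "netkin_domains"), inherits(part, "netkin_partition"))
  mode <- match.arg(mode)
  if (length(dm$significant_clusters) == 0) return(integer(0))
  clusters <- partition_clusters(part)
  sets <- lapply(dm$significant_clusters, function(cl) {
    members <- clusters[[as.character(cl)]]
    if (mode == "partition") return(members)
    if (is.null(ann)) stop("mode 'term-members' requires the annotation matrix")
    terms <- dm$labels[[as.character(cl)]]$term
    term_nodes <- rownames(ann$matrix)[
      Matrix::rowSums(ann$matrix[, terms, drop = FALSE]) > 0]
    term_nodes
  })
  names(sets) <- as.character(dm$significant_clusters)
  as.integer(unique_sets(sets, min_remaining))
}

#' Write domains as TSV
#' @param dm a `netkin_domains`
#' @param path file path
#' @export
write_domains <- function(dm, path) {
  stopifnot(inherits(dm, "netkin_domains"))
  rows <- do.call(rbind, lapply(names(dm$labels), function(cl) {
    data.frame(cluster = as.integer(cl),
               rank = seq_len(nrow(dm$labels[[cl]])),
               term = dm$labels[[cl]]$term,
               p = dm$labels[[cl]]$p, stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    rows <- data.frame(cluster = integer(), rank = integer(),
                       term = character(), p = numeric())
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
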