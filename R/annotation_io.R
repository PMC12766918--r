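#' Read a term-to-members annotation table
#'
#' Accepts a JSON object mapping each term id to an array of member node ids,
#' or a long-format CSV/TSV with header columns `term` and `node` (delimiter
#' chosen by extension). Duplicate members within a term are deduplicated.
#'
#' @param path file path
#' @param fmt one of `"auto"`, `"json"`, `"csv"`, `"tsv"`
#' @return named list: term id -> character vector of member ids
#' @export
read_annotations <- function(path, fmt = c("auto", "json", "csv", "tsv")) {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("format error: ", path, ": empty file")
  if (fmt == "auto") {
    ext <- tolower(tools::file_ext(path))
    fmt <- if (ext == "json") "json"
           else if (ext == "csv") "csv"
           else if (ext %in% c("tsv", "txt")) "tsv"
           else if (grepl("^\\s*\\{", readLines(path, n = 1L, warn = FALSE))) "json"
           else "tsv"
  }
  if (fmt == "json") {
    mapping <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    if (!is.list(mapping) || is.null(names(mapping)) || any(names(mapping) == ""))
      stop("format error: ", path, ": JSON must be an object of term -> member array")
    mapping <- lapply(mapping, function(m) unique(as.character(m)))
  } else {
    sep <- if (fmt == "csv") "," else "\t"
    df <- utils::read.table(path, sep = sep, header = TRUE,
                            stringsAsFactors = FALSE, quote = "\"",
                            comment.char = "", check.names = FALSE)
    if (!all(c("term", "node") %in% names(df)))
      stop("format error: ", path, ": required columns 'term' and 'node' ",
           "(found: ", paste(names(df), collapse = ", "), ")")
    bad <- which(is.na(df$term) | is.na(df$node) | df$term == "" | df$node == "")
    if (length(bad) > 0)
      stop("format error: ", path, " line ", bad[1] + 1L, ": empty term or node field")
    mapping <- lapply(split(as.character(df$node), as.character(df$term)), unique)
  }
  if (length(mapping) == 0) stop("format error: ", path, ": no terms found")
  mapping
}

#' Build the sparse node-by-term membership matrix
#'
#' Intersects each term's member list with the network's node set, drops
#' terms whose in-network size falls outside `[min_size, max_size]`, and
#' returns a sparse binary matrix whose row order is the network's canonical
#' node order. Members absent from the network are excluded and counted.
#'
#' The statistical universe N defaults to all network nodes; with
#' `universe = "annotated"` it is restricted to nodes carrying at least one
#' membership (both conventions are common in enrichment analysis).
#'
#' @param mapping named list term -> member ids (see [read_annotations()])
#' @param net a `netkin_network`
#' @param min_size,max_size keep terms with in-network size in this range.
#'   Defaults 2 and `Inf`: size-1 terms cannot be meaningfully overrepresented.
#' @param universe `"network"` (all nodes) or `"annotated"` (annotated nodes)
#' @param case_fold match identifiers case-insensitively
#' @param term_names optional named character vector of term descriptions
#' @return a `netkin_annotation`: list with `matrix` (sparse N x T dgCMatrix,
#'   dimnames node x term), `term_ids`, `term_names`, `coverage` (number of
#'   annotated network nodes), `universe_size`, `dropped_terms`,
#'   `unmatched_members`
#' @export
build_matrix <- function(mapping, net, min_size = 2L, max_size = Inf,
                         universe = c("network", "annotated"),
                         case_fold = FALSE, term_names = NULL) {
  stopifnot(inherits(net, "netkin_network"))
  universe <- match.arg(universe)
  if (min_size < 1) stop("min_size must be >= 1")
  if (max_size < min_size) stop("max_size must be >= min_size")
  if (length(mapping) == 0 || is.null(names(mapping)))
    stop("mapping must be a named list of term -> members")

  nodes <- net$nodes
  lookup <- if (case_fold) tolower(nodes) else nodes
  mapping <- lapply(mapping, function(m) unique(as.character(m)))
  flat <- unlist(mapping, use.names = FALSE)  # one match call, not one per term
  idx_flat <- match(if (case_fold) tolower(flat) else flat, lookup)
  n_unmatched <- sum(is.na(idx_flat))
  idx_split <- split(idx_flat, factor(rep.int(seq_along(mapping), lengths(mapping)),
                                      levels = seq_along(mapping)))
  members_idx <- lapply(idx_split, function(ix) sort(ix[!is.na(ix)]))
  names(members_idx) <- names(mapping)
  sizes <- lengths(members_idx)
  keep <- sizes >= min_size & sizes <= max_size
  dropped <- names(mapping)[!keep]
  if (!any(keep))
    stop("no terms survive size filtering [", min_size, ", ", max_size,
         "]; relax the thresholds")
  members_idx <- members_idx[keep]
  term_ids <- names(members_idx)
  ord <- order(term_ids, method = "radix")
  members_idx <- members_idx[ord]
  term_ids <- term_ids[ord]

  mat <- Matrix::sparseMatrix(
    i = unlist(members_idx, use.names = FALSE),
    j = rep.int(seq_along(members_idx), lengths(members_idx)),
    x = 1, dims = c(length(nodes), length(term_ids)),
    dimnames = list(nodes, term_ids))

  coverage <- sum(Matrix::rowSums(mat) > 0)
  structure(list(matrix = mat,
                 term_ids = term_ids,
                 term_names = term_names[term_ids],
                 coverage = coverage,
                 universe_size = if (universe == "annotated") coverage else length(nodes),
                 universe = universe,
                 dropped_terms = dropped,
                 unmatched_members = n_unmatched),
            class = "netkin_annotation")
}

#' @export
print.netkin_annotation <- function(x, ...) {
  cat("<netkin_annotation> ", nrow(x$matrix), " nodes x ", length(x$term_ids),
      " terms; ", x$coverage, " annotated nodes (universe N = ",
      x$universe_size, ")\n", sep = "")
  if (length(x$dropped_terms) > 0 || x$unmatched_members > 0)
    cat("  dropped ", length(x$dropped_terms), " term(s) by size filter; ",
        x$unmatched_members, " member id(s) not in network\n", sep = "")
  invisible(x)
}

#' Term sizes within the network
#' @param ann a `netkin_annotation`
#' @return named integer vector of in-network term sizes K_t
#' @export
term_sizes <- function(ann) {
  stopifnot(inherits(ann, "netkin_annotation"))
  stats::setNames(as.integer(Matrix::colSums(ann$matrix)), ann$term_ids)
}
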