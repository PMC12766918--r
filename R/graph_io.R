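#' Read a network from file
#'
#' Supported formats: Cytoscape JSON (`cyjs`, elements dialect),
#' whitespace/tab-delimited edge lists with an optional third weight column
#' and `#` comments (`edgelist`), GraphML (`graphml`), and R-native
#' serialization of a `netkin_network` (`rds`; non-portable, for caching
#' within R workflows). `fmt = "auto"` resolves by file extension, then by
#' content sniffing.
#'
#' Directed inputs (GraphML `edgedefault="directed"`, or any igraph directed
#' graph) are symmetrized. Parallel edges are collapsed with weights summed
#' and self-loops dropped with a warning. Isolated nodes are retained.
#'
#' @param path file path
#' @param fmt one of `"auto"`, `"cyjs"`, `"edgelist"`, `"graphml"`, `"rds"`
#' @return a [make_network()] canonical `netkin_network`
#' @export
read_network <- function(path, fmt = c("auto", "cyjs", "edgelist", "graphml", "rds")) {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) stop("file not found: ", path)
  if (fmt == "auto") fmt <- sniff_network_format(path)
  switch(fmt,
         cyjs = read_cyjs(path),
         edgelist = read_edgelist(path),
         graphml = read_graphml(path),
         rds = {
           net <- readRDS(path)
           if (!inherits(net, "netkin_network"))
             stop("format error: ", path, " is not a serialized netkin_network")
           net
         })
}

sniff_network_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("cyjs", "json")) return("cyjs")
  if (ext %in% c("graphml", "xml")) return("graphml")
  if (ext %in% c("rds")) return("rds")
  if (ext %in% c("tsv", "csv", "txt", "edgelist", "edges", "el")) return("edgelist")
  head <- tryCatch(readBin(path, "raw", 4L), error = function(e) raw())
  if (length(head) >= 2 && head[1] == as.raw(0x1f)) return("rds")  # gzip (serialized)
  first <- tryCatch(readLines(path, n = 1L, warn = FALSE), error = function(e) "")
  if (grepl("^\\s*[{\\[]", first)) return("cyjs")
  if (grepl("^\\s*<\\?xml|^\\s*<graphml", first)) return("graphml")
  "edgelist"
}

read_edgelist <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  keep <- which(!grepl("^\\s*$", lines))
  if (length(keep) == 0) stop("format error: ", path, ": no edge records found")
  fields <- strsplit(trimws(lines[keep]), "[\t ,]+")
  nf <- lengths(fields)
  bad <- which(nf < 2 | nf > 3)
  if (length(bad) > 0)
    stop("format error: ", path, " line ", keep[bad[1]],
         ": expected 2 or 3 fields, got ", nf[bad[1]])
  from <- vapply(fields, `[`, "", 1L)
  to <- vapply(fields, `[`, "", 2L)
  w <- vapply(fields, function(f) {
    if (length(f) >= 3) suppressWarnings(as.numeric(f[3])) else 1
  }, 0)
  if (anyNA(w)) {
    badw <- keep[which(is.na(w))[1]]
    stop("format error: ", path, " line ", badw, ": non-numeric weight")
  }
  make_network(data.frame(from = from, to = to, weight = w,
                          stringsAsFactors = FALSE))
}

read_cyjs <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop("format error: ", path,
                                           ": not valid JSON (", conditionMessage(e), ")"))
  elements <- doc$elements
  if (is.null(elements)) elements <- doc  # bare {nodes:..., edges:...}
  nodes <- elements$nodes
  if (is.null(nodes)) stop("format error: ", path, ": no 'elements.nodes' array")
  node_ids <- character(length(nodes))
  labels <- character(0)
  coords <- NULL
  have_pos <- vapply(nodes, function(nd) !is.null(nd$position), TRUE)
  if (all(have_pos) && length(nodes) > 0) coords <- matrix(NA_real_, length(nodes), 2)
  for (i in seq_along(nodes)) {
    nd <- nodes[[i]]
    id <- nd$data$id
    if (is.null(id)) stop("format error: ", path, ": node record ", i, " has no data.id")
    node_ids[i] <- as.character(id)
    if (!is.null(nd$data$name)) labels[node_ids[i]] <- as.character(nd$data$name)
    if (!is.null(coords)) coords[i, ] <- c(as.numeric(nd$position$x),
                                           as.numeric(nd$position$y))
  }
  if (anyDuplicated(node_ids))
    stop("format error: ", path, ": duplicate node id '",
         node_ids[anyDuplicated(node_ids)], "'")
  if (!is.null(coords)) rownames(coords) <- node_ids
  edges <- elements$edges
  ef <- et <- character(0); ew <- numeric(0)
  for (i in seq_along(edges)) {
    ed <- edges[[i]]$data
    if (is.null(ed$source) || is.null(ed$target))
      stop("format error: ", path, ": edge record ", i, " lacks source/target")
    s <- as.character(ed$source); t <- as.character(ed$target)
    if (!(s %in% node_ids) || !(t %in% node_ids))
      stop("validation error: ", path, ": edge record ", i,
           " references unknown node '", if (s %in% node_ids) t else s, "'")
    ef[i] <- s; et[i] <- t
    ew[i] <- if (!is.null(ed$weight)) as.numeric(ed$weight) else 1
  }
  make_network(data.frame(from = ef, to = et, weight = ew,
                          stringsAsFactors = FALSE),
               nodes = node_ids, coords = coords,
               labels = if (length(labels)) labels else NULL)
}

read_graphml <- function(path) {
  g <- tryCatch(igraph::read_graph(path, format = "graphml"),
                error = function(e) stop("format error: ", path,
                                         ": not valid GraphML (", conditionMessage(e), ")"))
  from_igraph(g)
}

#' Write a network to file
#'
#' Round trip holds for every format: `read_network(write_network(net))`
#' reproduces the node set, edge set and weights exactly; `cyjs`, `graphml`
#' and `rds` additionally round-trip coordinates.
#'
#' @param net a `netkin_network`
#' @param path output file path
#' @param fmt one of `"cyjs"`, `"edgelist"`, `"graphml"`, `"rds"`
#' @return `path`, invisibly
#' @export
write_network <- function(net, path, fmt = c("cyjs", "edgelist", "graphml", "rds")) {
  stopifnot(inherits(net, "netkin_network"))
  fmt <- match.arg(fmt)
  switch(fmt,
         edgelist = {
           lines <- sprintf("%s\t%s\t%s", net$edges$from, net$edges$to,
                            format(net$edges$weight, digits = 15, trim = TRUE,
                                   scientific = FALSE))
           writeLines(lines, path)
         },
         cyjs = {
           nodes <- lapply(net$nodes, function(id) {
             nd <- list(data = list(id = id))
             if (!is.null(net$labels) && id %in% names(net$labels))
               nd$data$name <- unname(net$labels[id])
             if (!is.null(net$coords))
               nd$position <- list(x = net$coords[id, "x"], y = net$coords[id, "y"])
             nd
           })
           edges <- lapply(seq_len(nrow(net$edges)), function(i) {
             list(data = list(id = paste0("e", i - 1),
                              source = net$edges$from[i],
                              target = net$edges$to[i],
                              weight = net$edges$weight[i]))
           })
           doc <- list(elements = list(nodes = nodes, edges = edges))
           jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
         },
         graphml = {
           g <- as_igraph(net)
           if (!is.null(net$coords)) {
             g <- igraph::set_vertex_attr(g, "x", value = net$coords[, "x"])
             g <- igraph::set_vertex_attr(g, "y", value = net$coords[, "y"])
           }
           igraph::write_graph(g, path, format = "graphml")
         },
         rds = saveRDS(net, path))
  invisible(path)
}
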