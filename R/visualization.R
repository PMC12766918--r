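#' Compute a 2-D layout
#'
#' Fruchterman-Reingold spring embedding (the default layout used
#' throughout), deterministic for a fixed seed. `"precomputed"` returns the
#' coordinates stored on the network. `"forceatlas2"` is backend-delegated
#' like the non-native clustering algorithms; no backend ships, so
#' requesting it without registering one is a capability error.
#'
#' @param net a `netkin_network`
#' @param method `"fr"` (alias `"fruchterman-reingold"`), `"precomputed"`,
#'   or `"forceatlas2"`
#' @param seed RNG seed
#' @param iterations FR iterations (default 500)
#' @return numeric matrix (x, y) with node rownames, canonical order
#' @export
layout_coords <- function(net, method = c("fr", "fruchterman-reingold",
                                          "precomputed", "forceatlas2"),
                          seed = 42L, iterations = 500L) {
  stopifnot(inherits(net, "netkin_network"))
  method <- match.arg(method)
  if (method == "precomputed") {
    if (is.null(net$coords)) stop("network carries no precomputed coordinates")
    return(net$coords)
  }
  if (method == "forceatlas2") {
    backend <- the_backends[["layout.forceatlas2"]]
    if (is.null(backend))
      stop("no backend registered for forceatlas2; native layout: fr")
    return(backend(net, list(seed = seed, iterations = iterations)))
  }
  g <- as_igraph(net)
  xy <- with_seed(seed, igraph::layout_with_fr(g, niter = iterations))
  rownames(xy) <- net$nodes
  colnames(xy) <- c("x", "y")
  xy
}

#' Plot specification
#'
#' @param layout layout method for [render_network()]
#' @param layout_seed seed for the layout
#' @param node_size node radius in user units (single value or per-node map)
#' @param palette vector of colors cycled over significant clusters in
#'   cluster-id order (defaults to a colorblind-safe qualitative palette);
#'   when more domains than colors exist the palette repeats with a
#'   brightness shift
#' @param contour_level member-density quantile enclosed by each contour,
#'   strictly in (0, 1); default 0.67
#' @param contour_bandwidth KDE bandwidth (numeric) or `NULL` for Scott's
#'   rule
#' @param dpi raster resolution (>= 72), PNG only
#' @param format `"svg"`, `"png"` or `"pdf"`
#' @return a validated `netkin_plotspec`
#' @export
plot_spec <- function(layout = "fr", layout_seed = 42L, node_size = 2,
                      palette = NULL, contour_level = 0.67,
                      contour_bandwidth = NULL, dpi = 150L,
                      format = c("svg", "png", "pdf")) {
  format <- match.arg(format)
  if (!(contour_level > 0 && contour_level < 1))
    stop("contour_level must be strictly between 0 and 1")
  if (dpi < 72) stop("dpi must be >= 72")
  if (is.null(palette))
    palette <- grDevices::hcl.colors(8, "Dark 3")
  structure(list(layout = layout, layout_seed = layout_seed,
                 node_size = node_size, palette = palette,
                 contour_level = contour_level,
                 contour_bandwidth = contour_bandwidth,
                 dpi = as.integer(dpi), format = format),
            class = "netkin_plotspec")
}

domain_colors <- function(spec, cluster_ids) {
  pal <- spec$palette
  cols <- character(length(cluster_ids))
  for (i in seq_along(cluster_ids)) {
    j <- (i - 1) %% length(pal) + 1
    col <- pal[j]
    shift <- (i - 1) %/% length(pal)
    if (shift > 0) {
      rgb <- grDevices::col2rgb(col) / 255
      rgb <- pmin(1, rgb + 0.25 * shift)  # brightness shift per cycle
      col <- grDevices::rgb(rgb[1], rgb[2], rgb[3])
    }
    cols[i] <- col
  }
  stats::setNames(cols, as.character(cluster_ids))
}

# Gaussian product-kernel density of pts evaluated at matrix `at`
kde2d_eval <- function(pts, at, h) {
  dx <- outer(at[, 1], pts[, 1], "-") / h[1]
  dy <- outer(at[, 2], pts[, 2], "-") / h[2]
  rowMeans(exp(-0.5 * (dx^2 + dy^2))) / (2 * pi * h[1] * h[2])
}

scott_bandwidth <- function(pts) {
  n <- nrow(pts)
  s <- pmax(apply(pts, 2, stats::sd), 1e-9)
  s * n^(-1 / 6)
}

# closed fallback polygon: circle around 1 point, capsule around a segment
# (also used for collinear point sets)
fallback_polygon <- function(pts, pad) {
  t <- seq(0, 2 * pi, length.out = 33)
  if (nrow(pts) == 1)
    return(data.frame(x = pts[1, 1] + pad * cos(t),
                      y = pts[1, 2] + pad * sin(t)))
  pr <- stats::prcomp(pts, center = TRUE)
  axis <- pr$rotation[, 1]
  proj <- pr$x[, 1]
  c0 <- colMeans(pts) + axis * min(proj)
  c1 <- colMeans(pts) + axis * max(proj)
  ang <- atan2(axis[2], axis[1])
  t1 <- seq(ang + pi / 2, ang + 3 * pi / 2, length.out = 17)
  t2 <- seq(ang - pi / 2, ang + pi / 2, length.out = 17)
  data.frame(x = c(c0[1] + pad * cos(t1), c1[1] + pad * cos(t2)),
             y = c(c0[2] + pad * sin(t1), c1[2] + pad * sin(t2)))
}

#' KDE contour polygons for significant clusters
#'
#' For each significant cluster, fits a Gaussian kernel density (Scott
#' bandwidth unless overridden) to the member coordinates and extracts the
#' iso-density line at the `level` quantile of the members' own densities,
#' so the returned polygon(s) enclose at least `level` of the member points.
#' Clusters with fewer than 3 members, or with degenerate (coincident /
#' collinear) coordinates, fall back to a buffered hull (circle or capsule)
#' with a warning.
#'
#' @param coords layout coordinate matrix with node rownames
#' @param dm a `netkin_domains`
#' @param part a `netkin_partition`
#' @param level density quantile in (0, 1), default 0.67
#' @param bandwidth numeric bandwidth (both axes) or `NULL` for Scott's rule
#' @return named list: cluster id -> list of closed polygon data.frames
#'   (columns x, y; first point repeated last)
#' @export
contours <- function(coords, dm, part, level = 0.67, bandwidth = NULL) {
  stopifnot(inherits(dm, "netkin_domains"), inherits(part, "netkin_partition"))
  if (!(level > 0 && level < 1)) stop("level must be strictly between 0 and 1")
  clusters <- partition_clusters(part)
  span <- max(apply(coords, 2, function(v) diff(range(v))), 1e-6)
  out <- list()
  for (cl in dm$significant_clusters) {
    pts <- coords[clusters[[as.character(cl)]], , drop = FALSE]
    polys <- cluster_contour(pts, level, bandwidth, pad = 0.02 * span)
    out[[as.character(cl)]] <- polys
  }
  out
}

cluster_contour <- function(pts, level, bandwidth, pad) {
  degenerate <- nrow(pts) < 3 ||
    min(apply(pts, 2, stats::sd)) < 1e-12 ||
    abs(stats::cor(pts[, 1], pts[, 2])) > 1 - 1e-12
  if (is.na(degenerate)) degenerate <- TRUE
  if (degenerate) {
    if (nrow(pts) >= 3) warning("degenerate cluster coordinates; hull fallback")
    poly <- fallback_polygon(pts, pad)
    return(list(close_polygon(poly)))
  }
  h <- if (is.null(bandwidth)) scott_bandwidth(pts) else rep(bandwidth, 2)[1:2]
  dens <- kde2d_eval(pts, pts, h)
  thr <- stats::quantile(dens, probs = 1 - level, type = 1, names = FALSE)
  gx <- seq(min(pts[, 1]) - 3 * h[1], max(pts[, 1]) + 3 * h[1], length.out = 80)
  gy <- seq(min(pts[, 2]) - 3 * h[2], max(pts[, 2]) + 3 * h[2], length.out = 80)
  grid <- as.matrix(expand.grid(x = gx, y = gy))
  z <- matrix(kde2d_eval(pts, grid, h), length(gx), length(gy))
  lines <- grDevices::contourLines(gx, gy, z, levels = thr)
  if (length(lines) == 0)
    return(list(close_polygon(fallback_polygon(pts, pad))))
  lapply(lines, function(l) close_polygon(data.frame(x = l$x, y = l$y)))
}

close_polygon <- function(df) {
  if (df$x[1] != df$x[nrow(df)] || df$y[1] != df$y[nrow(df)])
    df <- rbind(df, df[1, ])
  rownames(df) <- NULL
  df
}

#' Render an annotated network figure
#'
#' Draws edges, nodes colored by significant domain (palette order over
#' cluster ids; all other nodes grey), KDE contour overlays, and a legend of
#' domain labels (each domain's best term). Output is deterministic for
#' fixed inputs and seed; SVG output is byte-reproducible.
#'
#' @param net a `netkin_network`
#' @param coords layout coordinates (see [layout_coords()])
#' @param dm a `netkin_domains`, or `NULL` for an unannotated (all-grey) plot
#' @param part a `netkin_partition` (required when `dm` has clusters)
#' @param spec a [plot_spec()]
#' @param path output file; extension does not override `spec$format`
#' @return `path`, invisibly
#' @export
render_network <- function(net, coords, dm = NULL, part = NULL,
                           spec = plot_spec(), path) {
  stopifnot(inherits(net, "netkin_network"), inherits(spec, "netkin_plotspec"))
  sig <- if (!is.null(dm)) dm$significant_clusters else integer(0)
  if (length(sig) > 0 && is.null(part))
    stop("a partition is required to color significant clusters")
  coords <- coords[net$nodes, , drop = FALSE]
  cols <- rep("grey70", length(net$nodes))
  names(cols) <- net$nodes
  legend_txt <- character(0); legend_col <- character(0)
  if (length(sig) > 0) {
    dcols <- domain_colors(spec, sig)
    clusters <- partition_clusters(part)
    for (cl in sig) {
      cols[clusters[[as.character(cl)]]] <- dcols[[as.character(cl)]]
      legend_txt <- c(legend_txt, dm$labels[[as.character(cl)]]$term[1])
      legend_col <- c(legend_col, dcols[[as.character(cl)]])
    }
  }
  polys <- if (length(sig) > 0)
    contours(coords, dm, part, level = spec$contour_level,
             bandwidth = spec$contour_bandwidth) else list()

  open_device(spec, path)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mar = c(0.5, 0.5, 0.5, 0.5))
  graphics::plot(coords, type = "n", axes = FALSE, xlab = "", ylab = "",
                 asp = 1)
  if (nrow(net$edges) > 0)
    graphics::segments(coords[net$edges$from, 1], coords[net$edges$from, 2],
                       coords[net$edges$to, 1], coords[net$edges$to, 2],
                       col = "grey85", lwd = 0.4)
  for (cl in names(polys)) {
    for (poly in polys[[cl]])
      graphics::polygon(poly$x, poly$y, border = cols[[
        partition_clusters(part)[[cl]][1]]], lwd = 1.4,
        col = grDevices::adjustcolor(cols[[partition_clusters(part)[[cl]][1]]],
                                     alpha.f = 0.08))
  }
  sizes <- if (length(spec$node_size) > 1)
    spec$node_size[net$nodes] else rep(spec$node_size, length(net$nodes))
  graphics::points(coords, pch = 21, bg = cols, col = "grey30",
                   cex = sizes / 2, lwd = 0.3)
  if (length(legend_txt) > 0)
    graphics::legend("topleft", legend = legend_txt, pt.bg = legend_col,
                     pch = 21, bty = "n", cex = 0.7)
  invisible(path)
}

open_device <- function(spec, path) {
  switch(spec$format,
         svg = grDevices::svg(path, width = 7, height = 7),
         pdf = grDevices::pdf(path, width = 7, height = 7),
         png = grDevices::png(path, width = 7 * spec$dpi,
                              height = 7 * spec$dpi, res = spec$dpi))
}
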