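# Channel neighbourhood graphs used to define spatial adjacency for
# clustering. Graphs are always symmetric ("two channels are always regarded
# as neighbors of each other"), irreflexive, and cover exactly the layout's
# channels.

new_neighbor_graph <- function(channels, neighbors, layout = NULL,
                               method = "manual", warnings = character()) {
  stopifnot(is.character(channels), is.list(neighbors))
  neighbors <- neighbors[channels]
  names(neighbors) <- channels
  neighbors <- lapply(neighbors, function(v) sort(unique(as.character(v))))
  g <- list(channels = channels, neighbors = neighbors, layout = layout,
            method = method, warnings = warnings)
  class(g) <- "neighbor_graph"
  g
}

#' Construct a neighbour graph from an edge list
#'
#' @param channels character vector of channel names covered by the graph.
#' @param edges two-column character matrix or data.frame of channel pairs.
#'   Edges are made symmetric; self-edges are dropped.
#' @param layout optional `erp_layout` carrying coordinates (used by
#'   inverse-distance interpolation).
#' @return A `neighbor_graph`.
#' @export
neighbor_graph <- function(channels, edges, layout = NULL) {
  edges <- as.matrix(edges)
  if (ncol(edges) != 2 && length(edges) != 0) stop("edges must have 2 columns")
  nb <- stats::setNames(vector("list", length(channels)), channels)
  for (ch in channels) nb[[ch]] <- character()
  if (nrow(edges) > 0) {
    bad <- setdiff(unique(c(edges)), channels)
    if (length(bad)) stop("edge refers to unknown channel: ",
                          paste(bad, collapse = ", "))
    for (k in seq_len(nrow(edges))) {
      a <- edges[k, 1]; b <- edges[k, 2]
      if (a == b) next
      nb[[a]] <- c(nb[[a]], b)
      nb[[b]] <- c(nb[[b]], a)
    }
  }
  new_neighbor_graph(channels, nb, layout = layout, method = "manual")
}

#' Define neighbours by inter-electrode distance
#'
#' Channels i and j are neighbours iff `0 < dist(i, j) <= radius` in the 2-D
#' layout space. Symmetry holds by construction. A radius that leaves a
#' channel without any neighbour is not an error: the isolation is recorded
#' as a warning in the graph's metadata (`$warnings`).
#'
#' @param layout an `erp_layout`.
#' @param radius positive layout-space distance.
#' @return A `neighbor_graph`.
#' @examples
#' g <- neighbors_by_distance(layout_1020_32(), radius = 0.4)
#' audit_graph(g)
#' @export
neighbors_by_distance <- function(layout, radius) {
  stopifnot(inherits(layout, "erp_layout"))
  if (!is.numeric(radius) || length(radius) != 1 || radius <= 0)
    stop("radius must be a single positive number")
  d <- as.matrix(stats::dist(cbind(layout$x, layout$y)))
  adj <- d > 0 & d <= radius
  nb <- lapply(seq_len(nrow(adj)), function(i) layout$name[adj[i, ]])
  names(nb) <- layout$name
  iso <- layout$name[rowSums(adj) == 0]
  warn <- if (length(iso))
    paste0("isolated channel(s) at radius ", radius, ": ",
           paste(iso, collapse = ", ")) else character()
  new_neighbor_graph(layout$name, nb, layout = layout,
                     method = "distance", warnings = warn)
}

#' Define neighbours by Delaunay triangulation
#'
#' Edges of the Delaunay triangulation of the 2-D layout define adjacency.
#' Channels are sorted by name before triangulating so that cocircular
#' tie-breaking inside the triangulator is reproducible; the result is then
#' symmetrised. Optionally, edges longer than `max_edge` are pruned to drop
#' spurious convex-hull edges (default: no pruning).
#'
#' @param layout an `erp_layout` with at least 3 non-collinear channels.
#' @param max_edge optional positive length; triangulation edges longer than
#'   this are removed.
#' @return A `neighbor_graph`.
#' @examples
#' g <- neighbors_by_triangulation(layout_1020_32())
#' audit_graph(g)
#' @export
neighbors_by_triangulation <- function(layout, max_edge = Inf) {
  stopifnot(inherits(layout, "erp_layout"))
  if (nrow(layout) < 3) stop("triangulation requires at least 3 channels")
  ord <- order(layout$name)
  lx <- layout$x[ord]; ly <- layout$y[ord]; lnm <- layout$name[ord]
  # collinearity check: rank of centred coordinates < 2
  cc <- cbind(lx - mean(lx), ly - mean(ly))
  if (qr(cc)$rank < 2) stop("cannot triangulate a collinear channel layout")
  dd <- deldir::deldir(lx, ly, suppressMsge = TRUE)
  seg <- dd$delsgs
  keep <- sqrt((seg$x1 - seg$x2)^2 + (seg$y1 - seg$y2)^2) <= max_edge
  seg <- seg[keep, , drop = FALSE]
  edges <- cbind(lnm[seg$ind1], lnm[seg$ind2])
  g <- neighbor_graph(layout$name, edges, layout = layout)
  g$method <- "triangulation"
  g
}

#' Symmetrise a neighbour graph
#'
#' Ensures i in neighbors(j) whenever j in neighbors(i). Idempotent; graphs
#' produced by this package are already symmetric.
#'
#' @param graph a `neighbor_graph`.
#' @return A symmetric `neighbor_graph`.
#' @export
symmetrize_graph <- function(graph) {
  stopifnot(inherits(graph, "neighbor_graph"))
  nb <- graph$neighbors
  for (a in graph$channels) {
    for (b in nb[[a]]) {
      if (!(a %in% nb[[b]])) nb[[b]] <- c(nb[[b]], a)
    }
  }
  new_neighbor_graph(graph$channels, nb, layout = graph$layout,
                     method = graph$method, warnings = graph$warnings)
}

#' Audit a neighbour graph
#'
#' Per-channel degrees, degree summary and the number of asymmetric pairs.
#' Any graph built by this package has asymmetry count 0; auditing a graph
#' before using it mirrors the advice to check that the neighbour definition
#' is accurate, symmetric and homogeneous for the montage at hand.
#'
#' @param graph a `neighbor_graph`.
#' @return A list of class `neighbor_audit` with elements `degree` (named
#'   integer vector), `min_degree`, `max_degree`, `mean_degree`,
#'   `asymmetry_count`, `lowest_degree_channels`, `connected`, `warnings`.
#' @export
audit_graph <- function(graph) {
  stopifnot(inherits(graph, "neighbor_graph"))
  deg <- vapply(graph$neighbors, length, integer(1))
  asym <- 0L
  for (a in graph$channels)
    for (b in graph$neighbors[[a]])
      if (!(a %in% graph$neighbors[[b]])) asym <- asym + 1L
  low <- if (length(deg)) names(deg)[deg == min(deg)] else character()
  out <- list(
    degree = deg,
    min_degree = if (length(deg)) min(deg) else 0L,
    max_degree = if (length(deg)) max(deg) else 0L,
    mean_degree = if (length(deg)) mean(deg) else 0,
    asymmetry_count = asym,
    lowest_degree_channels = low,
    connected = graph_connected(graph),
    warnings = graph$warnings
  )
  class(out) <- "neighbor_audit"
  out
}

graph_connected <- function(graph) {
  n <- length(graph$channels)
  if (n == 0) return(TRUE)
  seen <- stats::setNames(rep(FALSE, n), graph$channels)
  stack <- graph$channels[1]
  seen[stack] <- TRUE
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    for (w in graph$neighbors[[v]]) {
      if (!seen[[w]]) { seen[[w]] <- TRUE; stack <- c(stack, w) }
    }
  }
  all(seen)
}

#' @export
print.neighbor_audit <- function(x, ...) {
  cat("Neighbour graph audit\n")
  cat(sprintf("  channels: %d, degree min/mean/max: %d/%.2f/%d\n",
              length(x$degree), x$min_degree, x$mean_degree, x$max_degree))
  cat(sprintf("  asymmetric pairs: %d; connected: %s\n",
              x$asymmetry_count, x$connected))
  cat("  lowest-degree channels:",
      paste(x$lowest_degree_channels, collapse = ", "), "\n")
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' @export
print.neighbor_graph <- function(x, ...) {
  deg <- vapply(x$neighbors, length, integer(1))
  cat(sprintf("Neighbour graph (%s): %d channels, %d edges\n",
              x$method, length(x$channels), sum(deg) / 2))
  if (length(x$warnings)) cat("warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Write / read a neighbour graph as an edge-list tsv
#'
#' The file has columns `channel`, `neighbor`, one row per directed pair;
#' isolated channels appear with neighbor "n/a" so that coverage round-trips.
#'
#' @param graph a `neighbor_graph`.
#' @param path output path.
#' @return `write_neighbor_graph` returns `path` invisibly;
#'   `read_neighbor_graph` returns a `neighbor_graph`.
#' @export
write_neighbor_graph <- function(graph, path) {
  stopifnot(inherits(graph, "neighbor_graph"))
  rows <- do.call(rbind, lapply(graph$channels, function(ch) {
    nb <- graph$neighbors[[ch]]
    if (!length(nb)) nb <- "n/a"
    data.frame(channel = ch, neighbor = nb, stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_neighbor_graph
#' @export
read_neighbor_graph <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  chans <- unique(df$channel)
  edges <- df[df$neighbor != "n/a", , drop = FALSE]
  neighbor_graph(chans, cbind(edges$channel, edges$neighbor))
}
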