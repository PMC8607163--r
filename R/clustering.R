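# Spatio-temporal connected components. Two suprathreshold samples are
# adjacent iff they share a channel and are consecutive in time, or share a
# timepoint and their channels are neighbours in the graph. No diagonal
# adjacency. Linear grid index: k = (t - 1) * n_channels + c.

# integer adjacency: list over channel indices
.adj_index <- function(graph, channels) {
  miss <- setdiff(channels, graph$channels)
  if (length(miss)) stop("neighbour graph does not cover channel(s): ",
                         paste(miss, collapse = ", "))
  lapply(channels, function(ch) {
    nb <- intersect(graph$neighbors[[ch]], channels)
    sort(match(nb, channels))
  })
}

# Label connected components among linear indices `idx` (ascending) of an
# nch x nt grid. Returns integer component label per element of idx.
.label_components <- function(idx, nch, nt, adj) {
  nidx <- length(idx)
  if (!nidx) return(integer(0))
  pos <- integer(nch * nt)
  pos[idx] <- seq_len(nidx)
  comp <- integer(nidx)
  stack <- integer(nidx)
  ncomp <- 0L
  for (s in seq_len(nidx)) {
    if (comp[s] != 0L) next
    ncomp <- ncomp + 1L
    comp[s] <- ncomp
    top <- 1L
    stack[1L] <- s
    while (top > 0L) {
      cur <- stack[top]; top <- top - 1L
      k <- idx[cur]
      tt <- (k - 1L) %/% nch + 1L
      cc <- k - (tt - 1L) * nch
      nbr <- adj[[cc]] + (tt - 1L) * nch
      if (tt > 1L) nbr <- c(nbr, k - nch)
      if (tt < nt) nbr <- c(nbr, k + nch)
      for (k2 in nbr) {
        p2 <- pos[k2]
        if (p2 != 0L && comp[p2] == 0L) {
          comp[p2] <- ncomp
          top <- top + 1L
          stack[top] <- p2
        }
      }
    }
  }
  comp
}

# max positive / min negative cluster masses for one t vector (length nch*nt)
.max_cluster_masses <- function(tv, crit, nch, nt, adj) {
  posmax <- 0
  negmin <- 0
  pidx <- which(tv > crit)
  if (length(pidx)) {
    comp <- .label_components(pidx, nch, nt, adj)
    posmax <- max(rowsum(tv[pidx], comp))
  }
  nidx <- which(tv < -crit)
  if (length(nidx)) {
    comp <- .label_components(nidx, nch, nt, adj)
    negmin <- min(rowsum(tv[nidx], comp))
  }
  c(posmax, negmin)
}

#' Form spatio-temporal clusters from suprathreshold masks
#'
#' Connected components of the suprathreshold samples under the adjacency
#' relation: `(c, t) ~ (c, t +/- 1)` and `(c, t) ~ (c', t)` for neighbouring
#' channels `c`, `c'`. Positive and negative masks are clustered separately;
#' a cluster's mass is the sum of the statistic over its members.
#'
#' @param masks a `threshold_masks` object (or a single logical
#'   channels x timepoints matrix, treated as a positive mask).
#' @param graph a `neighbor_graph` covering the map's channels.
#' @param map the `stat_map` the masks were derived from; required to compute
#'   masses (may be omitted for a bare logical matrix, in which case each
#'   member contributes mass 1).
#' @return A list of `erp_cluster` objects, each with `members` (two-column
#'   matrix of channel/time indices), `channels`, `time_range` (seconds),
#'   `mass`, `polarity` and `size`; sorted by decreasing `|mass|` with ties
#'   broken by earliest first sample then channel name order.
#' @export
form_clusters <- function(masks, graph, map = NULL) {
  if (is.matrix(masks) && is.logical(masks)) {
    masks <- list(pos = masks, neg = array(FALSE, dim(masks)))
  }
  pos <- masks$pos
  nch <- nrow(pos); nt <- ncol(pos)
  if (is.null(map)) {
    tmat <- matrix(1, nch, nt)
    channels <- rownames(pos)
    if (is.null(channels)) {
      channels <- if (length(graph$channels) == nch) graph$channels
                  else as.character(seq_len(nch))
    }
    times <- seq_len(nt)
  } else {
    tmat <- map$t
    channels <- map$channels
    times <- map$times
  }
  adj <- .adj_index(graph, channels)
  tv <- as.vector(tmat)
  out <- list()
  for (polarity in c("positive", "negative")) {
    mask <- if (polarity == "positive") masks$pos else masks$neg
    idx <- which(as.vector(mask))
    if (!length(idx)) next
    comp <- .label_components(idx, nch, nt, adj)
    for (g in seq_len(max(comp))) {
      ki <- idx[comp == g]
      tt <- (ki - 1L) %/% nch + 1L
      cc <- ki - (tt - 1L) * nch
      cl <- list(
        members = cbind(channel = cc, time = tt),
        channels = sort(unique(channels[cc])),
        time_range = range(times[tt]),
        mass = sum(tv[ki]),
        polarity = polarity,
        size = length(ki)
      )
      class(cl) <- "erp_cluster"
      out[[length(out) + 1L]] <- cl
    }
  }
  if (!length(out)) return(out)
  # deterministic order: |mass| desc, then earliest first sample, then channels
  key_t <- vapply(out, function(cl) min(cl$members[, "time"]), numeric(1))
  key_c <- vapply(out, function(cl) cl$channels[1], character(1))
  ord <- order(-abs(vapply(out, `[[`, numeric(1), "mass")), key_t, key_c)
  out[ord]
}

#' @export
print.erp_cluster <- function(x, ...) {
  cat(sprintf("%s cluster: %d samples, %d channels, %.4g..%.4g s, mass = %.3f\n",
              x$polarity, x$size, length(x$channels),
              x$time_range[1], x$time_range[2], x$mass))
  invisible(x)
}
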