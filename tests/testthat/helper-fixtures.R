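# Shared fixtures: tiny layouts/graphs, an independent flood-fill clustering
# oracle, and generators for small random problem instances.

tiny_layout <- function() {
  erp_layout(c("a", "b", "c"), x = c(0, 1, 2), y = c(0, 0.5, 0))
}

# chain graph a - b - c
tiny_graph <- function() {
  neighbor_graph(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c")),
                 layout = tiny_layout())
}

grid3x3_layout <- function() {
  erp_layout(paste0("g", 1:9),
             x = rep(0:2, times = 3), y = rep(0:2, each = 3))
}

random_graph <- function(channels, p_edge = 0.3) {
  n <- length(channels)
  edges <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (stats::runif(1) < p_edge) edges <- rbind(edges, c(channels[i], channels[j]))
  }
  if (is.null(edges)) edges <- matrix(character(0), 0, 2)
  neighbor_graph(channels, edges)
}

# Independent flood-fill oracle for spatio-temporal connected components:
# breadth-first over an explicit queue of (channel, time) pairs, using a
# boolean channel-adjacency matrix. Deliberately naive.
oracle_components <- function(mask, adjmat) {
  nch <- nrow(mask); nt <- ncol(mask)
  lab <- matrix(0L, nch, nt)
  cur <- 0L
  for (c0 in seq_len(nch)) for (t0 in seq_len(nt)) {
    if (!mask[c0, t0] || lab[c0, t0] != 0L) next
    cur <- cur + 1L
    queue <- list(c(c0, t0))
    lab[c0, t0] <- cur
    while (length(queue)) {
      q <- queue[[1]]; queue <- queue[-1]
      cc <- q[1]; tt <- q[2]
      cand <- list()
      if (tt > 1) cand <- c(cand, list(c(cc, tt - 1)))
      if (tt < nt) cand <- c(cand, list(c(cc, tt + 1)))
      for (c2 in which(adjmat[cc, ])) cand <- c(cand, list(c(c2, tt)))
      for (p in cand) {
        if (mask[p[1], p[2]] && lab[p[1], p[2]] == 0L) {
          lab[p[1], p[2]] <- cur
          queue <- c(queue, list(p))
        }
      }
    }
  }
  lab
}

# canonical partition of a labelled grid: sorted list of sorted index vectors
partition_of <- function(lab) {
  idx <- which(lab != 0L)
  parts <- unname(split(idx, lab[idx]))
  parts <- lapply(parts, function(p) sort(unname(p)))
  parts[order(vapply(parts, min, numeric(1)))]
}

clusters_to_partition <- function(clusters, nch) {
  parts <- lapply(clusters, function(cl)
    sort(unname((cl$members[, "time"] - 1L) * nch + cl$members[, "channel"])))
  parts[order(vapply(parts, min, numeric(1)))]
}

adjmat_of <- function(graph) {
  n <- length(graph$channels)
  m <- matrix(FALSE, n, n, dimnames = list(graph$channels, graph$channels))
  for (ch in graph$channels) m[ch, graph$neighbors[[ch]]] <- TRUE
  m
}

# small dataset with a planted effect on the first channels / middle times
toy_dataset <- function(n = 6, nch = 3, nt = 4, effect = 1, seed = 1) {
  set.seed(seed)
  A <- array(stats::rnorm(n * nch * nt), c(n, nch, nt))
  B <- array(stats::rnorm(n * nch * nt), c(n, nch, nt))
  A[, 1, 2:3] <- A[, 1, 2:3] + effect
  erp_dataset(list(condA = A, condB = B),
              channels = letters[seq_len(nch)], times = seq_len(nt) / 100)
}

make_epochs <- function(data, sfreq = 500, channels = NULL,
                        condition = NULL, times = NULL) {
  d <- dim(data)
  if (is.null(channels)) channels <- paste0("ch", seq_len(d[2]))
  if (is.null(condition)) condition <- rep("standard", d[1])
  if (is.null(times)) times <- (seq_len(d[3]) - 1) / sfreq - 0.5
  erpcluster:::new_epochs(data, times = times, channels = channels,
                          sfreq = sfreq, condition = condition)
}
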