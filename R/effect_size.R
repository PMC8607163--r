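# Three Cohen's d quantifications of a cluster effect, paired-design variant:
# d = mean(differences) / sd(differences), sd with the n - 1 denominator.
# This variant is consistent with the dependent-samples t map via the
# identity d = t / sqrt(n).
#
# Option 1: d of the data averaged over exactly the cluster's member samples.
# Option 2: the largest-|d| member sample (an upper-bound-style estimate).
# Option 3: d of the data averaged over a circumscribing rectangle
#           (channels x contiguous time interval; a lower-bound-style
#           estimate for the "outside" variant).

#' Cohen's d for paired differences
#'
#' `d = mean(diffs) / sd(diffs)` with the `n - 1` denominator in `sd`.
#'
#' @param diffs numeric vector of per-subject differences, length >= 2.
#' @return The scalar d.
#' @examples
#' cohens_d_paired(c(1, 2, 3, 4, 5))  # 1.8974
#' @export
cohens_d_paired <- function(diffs) {
  if (length(diffs) < 2) stop("need at least 2 paired differences")
  s <- stats::sd(diffs)
  if (s == 0) stop("zero standard deviation of differences: effect size undefined")
  mean(diffs) / s
}

# per-subject condition difference of data averaged over a sample set
.subject_diffs_over <- function(data, conditions, members) {
  A <- data$data[[conditions[1]]]
  B <- data$data[[conditions[2]]]
  n <- dim(A)[1]
  idx <- (members[, "time"] - 1L) * dim(A)[2] + members[, "channel"]
  MA <- matrix(A, nrow = n)[, idx, drop = FALSE]
  MB <- matrix(B, nrow = n)[, idx, drop = FALSE]
  rowMeans(MA) - rowMeans(MB)
}

#' Effect size option 1: average over the cluster
#'
#' Averages each subject's condition data over exactly the channel-time
#' samples comprising the cluster, then computes paired Cohen's d of the
#' per-subject condition differences of those means.
#'
#' @param data an `erp_dataset`.
#' @param cluster an `erp_cluster`.
#' @param conditions length-2 character vector (default: first two).
#' @return The scalar d.
#' @export
es_average_over_cluster <- function(data, cluster, conditions = NULL) {
  stopifnot(inherits(data, "erp_dataset"), inherits(cluster, "erp_cluster"))
  if (is.null(conditions)) conditions <- data$conditions[1:2]
  cohens_d_paired(.subject_diffs_over(data, conditions, cluster$members))
}

#' Effect size option 2: maximum within the cluster
#'
#' Computes paired Cohen's d at every member sample of the cluster and
#' returns the one largest in magnitude (signed), with its channel and
#' latency. Peak estimates carry positive bias, so this is an
#' upper-bound-style summary.
#'
#' @inheritParams es_average_over_cluster
#' @return A list with `d`, `channel`, `latency` (seconds) and
#'   `sample` (channel/time indices).
#' @export
es_max_within_cluster <- function(data, cluster, conditions = NULL) {
  stopifnot(inherits(data, "erp_dataset"), inherits(cluster, "erp_cluster"))
  if (is.null(conditions)) conditions <- data$conditions[1:2]
  A <- data$data[[conditions[1]]]
  B <- data$data[[conditions[2]]]
  n <- dim(A)[1]
  idx <- (cluster$members[, "time"] - 1L) * dim(A)[2] + cluster$members[, "channel"]
  D <- matrix(A - B, nrow = n)[, idx, drop = FALSE]
  mu <- colMeans(D)
  sd_ <- sqrt((colSums(D * D) - n * mu * mu) / (n - 1))
  d <- mu / sd_
  d[sd_ == 0] <- sign(mu[sd_ == 0]) * Inf
  best <- which.max(abs(d))
  # deterministic tie-break: earliest time then channel order
  ties <- which(abs(abs(d) - abs(d[best])) < 1e-15)
  if (length(ties) > 1) {
    ord <- order(cluster$members[ties, "time"], cluster$members[ties, "channel"])
    best <- ties[ord[1]]
  }
  ch <- cluster$members[best, "channel"]
  tt <- cluster$members[best, "time"]
  list(d = d[best], channel = data$channels[ch], latency = data$times[tt],
       sample = c(channel = ch, time = tt))
}

#' Effect size option 3: circumscribing rectangle
#'
#' Summarises the cluster by a rectangle in channel x time space and computes
#' paired Cohen's d of the data averaged over that rectangle.
#'
#' The `outside` variant fits tightly around the cluster: all member channels
#' crossed with the full member time range, a superset of the cluster. The
#' `inside` variant fits exactly inside it: over all contiguous time
#' intervals, the channels covered at every timepoint of the interval are
#' taken, and the footprint maximising the member-sample count is chosen
#' (ties: longer interval, then earlier start, then lexicographic channel
#' set). If no interval is fully covered by any channel the largest
#' single-channel interval is used, with a warning.
#'
#' @inheritParams es_average_over_cluster
#' @param variant `"outside"` (default) or `"inside"`.
#' @return A list with `d`, `channels`, `time_range` (seconds) and `variant`.
#' @export
es_rectangle <- function(data, cluster, variant = c("outside", "inside"),
                         conditions = NULL) {
  stopifnot(inherits(data, "erp_dataset"), inherits(cluster, "erp_cluster"))
  variant <- match.arg(variant)
  if (is.null(conditions)) conditions <- data$conditions[1:2]
  mem <- cluster$members
  if (variant == "outside") {
    chans <- sort(unique(mem[, "channel"]))
    trange <- range(mem[, "time"])
  } else {
    fp <- .inside_rectangle(mem)
    chans <- fp$channels
    trange <- fp$time_range
    if (fp$fallback)
      warning("no multi-channel interval lies fully inside the cluster; ",
              "using the largest single-channel interval")
  }
  tt <- seq(trange[1], trange[2])
  members <- cbind(channel = rep(chans, times = length(tt)),
                   time = rep(tt, each = length(chans)))
  d <- cohens_d_paired(.subject_diffs_over(data, conditions, members))
  list(d = d, channels = data$channels[chans],
       time_range = data$times[trange], variant = variant)
}

# search the inside rectangle: channels covered at every timepoint of a
# contiguous interval, maximising covered member-sample count
.inside_rectangle <- function(members) {
  tvals <- sort(unique(members[, "time"]))
  by_t <- split(members[, "channel"], members[, "time"])
  best <- NULL
  for (i in seq_along(tvals)) {
    cover <- by_t[[as.character(tvals[i])]]
    for (j in i:length(tvals)) {
      if (j > i) {
        if (tvals[j] != tvals[j - 1] + 1) break  # interval must be contiguous
        cover <- intersect(cover, by_t[[as.character(tvals[j])]])
      }
      if (!length(cover)) break
      cand <- list(channels = sort(cover),
                   time_range = c(tvals[i], tvals[j]),
                   count = length(cover) * (j - i + 1),
                   len = j - i + 1, start = tvals[i])
      if (is.null(best) || .rect_better(cand, best)) best <- cand
    }
  }
  if (is.null(best)) stop("empty cluster")
  # fallback: the cluster spans several channels but no multi-channel
  # footprint lies fully inside it
  best$fallback <- length(best$channels) == 1 &&
    length(unique(members[, "channel"])) > 1
  best
}

.rect_better <- function(a, b) {
  if (a$count != b$count) return(a$count > b$count)
  if (a$len != b$len) return(a$len > b$len)
  if (a$start != b$start) return(a$start < b$start)
  paste(a$channels, collapse = ",") < paste(b$channels, collapse = ",")
}

#' Effect-size report for a cluster test result
#'
#' Computes all three effect-size options for each (by default significant)
#' cluster of a [cluster_perm_test()] result. Option 2 (maximum within the
#' cluster) is an upper-bound-style estimate and option 3 (rectangle,
#' outside variant) a lower-bound-style estimate; together they bracket the
#' effect.
#'
#' @param data the `erp_dataset` the test was run on.
#' @param result a `cluster_perm_test` object (or a `cluster_result_file`
#'   from [read_cluster_result()]).
#' @param which `"significant"` (default) or `"all"`.
#' @param rect_variant variant for option 3; default `"outside"`.
#' @return An object of class `effect_size_report`: a data.frame with one row
#'   per cluster and columns for all three options, plus a `footprints`
#'   attribute holding the option 2 locations and option 3 rectangles.
#' @export
effect_size_report <- function(data, result, which = c("significant", "all"),
                               rect_variant = "outside") {
  stopifnot(inherits(data, "erp_dataset"),
            inherits(result, "cluster_perm_test") ||
              inherits(result, "cluster_result_file"))
  which <- match.arg(which)
  conditions <- result$conditions
  keep <- if (which == "significant")
    Filter(function(cl) isTRUE(cl$significant), result$clusters)
  else result$clusters
  rows <- list(); fps <- list()
  for (i in seq_along(keep)) {
    cl <- keep[[i]]
    d1 <- es_average_over_cluster(data, cl, conditions)
    d2 <- es_max_within_cluster(data, cl, conditions)
    d3 <- es_rectangle(data, cl, variant = rect_variant, conditions = conditions)
    rows[[i]] <- data.frame(
      cluster = i, polarity = cl$polarity, mass = cl$mass,
      p_corrected = cl$p_corrected,
      d_average = d1,
      d_max = d2$d, d_max_channel = d2$channel,
      d_max_latency = d2$latency,
      d_rectangle = d3$d,
      rect_t_start = d3$time_range[1], rect_t_end = d3$time_range[2],
      rect_n_channels = length(d3$channels),
      stringsAsFactors = FALSE
    )
    fps[[i]] <- list(max_location = d2, rectangle = d3, cluster = cl)
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame()
  attr(out, "footprints") <- fps
  attr(out, "n_subjects") <- length(data$subjects)
  attr(out, "conditions") <- conditions
  attr(out, "rect_variant") <- rect_variant
  class(out) <- c("effect_size_report", "data.frame")
  out
}

#' @export
print.effect_size_report <- function(x, ...) {
  cat(sprintf("Effect sizes (paired Cohen's d, n = %d): %s - %s\n",
              attr(x, "n_subjects"), attr(x, "conditions")[1],
              attr(x, "conditions")[2]))
  if (!nrow(x)) {
    cat("no clusters to report\n")
    return(invisible(x))
  }
  for (i in seq_len(nrow(x))) {
    r <- x[i, ]
    cat(sprintf("  %s cluster: average d = %.3f; max d = %.3f at %s, %.0f ms; rectangle (%s) d = %.3f over %d channels, %.0f..%.0f ms\n",
                r$polarity, r$d_average, r$d_max, r$d_max_channel,
                r$d_max_latency * 1000, attr(x, "rect_variant"), r$d_rectangle,
                r$rect_n_channels, r$rect_t_start * 1000, r$rect_t_end * 1000))
  }
  invisible(x)
}
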