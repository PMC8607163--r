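# Max-cluster permutation engine for the paired (within-subject) design.
# The null hypothesis is exchangeability of the two condition labels within
# each subject, equivalent to flipping the sign of each subject's condition
# difference. Each draw re-runs the full map -> threshold -> cluster pipeline
# and records the largest positive and the most negative cluster mass
# (0 when a tail has no cluster, keeping the distribution length fixed).

.exhaustive_signs <- function(n) {
  if (n > 30) stop("exhaustive enumeration not supported beyond n = 30")
  npat <- 2^n
  S <- matrix(-1, nrow = npat, ncol = n)
  patterns <- 0:(npat - 1)
  for (j in seq_len(n)) {
    S[bitwAnd(patterns, bitwShiftL(1L, j - 1L)) > 0, j] <- 1
  }
  S
}

#' Number of unique permutations of a paired design
#'
#' A two-condition within-subject design admits `2^n` unique label
#' reassignments for `n` subjects (1024 for n = 10, 65536 for n = 16).
#'
#' @param n_subjects number of subjects.
#' @return `2^n_subjects` as a double.
#' @export
n_exhaustive_permutations <- function(n_subjects) 2^n_subjects

# core engine: D is the n x m matrix of per-subject condition differences.
# Returns list(pos, neg) of length B plus bookkeeping.
.permutation_engine <- function(D, crit, nch, nt, adj, n_randomizations,
                                seed, mode, block = 2000L) {
  n <- nrow(D)
  ssq <- colSums(D * D)
  if (mode == "exhaustive") {
    S <- .exhaustive_signs(n)
    B <- nrow(S)
  } else {
    B <- as.integer(n_randomizations)
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
      set.seed(seed)
    }
    S <- matrix(sample(c(-1, 1), B * n, replace = TRUE), nrow = B, ncol = n)
  }
  pos <- numeric(B)
  neg <- numeric(B)
  nm1 <- n - 1
  for (b0 in seq(1L, B, by = block)) {
    b1 <- min(b0 + block - 1L, B)
    Sb <- S[b0:b1, , drop = FALSE]
    M <- (Sb %*% D) / n
    # var of signed diffs: signs square to 1, so sum of squares is constant
    V <- sweep(-n * M * M, 2L, ssq, `+`) / nm1
    V[V < 0] <- 0
    SE <- sqrt(V / n)
    Tm <- M / SE
    Tm[SE == 0] <- sign(M[SE == 0]) * T_LARGE
    for (r in seq_len(nrow(Tm))) {
      mm <- .max_cluster_masses(Tm[r, ], crit, nch, nt, adj)
      pos[b0 + r - 1L] <- mm[1]
      neg[b0 + r - 1L] <- mm[2]
    }
  }
  list(pos = pos, neg = neg, n = B)
}

#' Permutation distribution of the max-cluster statistic
#'
#' For a paired design, each randomization flips every subject's condition
#' assignment by an independent fair sign (Monte Carlo mode) or enumerates
#' all `2^n` sign patterns (exhaustive mode). For every draw the complete
#' map -> threshold -> cluster pipeline is evaluated and the largest positive
#' cluster mass and most negative cluster mass are recorded (0 for an empty
#' tail). With a fixed seed the Monte Carlo output is fully reproducible.
#'
#' @param condA,condB numeric arrays `subjects x channels x timepoints`.
#' @param graph a `neighbor_graph` covering the channels.
#' @param n_randomizations number of Monte Carlo draws; a warning is issued
#'   below 1000, where the Monte Carlo p resolution becomes coarse.
#' @param seed integer seed controlling the Monte Carlo draws.
#' @param mode `"monte_carlo"` or `"exhaustive"`.
#' @param cluster_alpha cluster-forming alpha (two-sided); default 0.05.
#' @param channels,times optional grid labels.
#' @param exhaustive_cap refuse exhaustive enumeration beyond this many
#'   patterns (default `2^20`), advising Monte Carlo instead.
#' @return An object of class `permutation_distribution` with elements
#'   `pos`, `neg` (max-cluster masses per draw), `n_randomizations`, `mode`,
#'   `seed`, `df` and the cluster-forming threshold `crit`.
#' @export
permutation_distribution <- function(condA, condB, graph,
                                     n_randomizations = 1000, seed = NULL,
                                     mode = c("monte_carlo", "exhaustive"),
                                     cluster_alpha = 0.05,
                                     channels = NULL, times = NULL,
                                     exhaustive_cap = 2^20) {
  mode <- match.arg(mode)
  if (!identical(dim(condA), dim(condB))) stop("condition arrays must have equal shape")
  d <- dim(condA)
  if (length(d) != 3) stop("arrays must be subjects x channels x timepoints")
  n <- d[1]; nch <- d[2]; nt <- d[3]
  if (n < 2) stop("need at least 2 subjects")
  if (mode == "exhaustive" && 2^n > exhaustive_cap)
    stop("exhaustive enumeration of 2^", n, " = ", 2^n,
         " patterns exceeds the cap (", exhaustive_cap,
         "); use mode = 'monte_carlo'")
  if (mode == "monte_carlo") {
    if (n_randomizations < 1) stop("n_randomizations must be >= 1")
    if (n_randomizations < 1000)
      warning("fewer than 1000 randomizations gives a coarse Monte Carlo estimate")
  }
  if (is.null(channels)) {
    channels <- if (length(graph$channels) == nch) graph$channels
                else as.character(seq_len(nch))
  }
  adj <- .adj_index(graph, channels)
  crit <- stats::qt(1 - cluster_alpha / 2, df = n - 1)
  D <- matrix(condA - condB, nrow = n)
  eng <- .permutation_engine(D, crit, nch, nt, adj,
                             n_randomizations = n_randomizations,
                             seed = seed, mode = mode)
  out <- list(pos = eng$pos, neg = eng$neg, n_randomizations = eng$n,
              mode = mode, seed = seed, df = n - 1, crit = crit,
              cluster_alpha = cluster_alpha, n_subjects = n)
  class(out) <- "permutation_distribution"
  out
}

#' @export
print.permutation_distribution <- function(x, ...) {
  cat(sprintf("Permutation distribution (%s): %d draws, n = %d subjects\n",
              x$mode, x$n_randomizations, x$n_subjects))
  cat(sprintf("  cluster-forming |t| > %.4f (alpha = %g, df = %d)\n",
              x$crit, x$cluster_alpha, x$df))
  cat(sprintf("  max positive mass: median %.3f, max %.3f\n",
              stats::median(x$pos), max(x$pos)))
  cat(sprintf("  min negative mass: median %.3f, min %.3f\n",
              stats::median(x$neg), min(x$neg)))
  invisible(x)
}

#' Monte Carlo p-values for observed clusters
#'
#' Every observed cluster is compared against the max-cluster distribution of
#' its tail: for a positive cluster of mass `m`, the one-tail p-value is
#' `(#{draws with max mass >= m} + 1) / (B + 1)` (mirrored for the negative
#' tail); in exhaustive mode the exact proportion `k / B` is used instead
#' (the identity assignment is among the draws, so `k >= 1`). With
#' `tails = "both"` the two tails are Bonferroni-corrected by doubling:
#' `p_corrected = min(1, 2 p)`. Either way p-values are valid and strictly
#' greater than 0.
#'
#' @param clusters list of `erp_cluster` objects (as from [form_clusters()]).
#' @param dist a `permutation_distribution`.
#' @param alpha test-level alpha; default 0.05.
#' @param tails `"both"` (two-tailed, corrected) or `"one"`.
#' @return The input clusters, each augmented with `p` (one-tail),
#'   `p_corrected` and `significant`.
#' @export
cluster_p_values <- function(clusters, dist, alpha = 0.05,
                             tails = c("both", "one")) {
  tails <- match.arg(tails)
  stopifnot(inherits(dist, "permutation_distribution"))
  B <- dist$n_randomizations
  if (B < 1) stop("empty permutation distribution")
  lapply(clusters, function(cl) {
    k <- if (cl$polarity == "positive") sum(dist$pos >= cl$mass)
         else sum(dist$neg <= cl$mass)
    # exhaustive mode: exact proportion (the identity assignment is among the
    # draws, so k >= 1 and p > 0 without correction)
    p1 <- if (dist$mode == "exhaustive") k / B else (k + 1) / (B + 1)
    cl$p <- p1
    cl$p_corrected <- if (tails == "both") min(1, 2 * p1) else p1
    cl$significant <- cl$p_corrected < alpha
    cl
  })
}

#' Spatio-temporal cluster-based permutation test
#'
#' The main fitting function: given per-subject, per-condition averaged ERPs
#' and a channel neighbour graph, computes the massive-univariate
#' dependent-samples t map for `conditions[1] - conditions[2]`, forms
#' spatio-temporal clusters of samples exceeding the cluster-forming
#' threshold, and evaluates each cluster's mass (sum of t values) against the
#' permutation distribution of the maximal cluster mass, controlling the
#' family-wise error rate. Positive and negative clusters are tested against
#' their own tails; with `tails = "both"` the Monte Carlo p-values are
#' Bonferroni-corrected by doubling.
#'
#' A significant result licenses the statement that the data in the two
#' conditions differ (the exchangeability null is rejected); it does not
#' license inference on the precise location or extent of the cluster.
#'
#' @param data an `erp_dataset`.
#' @param graph a `neighbor_graph` covering the dataset's channels.
#' @param conditions length-2 character vector naming the conditions to
#'   compare (default: the dataset's first two).
#' @param alpha test-level alpha; default 0.05.
#' @param cluster_alpha cluster-forming alpha (two-sided); default 0.05.
#' @param n_randomizations Monte Carlo draw count; default 1000.
#' @param mode `"monte_carlo"` or `"exhaustive"`.
#' @param tails `"both"` or `"one"`.
#' @param seed integer seed; recorded in the result.
#' @param channels,time_window optional subselection applied before testing
#'   (a priori regions of interest).
#' @return An object of class `cluster_perm_test`: the observed `stat_map`,
#'   `clusters` (each with mass, member samples, one-tail and corrected
#'   p-values), the `distribution`, the thresholds and configuration used,
#'   and the seed.
#' @examples
#' sim <- simulate_erp_dataset(sim_config(n_subjects = 8, n_channels = 16,
#'                                        sfreq = 100), seed = 1)
#' g <- neighbors_by_triangulation(sim$layout)
#' fit <- cluster_perm_test(sim$dataset, g, n_randomizations = 200, seed = 1)
#' print(fit)
#' @export
cluster_perm_test <- function(data, graph,
                              conditions = NULL,
                              alpha = 0.05, cluster_alpha = 0.05,
                              n_randomizations = 1000,
                              mode = c("monte_carlo", "exhaustive"),
                              tails = c("both", "one"),
                              seed = NULL,
                              channels = NULL, time_window = NULL) {
  stopifnot(inherits(data, "erp_dataset"))
  mode <- match.arg(mode)
  tails <- match.arg(tails)
  if (is.null(conditions)) conditions <- data$conditions[1:2]
  if (length(conditions) != 2 || !all(conditions %in% data$conditions))
    stop("conditions must name two conditions present in the dataset")
  if (!is.null(channels) || !is.null(time_window))
    data <- subset_erp(data, channels = channels, time_window = time_window)
  A <- data$data[[conditions[1]]]
  B <- data$data[[conditions[2]]]
  map <- paired_t_map(A, B, channels = data$channels, times = data$times)
  masks <- threshold_map(map, alpha_cluster = cluster_alpha, tail = "both")
  clusters <- form_clusters(masks, graph, map)
  dist <- permutation_distribution(A, B, graph,
                                   n_randomizations = n_randomizations,
                                   seed = seed, mode = mode,
                                   cluster_alpha = cluster_alpha,
                                   channels = data$channels,
                                   times = data$times)
  clusters <- cluster_p_values(clusters, dist, alpha = alpha, tails = tails)
  fit <- list(stat_map = map, clusters = clusters, distribution = dist,
              alpha = alpha, cluster_alpha = cluster_alpha,
              crit = dist$crit, tails = tails, mode = mode,
              n_randomizations = dist$n_randomizations, seed = seed,
              conditions = conditions, n_subjects = dim(A)[1],
              channels = data$channels, times = data$times,
              call = match.call())
  class(fit) <- "cluster_perm_test"
  fit
}

#' Estimate permutation-test runtime without revealing p-values
#'
#' Runs a pilot batch of randomizations (default 1000) and linearly
#' extrapolates the wall time to `target_randomizations`. The pilot result is
#' discarded and no p-value is computed or displayed: deciding the
#' randomization count must not be informed by interim significance, which
#' would constitute p-hacking.
#'
#' @param data an `erp_dataset`.
#' @param graph a `neighbor_graph`.
#' @param target_randomizations the intended randomization count.
#' @param conditions,cluster_alpha as in [cluster_perm_test()].
#' @param pilot_randomizations size of the timing batch; default 1000.
#' @return A list with `pilot_seconds`, `estimated_seconds` and
#'   `target_randomizations`.
#' @export
estimate_permutation_runtime <- function(data, graph,
                                         target_randomizations,
                                         conditions = NULL,
                                         cluster_alpha = 0.05,
                                         pilot_randomizations = 1000) {
  stopifnot(inherits(data, "erp_dataset"))
  if (is.null(conditions)) conditions <- data$conditions[1:2]
  A <- data$data[[conditions[1]]]
  B <- data$data[[conditions[2]]]
  elapsed <- system.time(
    permutation_distribution(A, B, graph,
                             n_randomizations = pilot_randomizations,
                             seed = 0, mode = "monte_carlo",
                             cluster_alpha = cluster_alpha,
                             channels = data$channels)
  )[["elapsed"]]
  list(pilot_seconds = elapsed,
       estimated_seconds = elapsed * target_randomizations / pilot_randomizations,
       target_randomizations = target_randomizations)
}

#' @export
print.cluster_perm_test <- function(x, max_clusters = 10, ...) {
  cat("Cluster-based permutation test (paired design)\n")
  cat(sprintf("  conditions: %s - %s, n = %d subjects\n",
              x$conditions[1], x$conditions[2], x$n_subjects))
  cat(sprintf("  %s, %d randomizations; cluster-forming |t| > %.4f; alpha = %g (%s tails)\n",
              x$mode, x$n_randomizations, x$crit, x$alpha, x$tails))
  if (!length(x$clusters)) {
    cat("  no suprathreshold clusters; no evidence against exchangeability\n")
    return(invisible(x))
  }
  show <- seq_len(min(length(x$clusters), max_clusters))
  for (i in show) {
    cl <- x$clusters[[i]]
    cat(sprintf("  [%d] %s: mass = %.2f, %d samples, %.0f..%.0f ms, %s%s\n",
                i, cl$polarity, cl$mass, cl$size,
                cl$time_range[1] * 1000, cl$time_range[2] * 1000,
                format_p(cl$p_corrected, x$n_randomizations, x$tails),
                if (isTRUE(cl$significant)) " *" else ""))
  }
  if (length(x$clusters) > max_clusters)
    cat("  ... and", length(x$clusters) - max_clusters, "smaller cluster(s)\n")
  invisible(x)
}

#' @export
summary.cluster_perm_test <- function(object, ...) {
  cl <- object$clusters
  df <- if (length(cl)) data.frame(
    cluster = seq_along(cl),
    polarity = vapply(cl, `[[`, character(1), "polarity"),
    mass = vapply(cl, `[[`, numeric(1), "mass"),
    n_samples = vapply(cl, `[[`, numeric(1), "size"),
    n_channels = vapply(cl, function(z) length(z$channels), numeric(1)),
    t_start = vapply(cl, function(z) z$time_range[1], numeric(1)),
    t_end = vapply(cl, function(z) z$time_range[2], numeric(1)),
    p = vapply(cl, `[[`, numeric(1), "p"),
    p_corrected = vapply(cl, `[[`, numeric(1), "p_corrected"),
    significant = vapply(cl, `[[`, logical(1), "significant"),
    stringsAsFactors = FALSE
  ) else data.frame()
  out <- list(table = df, conditions = object$conditions,
              alpha = object$alpha, n_randomizations = object$n_randomizations,
              mode = object$mode, n_subjects = object$n_subjects)
  class(out) <- "summary.cluster_perm_test"
  out
}

#' @export
print.summary.cluster_perm_test <- function(x, ...) {
  cat(sprintf("Cluster permutation test summary: %s vs %s (n = %d, %s, B = %d)\n",
              x$conditions[1], x$conditions[2], x$n_subjects, x$mode,
              x$n_randomizations))
  if (nrow(x$table)) print(x$table, row.names = FALSE)
  else cat("no suprathreshold clusters\n")
  invisible(x)
}

# p rendered as an inequality at the estimator's floor (observed mass beat
# every draw); never "p = 0"
format_p <- function(p, B, tails = "both") {
  floorp <- if (tails == "both") 2 / (B + 1) else 1 / (B + 1)
  if (p <= floorp + 1e-12) sprintf("p < %.4g", floorp)
  else sprintf("p = %.4g", p)
}
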