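# Massive-univariate statistic maps over the channels x timepoints grid.
# Zero-variance samples yield t = sign(mean) * 1e10 with a warning rather
# than NaN, so downstream thresholding and clustering stay well defined.

T_LARGE <- 1e10

new_stat_map <- function(t, df, statistic, channels, times) {
  stopifnot(is.matrix(t))
  m <- list(t = t, df = df, statistic = statistic,
            channels = channels, times = times)
  class(m) <- "stat_map"
  m
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("Statistic map (%s, df = %g): %d channels x %d timepoints, range [%.3f, %.3f]\n",
              x$statistic, x$df, nrow(x$t), ncol(x$t), min(x$t), max(x$t)))
  invisible(x)
}

# t-statistics for each column of an n x m matrix of per-subject differences
.paired_t_cols <- function(D) {
  n <- nrow(D)
  m <- colMeans(D)
  v <- (colSums(D * D) - n * m * m) / (n - 1)
  v[v < 0] <- 0
  se <- sqrt(v / n)
  zv <- se == 0
  t <- m / se
  if (any(zv)) {
    t[zv] <- sign(m[zv]) * T_LARGE
    warning("zero variance at ", sum(zv), " sample(s); t set to +/-1e10")
  }
  t
}

#' Dependent-samples t map
#'
#' Per channel-time sample, the paired t statistic of `condA - condB`
#' across subjects: `t = mean(d) / (sd(d)/sqrt(n))`, `sd` with the `n - 1`
#' denominator, `df = n - 1`.
#'
#' @param condA,condB numeric arrays `subjects x channels x timepoints` of
#'   equal shape, subjects matched by position.
#' @param channels,times optional labels for the grid; defaults to indices.
#' @return A `stat_map`.
#' @examples
#' a <- array(rnorm(5 * 2 * 3), c(5, 2, 3))
#' b <- array(rnorm(5 * 2 * 3), c(5, 2, 3))
#' paired_t_map(a, b)
#' @export
paired_t_map <- function(condA, condB, channels = NULL, times = NULL) {
  if (!identical(dim(condA), dim(condB))) stop("condition arrays must have equal shape")
  d <- dim(condA)
  if (length(d) != 3) stop("arrays must be subjects x channels x timepoints")
  n <- d[1]
  if (n < 2) stop("need at least 2 subjects")
  D <- matrix(condA - condB, nrow = n)
  tv <- .paired_t_cols(D)
  if (is.null(channels)) channels <- as.character(seq_len(d[2]))
  if (is.null(times)) times <- seq_len(d[3])
  new_stat_map(matrix(tv, d[2], d[3]), df = n - 1, statistic = "paired_t",
               channels = channels, times = times)
}

#' Independent-samples t map
#'
#' Pooled-variance two-sample t per sample, `df = nA + nB - 2`.
#'
#' @param groupA,groupB numeric arrays `subjects x channels x timepoints`
#'   with identical channel/time dimensions.
#' @param channels,times optional grid labels.
#' @return A `stat_map`.
#' @export
independent_t_map <- function(groupA, groupB, channels = NULL, times = NULL) {
  da <- dim(groupA); db <- dim(groupB)
  if (length(da) != 3 || length(db) != 3 || !identical(da[2:3], db[2:3]))
    stop("groups must share channel/time dimensions")
  na <- da[1]; nb <- db[1]
  if (na < 2 || nb < 2) stop("need at least 2 subjects per group")
  A <- matrix(groupA, nrow = na); B <- matrix(groupB, nrow = nb)
  ma <- colMeans(A); mb <- colMeans(B)
  va <- (colSums(A * A) - na * ma * ma) / (na - 1)
  vb <- (colSums(B * B) - nb * mb * mb) / (nb - 1)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  zv <- se == 0
  t <- (ma - mb) / se
  if (any(zv)) {
    t[zv] <- sign((ma - mb)[zv]) * T_LARGE
    warning("zero variance at ", sum(zv), " sample(s); t set to +/-1e10")
  }
  if (is.null(channels)) channels <- as.character(seq_len(da[2]))
  if (is.null(times)) times <- seq_len(da[3])
  new_stat_map(matrix(t, da[2], da[3]), df = na + nb - 2,
               statistic = "independent_t", channels = channels, times = times)
}

#' Across-subject regression-slope t map
#'
#' Per sample, the t statistic of the slope from regressing the subjects'
#' values on a per-subject regressor; `df = n - 2`.
#'
#' @param data numeric array `subjects x channels x timepoints`.
#' @param regressor numeric vector, one value per subject, non-constant.
#' @param channels,times optional grid labels.
#' @return A `stat_map`.
#' @export
regression_map <- function(data, regressor, channels = NULL, times = NULL) {
  d <- dim(data)
  if (length(d) != 3) stop("data must be subjects x channels x timepoints")
  n <- d[1]
  if (n < 3) stop("need at least 3 subjects")
  if (length(regressor) != n) stop("regressor length must equal number of subjects")
  if (stats::var(regressor) == 0) stop("regressor has no variance")
  X <- regressor - mean(regressor)
  sxx <- sum(X * X)
  Y <- matrix(data, nrow = n)
  beta <- as.vector(crossprod(X, Y)) / sxx
  my <- colMeans(Y)
  # residual sum of squares without forming residual matrices twice
  syy <- colSums(Y * Y) - n * my * my
  rss <- syy - beta^2 * sxx
  rss[rss < 0] <- 0
  se <- sqrt(rss / (n - 2) / sxx)
  zv <- se == 0
  t <- beta / se
  if (any(zv)) {
    t[zv] <- sign(beta[zv]) * T_LARGE
    warning("zero residual variance at ", sum(zv), " sample(s); t set to +/-1e10")
  }
  if (is.null(channels)) channels <- as.character(seq_len(d[2]))
  if (is.null(times)) times <- seq_len(d[3])
  new_stat_map(matrix(t, d[2], d[3]), df = n - 2, statistic = "regression",
               channels = channels, times = times)
}

#' Threshold a statistic map into suprathreshold masks
#'
#' The cluster-forming threshold is the two-sided critical t value at
#' `alpha_cluster` for the map's degrees of freedom. The positive mask marks
#' samples with `t > +crit`, the negative mask `t < -crit`; the `tail`
#' argument selects which masks are populated.
#'
#' @param map a `stat_map`.
#' @param alpha_cluster cluster-forming alpha in (0, 1); default 0.05.
#' @param tail `"both"`, `"pos"` or `"neg"`.
#' @return A list of class `threshold_masks`: logical matrices `pos` and
#'   `neg`, the critical value `crit`, `alpha_cluster` and `tail`.
#' @export
threshold_map <- function(map, alpha_cluster = 0.05, tail = c("both", "pos", "neg")) {
  stopifnot(inherits(map, "stat_map"))
  tail <- match.arg(tail)
  if (!is.numeric(alpha_cluster) || length(alpha_cluster) != 1 ||
      alpha_cluster <= 0 || alpha_cluster >= 1)
    stop("alpha_cluster must be in (0, 1)")
  if (map$df < 1) stop("degrees of freedom must be >= 1")
  crit <- stats::qt(1 - alpha_cluster / 2, df = map$df)
  pos <- map$t > crit
  neg <- map$t < -crit
  if (tail == "pos") neg[] <- FALSE
  if (tail == "neg") pos[] <- FALSE
  out <- list(pos = pos, neg = neg, crit = crit,
              alpha_cluster = alpha_cluster, tail = tail)
  class(out) <- "threshold_masks"
  out
}
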