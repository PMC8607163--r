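# Deterministic single-subject pipeline: continuous recording -> epochs ->
# band-pass filter -> whole-epoch baseline -> automated artifact rejection
# (condition-blind) -> bad-channel interpolation -> linked-mastoid
# re-reference -> per-condition averages; plus the group-level trial-retention
# inclusion rule.

new_epochs <- function(data, times, channels, sfreq, condition,
                       bad_trials = NULL, bad_channels = character()) {
  stopifnot(length(dim(data)) == 3)
  if (is.null(bad_trials)) bad_trials <- rep(FALSE, dim(data)[1])
  ep <- list(data = data, times = times, channels = channels, sfreq = sfreq,
             condition = condition, bad_trials = bad_trials,
             bad_channels = bad_channels)
  class(ep) <- "erp_epochs"
  ep
}

#' @export
print.erp_epochs <- function(x, ...) {
  cat(sprintf("Epochs: %d trials x %d channels x %d samples (%.3f..%.3f s at %g Hz)\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              min(x$times), max(x$times), x$sfreq))
  cat("conditions:", paste(sprintf("%s=%d", names(table(x$condition)),
                                   table(x$condition)), collapse = ", "), "\n")
  if (any(x$bad_trials)) cat("rejected trials:", sum(x$bad_trials), "\n")
  if (length(x$bad_channels)) cat("bad channels:",
                                  paste(x$bad_channels, collapse = ", "), "\n")
  invisible(x)
}

#' Segment a continuous recording into stimulus-locked epochs
#'
#' Epoch windows follow the half-open convention `[onset + window[1],
#' onset + window[2])` with 0-based stimulus samples, giving exactly
#' `(window[2] - window[1]) * sfreq` samples per epoch (750 at 500 Hz for
#' the default -0.5..1.0 s window). The event's integer `sample` column is
#' authoritative for the onset; `onset` seconds are used only if `sample` is
#' absent.
#'
#' The default `"oddball"` selection policy keeps oddball trials and all
#' standard trials except the first standard of a sequence and the standard
#' immediately following an oddball (only repeated standards enter the
#' standard average). `"all"` keeps every event.
#'
#' @param recording an `erp_recording` (list with `data` channels x samples,
#'   `sfreq`, `channels`).
#' @param events a data.frame with `trial_type` and `sample` (0-based) or
#'   `onset` (seconds); an optional `sequence` column marks sequence
#'   membership for the selection policy.
#' @param window epoch window in seconds, default `c(-0.5, 1.0)`.
#' @param policy `"oddball"` or `"all"`.
#' @return An `erp_epochs` object.
#' @export
segment_epochs <- function(recording, events, window = c(-0.5, 1.0),
                           policy = c("oddball", "all")) {
  policy <- match.arg(policy)
  X <- recording$data
  fs <- recording$sfreq
  ns <- ncol(X)
  s0 <- if ("sample" %in% names(events)) as.integer(events$sample)
        else as.integer(round(events$onset * fs))
  keep <- rep(TRUE, nrow(events))
  if (policy == "oddball") {
    is_std <- events$trial_type == "standard"
    seqid <- if ("sequence" %in% names(events)) events$sequence
             else rep(1L, nrow(events))
    prev_odd <- c(FALSE, events$trial_type[-nrow(events)] == "oddball")
    # first standard within each sequence
    first_std <- rep(FALSE, nrow(events))
    for (sq in unique(seqid)) {
      i <- which(is_std & seqid == sq)
      if (length(i)) first_std[i[1]] <- TRUE
    }
    keep <- !is_std | (!first_std & !prev_odd)
  }
  ev <- events[keep, , drop = FALSE]
  s0 <- s0[keep]
  nsamp <- round((window[2] - window[1]) * fs)
  rel <- round(window[1] * fs) + seq_len(nsamp) - 1L
  lo <- s0 + 1L + min(rel)
  hi <- s0 + 1L + max(rel)
  bad <- lo < 1L | hi > ns
  if (any(bad))
    stop("epoch window exceeds recording bounds for event(s) at onset ",
         paste(round(ev$onset[bad], 3), collapse = ", "), " s")
  nev <- nrow(ev)
  data <- array(0, c(nev, nrow(X), nsamp))
  for (i in seq_len(nev)) data[i, , ] <- X[, s0[i] + 1L + rel]
  new_epochs(data, times = (round(window[1] * fs) + seq_len(nsamp) - 1L) / fs,
             channels = recording$channels, sfreq = fs,
             condition = ev$trial_type)
}

# mirror-pad a matrix (channels x samples) by repeated reflection
.mirror_pad <- function(M, npad) {
  n <- ncol(M)
  # reflect indices around 1 and n, repeating as needed (period 2n - 2)
  reflect <- function(k) {
    # map arbitrary integer k (may be <1 or >n) into 1..n by mirror rule
    p <- 2L * n - 2L
    k <- (k - 1L) %% p
    ifelse(k < n, k + 1L, p - k + 1L)
  }
  left <- reflect(seq(1L - npad, 0L))
  right <- reflect(seq(n + 1L, n + npad))
  cbind(M[, left, drop = FALSE], M, M[, right, drop = FALSE])
}

#' Zero-phase band-pass filter epochs
#'
#' Forward-backward (zero-phase) 4th-order Butterworth band-pass per pass,
#' applied to mirror-padded epochs; the padding (default 5 s, by repeated
#' reflection since epochs are shorter than the pad) is removed afterwards,
#' so the shape is preserved.
#'
#' @param epochs an `erp_epochs`.
#' @param low,high band edges in Hz, `0 < low < high < sfreq/2`.
#' @param pad padding duration in seconds (default 5).
#' @return Filtered `erp_epochs`.
#' @export
bandpass_filter <- function(epochs, low = 1, high = 30, pad = 5) {
  fs <- epochs$sfreq
  if (!(low > 0 && high > low)) stop("need 0 < low < high")
  if (high >= fs / 2) stop("high edge must be below the Nyquist frequency (",
                           fs / 2, " Hz)")
  bf <- signal::butter(4, c(low, high) / (fs / 2), type = "pass")
  npad <- round(pad * fs)
  d <- dim(epochs$data)
  out <- epochs$data
  for (i in seq_len(d[1])) {
    M <- matrix(epochs$data[i, , ], d[2], d[3])
    P <- .mirror_pad(M, npad)
    F <- t(apply(P, 1, function(x) signal::filtfilt(bf, x)))
    out[i, , ] <- F[, npad + seq_len(d[3])]
  }
  epochs$data <- out
  epochs
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean over the baseline window.
#' The default window is the entire epoch (whole-epoch baseline).
#'
#' @param epochs an `erp_epochs`.
#' @param window `"whole"` or `c(t_min, t_max)` seconds.
#' @return Baseline-corrected `erp_epochs`. Idempotent.
#' @export
baseline_correct <- function(epochs, window = "whole") {
  if (identical(window, "whole")) {
    sel <- seq_along(epochs$times)
  } else {
    sel <- which(epochs$times >= window[1] & epochs$times <= window[2])
    if (!length(sel)) stop("baseline window overlaps no timepoints")
  }
  d <- dim(epochs$data)
  bl <- apply(epochs$data[, , sel, drop = FALSE], c(1, 2), mean)
  epochs$data <- epochs$data - array(rep(bl, d[3]), d)
  epochs
}

#' Automated amplitude-based artifact rejection
#'
#' A reproducible, condition-blind stand-in for interactive artifact
#' screening: a channel is marked bad when its peak-to-peak amplitude
#' exceeds `amplitude_limit` (or falls below `flat_limit`) on more than
#' `bad_channel_fraction` of trials; a trial is then rejected when any
#' remaining good channel exceeds the limits on it. Condition labels are
#' never consulted.
#'
#' @param epochs an `erp_epochs`.
#' @param amplitude_limit peak-to-peak rejection threshold in volts
#'   (default 200e-6).
#' @param flat_limit minimal peak-to-peak amplitude in volts (default 0;
#'   set > 0 to catch flat channels).
#' @param bad_channel_fraction fraction of artifact trials above which a
#'   channel is marked bad (default 0.3).
#' @param subject subject identifier recorded in the log.
#' @return A list with `epochs` (flags set) and `log` (a `rejection_log`:
#'   `subject`, `n_trials_total`, `n_trials_rejected`, `rejected_trials`,
#'   `rejected_channels`).
#' @export
reject_artifacts_auto <- function(epochs, amplitude_limit = 200e-6,
                                  flat_limit = 0, bad_channel_fraction = 0.3,
                                  subject = "sub-01") {
  if (amplitude_limit <= 0) stop("amplitude_limit must be positive")
  d <- dim(epochs$data)
  ptp <- apply(epochs$data, c(1, 2), function(x) max(x) - min(x))
  artifact <- ptp > amplitude_limit | ptp < flat_limit
  ch_bad_frac <- colMeans(artifact)
  bad_ch <- epochs$channels[ch_bad_frac > bad_channel_fraction]
  good <- !(epochs$channels %in% c(bad_ch, epochs$bad_channels))
  bad_trial <- if (any(good))
    apply(artifact[, good, drop = FALSE], 1, any) else rep(FALSE, d[1])
  epochs$bad_trials <- epochs$bad_trials | bad_trial
  epochs$bad_channels <- union(epochs$bad_channels, bad_ch)
  log <- list(subject = subject, n_trials_total = d[1],
              n_trials_rejected = sum(epochs$bad_trials),
              rejected_trials = which(epochs$bad_trials),
              rejected_channels = epochs$bad_channels)
  class(log) <- "rejection_log"
  list(epochs = epochs, log = log)
}

#' @export
print.rejection_log <- function(x, ...) {
  cat(sprintf("%s: %d/%d trials rejected; bad channels: %s\n", x$subject,
              x$n_trials_rejected, x$n_trials_total,
              if (length(x$rejected_channels))
                paste(x$rejected_channels, collapse = ", ") else "none"))
  invisible(x)
}

#' Interpolate bad channels from their neighbours
#'
#' Replaces each bad channel by the inverse-distance-weighted average of its
#' good neighbours in the graph (equal weights when the graph carries no
#' layout coordinates). Good channels are untouched.
#'
#' @param epochs an `erp_epochs` with `bad_channels` set.
#' @param graph a `neighbor_graph` covering the epochs' channels.
#' @return `erp_epochs` with bad channels replaced and unflagged.
#' @export
interpolate_bad_channels <- function(epochs, graph) {
  if (!length(epochs$bad_channels)) return(epochs)
  chans <- epochs$channels
  lay <- graph$layout
  for (bc in epochs$bad_channels) {
    nb <- setdiff(graph$neighbors[[bc]], epochs$bad_channels)
    nb <- intersect(nb, chans)
    if (!length(nb))
      stop("bad channel ", bc, " has no good neighbour to interpolate from")
    if (!is.null(lay)) {
      i0 <- match(bc, lay$name); ii <- match(nb, lay$name)
      w <- 1 / sqrt((lay$x[ii] - lay$x[i0])^2 + (lay$y[ii] - lay$y[i0])^2)
    } else {
      w <- rep(1, length(nb))
    }
    w <- w / sum(w)
    bi <- match(bc, chans)
    ni <- match(nb, chans)
    acc <- 0
    for (k in seq_along(ni)) acc <- acc + w[k] * epochs$data[, ni[k], ]
    epochs$data[, bi, ] <- acc
  }
  epochs$bad_channels <- character()
  epochs
}

#' Re-reference epochs to a channel set
#'
#' Subtracts the mean of the reference channels (default linked mastoids
#' TP9/TP10) from every channel at every sample.
#'
#' @param epochs an `erp_epochs`.
#' @param reference character vector of reference channels; must exist and
#'   not be flagged bad.
#' @return Re-referenced `erp_epochs`. Idempotent for a fixed reference.
#' @export
rereference <- function(epochs, reference = c("TP9", "TP10")) {
  if (!length(reference)) stop("reference channel set is empty")
  ri <- match(reference, epochs$channels)
  if (anyNA(ri)) stop("missing reference channel(s): ",
                      paste(reference[is.na(ri)], collapse = ", "))
  if (any(reference %in% epochs$bad_channels))
    stop("reference channel flagged bad; interpolate first")
  ref <- apply(epochs$data[, ri, , drop = FALSE], c(1, 3), mean)
  d <- dim(epochs$data)
  epochs$data <- epochs$data - aperm(array(ref, c(d[1], d[3], d[2])), c(1, 3, 2))
  epochs
}

#' Average epochs per condition
#'
#' Arithmetic mean over unrejected trials, separately per condition.
#'
#' @param epochs an `erp_epochs`.
#' @param conditions conditions to average (default: all present).
#' @return A `subject_average`: list with `conditions` (named list of
#'   channels x times matrices), `n_trials`, `channels`, `times`, `sfreq`.
#' @export
average_by_condition <- function(epochs, conditions = NULL) {
  if (is.null(conditions)) conditions <- unique(epochs$condition)
  keep <- !epochs$bad_trials
  avgs <- list(); ntr <- integer()
  for (cn in conditions) {
    sel <- keep & epochs$condition == cn
    if (!any(sel)) stop("no unrejected trials for condition '", cn, "'")
    avgs[[cn]] <- apply(epochs$data[sel, , , drop = FALSE], c(2, 3), mean)
    ntr[cn] <- sum(sel)
  }
  out <- list(conditions = avgs, n_trials = ntr, channels = epochs$channels,
              times = epochs$times, sfreq = epochs$sfreq)
  class(out) <- "subject_average"
  out
}

#' Apply the trial-retention inclusion rule
#'
#' A subject is excluded iff strictly more than `max_rejected_fraction` of
#' their trials were rejected (default 0.70: rejecting more than 70% of
#' trials leaves at most 0.3 N trials, inflating the within-subject SEM by
#' about a factor 2, see [sem_inflation_factor()]).
#'
#' @param logs list of `rejection_log` objects.
#' @param max_rejected_fraction default 0.7; exclusion uses strict `>`.
#' @return A list with `included`, `excluded` (subject ids) and `fraction`
#'   (named numeric vector of rejected fractions).
#' @export
exclude_subjects <- function(logs, max_rejected_fraction = 0.7) {
  if (!length(logs)) stop("no rejection logs supplied")
  ids <- vapply(logs, `[[`, character(1), "subject")
  tot <- vapply(logs, `[[`, numeric(1), "n_trials_total")
  rej <- vapply(logs, `[[`, numeric(1), "n_trials_rejected")
  if (any(tot == 0)) stop("rejection log with zero total trials: ",
                          paste(ids[tot == 0], collapse = ", "))
  frac <- stats::setNames(rej / tot, ids)
  excl <- frac > max_rejected_fraction
  list(included = ids[!excl], excluded = ids[excl], fraction = frac)
}

#' SEM inflation from trial loss
#'
#' Keeping a fraction `f` of the trials inflates the within-subject standard
#' error of the mean by `sqrt(1 / f)`; keeping 30% of the trials gives a
#' factor of about 2, the rationale behind the 70%-rejection exclusion rule.
#'
#' @param kept_fraction fraction of trials retained, in (0, 1].
#' @return `sqrt(1 / kept_fraction)`.
#' @examples
#' sem_inflation_factor(0.3)   # 1.826 ~ 2
#' sem_inflation_factor(0.25)  # 2
#' @export
sem_inflation_factor <- function(kept_fraction) {
  if (any(kept_fraction <= 0) || any(kept_fraction > 1))
    stop("kept_fraction must be in (0, 1]")
  sqrt(1 / kept_fraction)
}

#' Run the full single-subject preprocessing pipeline
#'
#' segment -> band-pass -> whole-epoch baseline -> automated rejection ->
#' interpolation -> linked-mastoid re-reference -> per-condition averages.
#'
#' @param recording an `erp_recording`.
#' @param events event data.frame (see [segment_epochs()]).
#' @param graph a `neighbor_graph` (for interpolation).
#' @param subject subject identifier for the log.
#' @param window,band,pad,reject_uv,reference pipeline parameters; reference
#'   channels absent from the montage are dropped (no re-referencing when
#'   none remain, e.g. a montage without mastoid channels).
#' @return A list with `average` (a `subject_average`) and `log`
#'   (a `rejection_log`); `average` is NULL when every trial of some
#'   condition was rejected.
#' @export
preprocess_subject <- function(recording, events, graph,
                               subject = "sub-01",
                               window = c(-0.5, 1.0), band = c(1, 30),
                               pad = 5, reject_uv = 200,
                               reference = c("TP9", "TP10")) {
  ep <- segment_epochs(recording, events, window = window, policy = "oddball")
  ep <- bandpass_filter(ep, band[1], band[2], pad = pad)
  ep <- baseline_correct(ep, "whole")
  rj <- reject_artifacts_auto(ep, amplitude_limit = reject_uv * 1e-6,
                              subject = subject)
  ep <- rj$epochs
  ep <- interpolate_bad_channels(ep, graph)
  reference <- intersect(reference, ep$channels)
  if (length(reference)) ep <- rereference(ep, reference)
  avg <- tryCatch(average_by_condition(ep), error = function(e) NULL)
  list(average = avg, log = rj$log)
}

#' Combine subject averages into a group ERP dataset
#'
#' @param averages named list of `subject_average` objects (names = subject
#'   ids) sharing channels, times and condition sets.
#' @return An [erp_dataset()].
#' @export
combine_subject_averages <- function(averages) {
  if (!length(averages)) stop("no subject averages supplied")
  a1 <- averages[[1]]
  conds <- names(a1$conditions)
  ns <- length(averages)
  data <- lapply(conds, function(cn)
    array(0, c(ns, length(a1$channels), length(a1$times))))
  names(data) <- conds
  for (s in seq_len(ns)) {
    as_ <- averages[[s]]
    if (!identical(as_$channels, a1$channels))
      stop("subject averages have mismatching channels")
    for (cn in conds) data[[cn]][s, , ] <- as_$conditions[[cn]]
  }
  subjects <- names(averages)
  if (is.null(subjects)) subjects <- sprintf("sub-%02d", seq_len(ns))
  erp_dataset(data, a1$channels, a1$times, subjects)
}
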