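# Seeded oddball-ERP simulator with analytic ground truth.
#
# Generative model for a subject's condition-average ERP (volts):
#   avg[s, c] = offset[s] + gain[s] * mu_c + eps[s, c]
# where mu_c is the deterministic condition mean (a Gaussian-windowed
# negative fronto-central deflection whose latency and amplitude differ
# between conditions, times a Gaussian spatial profile), gain[s] = 1 + N(0,
# gain_sd) is a subject-level amplitude gain shared across conditions,
# offset[s] is a per-channel offset shared across conditions (cancels in the
# paired difference), and eps is zero-mean noise with unit-variance
# spatio-temporal correlation (exponential spatial kernel, AR(1) in time)
# scaled to sigma_uv / sqrt(n_trials_condition).
#
# The paired difference at sample j is gain[s] * dmu[j] + noise, so the true
# pointwise paired Cohen's d is analytic:
#   d(j) = dmu(j) / sqrt(gain_sd^2 dmu(j)^2 + sigma_A^2 + sigma_B^2)
# and the effect amplitude can be calibrated in closed form to hit a target
# peak d.

#' Simulation configuration
#'
#' Defaults emulate an infant oddball ERP study: 48 analysed subjects, a
#' 32-channel 10-20 montage sampled at 500 Hz, epochs from -0.5 to 1.0 s,
#' 90 standard and 50 oddball trials, and an Nc-like negative fronto-central
#' deflection peaking earlier for oddballs than for standards.
#'
#' @param n_subjects number of subjects (default 48).
#' @param n_channels number of channels, up to 32; the first `n_channels`
#'   of [layout_1020_32()] are used unless `layout` is given.
#' @param layout optional `erp_layout` overriding the template.
#' @param sfreq sampling rate in Hz (default 500).
#' @param window epoch window `c(pre, post)` in seconds, half-open on the
#'   right (default `c(-0.5, 1.0)`, i.e. 750 samples at 500 Hz).
#' @param n_trials named vector of trials per condition
#'   (default `c(standard = 90, oddball = 50)`).
#' @param peak_latency named vector of Nc peak latencies in seconds
#'   (default standard 0.55, oddball 0.45: the oddball peak is faster).
#' @param peak_width temporal Gaussian sd of the deflection in seconds
#'   (default 0.10: the Nc is a broad deflection spanning a few hundred ms).
#' @param center_channel channel carrying the peak of the spatial profile.
#' @param spatial_decay Gaussian decay length of the topography in layout
#'   units (default 0.8: a fronto-central component that, like the observed
#'   infant Nc difference, extends over most of the cap).
#' @param effect_d target true peak pointwise paired d; the deflection
#'   amplitude difference is calibrated to it (default 0.8). Ignored when
#'   `amplitude_uv` is given.
#' @param amplitude_uv optional explicit condition amplitudes in microvolts,
#'   named like `n_trials`; negative values give a negative deflection.
#' @param noise_uv trial-level noise sd in microvolts (default 20).
#' @param spatial_corr_length exponential correlation length of the noise
#'   over the layout, in layout units (default 1.5: volume-conducted scalp
#'   fields are strongly correlated between neighbouring electrodes,
#'   r of about 0.8).
#' @param noise_tau temporal correlation time constant of the noise in
#'   seconds (default 0.2: residual noise in 1-30 Hz band-passed subject
#'   averages is dominated by its low-frequency end). Internally realised as
#'   an AR(1) with per-sample coefficient `exp(-1 / (sfreq * noise_tau))`;
#'   0 gives temporally white noise.
#' @param gain_sd sd of the subject amplitude gain (default 0.2).
#' @param offset_uv sd of the per-channel subject offset in microvolts
#'   (default 1).
#' @param soa stimulus-onset asynchrony in seconds for continuous
#'   recordings (default 2.0, plus up to 0.4 s uniform jitter).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 48, n_channels = 32, layout = NULL,
                       sfreq = 500, window = c(-0.5, 1.0),
                       n_trials = c(standard = 90, oddball = 50),
                       peak_latency = c(standard = 0.55, oddball = 0.45),
                       peak_width = 0.10,
                       center_channel = "FCz", spatial_decay = 0.8,
                       effect_d = 0.8, amplitude_uv = NULL,
                       noise_uv = 20, spatial_corr_length = 1.5,
                       noise_tau = 0.2, gain_sd = 0.2, offset_uv = 1,
                       soa = 2.0) {
  if (is.null(layout)) {
    full <- layout_1020_32()
    if (n_channels > nrow(full)) stop("template layout has 32 channels")
    layout <- erp_layout(full$name[seq_len(n_channels)],
                         full$x[seq_len(n_channels)],
                         full$y[seq_len(n_channels)])
  }
  if (!(center_channel %in% layout$name)) center_channel <- layout$name[1]
  if (n_subjects < 1 || any(n_trials < 1)) stop("counts must be positive")
  if (window[1] >= window[2]) stop("invalid epoch window")
  if (any(peak_latency <= window[1]) || any(peak_latency >= window[2]))
    stop("peak latencies must lie inside the epoch window")
  cfg <- list(n_subjects = n_subjects, layout = layout, sfreq = sfreq,
              window = window, n_trials = n_trials,
              peak_latency = peak_latency, peak_width = peak_width,
              center_channel = center_channel, spatial_decay = spatial_decay,
              effect_d = effect_d, amplitude_uv = amplitude_uv,
              noise_uv = noise_uv, spatial_corr_length = spatial_corr_length,
              noise_tau = noise_tau, gain_sd = gain_sd,
              offset_uv = offset_uv, soa = soa)
  class(cfg) <- "sim_config"
  cfg
}

.sim_times <- function(cfg) {
  n <- round((cfg$window[2] - cfg$window[1]) * cfg$sfreq)
  cfg$window[1] + (seq_len(n) - 1) / cfg$sfreq
}

# spatial profile: Gaussian decay from the centre channel, peak 1
.sim_topography <- function(cfg) {
  lay <- cfg$layout
  i0 <- match(cfg$center_channel, lay$name)
  d2 <- (lay$x - lay$x[i0])^2 + (lay$y - lay$y[i0])^2
  exp(-d2 / (2 * cfg$spatial_decay^2))
}

# condition means (volts, channels x times) and their difference, given the
# per-condition amplitudes in volts (negative deflection)
.sim_means <- function(cfg, amp_v) {
  times <- .sim_times(cfg)
  topo <- .sim_topography(cfg)
  mu <- lapply(names(cfg$n_trials), function(cond) {
    shape <- exp(-(times - cfg$peak_latency[[cond]])^2 / (2 * cfg$peak_width^2))
    amp_v[[cond]] * outer(topo, shape)
  })
  names(mu) <- names(cfg$n_trials)
  mu
}

# condition amplitudes in volts: explicit, or calibrated so that the peak of
# the true pointwise d map equals effect_d
.sim_amplitudes <- function(cfg) {
  conds <- names(cfg$n_trials)
  if (!is.null(cfg$amplitude_uv)) {
    return(vapply(conds, function(cn) cfg$amplitude_uv[[cn]] * 1e-6,
                  numeric(1)))
  }
  # unit-amplitude difference shape, its peak magnitude K
  unit <- stats::setNames(rep(-1e-6, length(conds)), conds)
  mu_unit <- .sim_means(cfg, unit)
  K <- max(abs(mu_unit[[1]] - mu_unit[[2]])) / 1e-6  # per microvolt of amplitude
  sig2 <- sum((cfg$noise_uv * 1e-6)^2 / cfg$n_trials[conds[1:2]])
  d <- cfg$effect_d
  if (d <= 0 || K == 0) {
    a_uv <- 0
  } else {
    denom <- 1 - d^2 * cfg$gain_sd^2
    if (denom <= 0) stop("effect_d unattainable at this gain_sd")
    a_uv <- d * sqrt(sig2) / sqrt(denom) / (K * 1e-6)
  }
  # both conditions share the deflection amplitude (latency-shift effect);
  # calibration scales the common amplitude
  stats::setNames(rep(-a_uv * 1e-6, length(conds)), conds)
}

# true pointwise paired d map for a latency-shift effect
.sim_true_d <- function(cfg, mu) {
  conds <- names(cfg$n_trials)
  dmu <- mu[[conds[1]]] - mu[[conds[2]]]
  sig2 <- sum((cfg$noise_uv * 1e-6)^2 / cfg$n_trials[conds[1:2]])
  dmu / sqrt(cfg$gain_sd^2 * dmu^2 + sig2)
}

# per-sample AR(1) coefficient realising the configured time constant
.sim_rho <- function(cfg) {
  if (cfg$noise_tau <= 0) 0 else exp(-1 / (cfg$sfreq * cfg$noise_tau))
}

# unit-variance spatio-temporal noise: channels x times
.sim_noise <- function(nch, nt, Lspat, ar1) {
  Z <- matrix(stats::rnorm(nch * nt), nch, nt)
  if (ar1 != 0) {
    s <- sqrt(1 - ar1^2)
    for (t in 2:nt) Z[, t] <- ar1 * Z[, t - 1] + s * Z[, t]
  }
  Lspat %*% Z
}

.sim_chol <- function(cfg) {
  lay <- cfg$layout
  D <- as.matrix(stats::dist(cbind(lay$x, lay$y)))
  C <- exp(-D / cfg$spatial_corr_length)
  t(chol(C + diag(1e-10, nrow(C))))
}

# per-subject RNG substreams derived from one root seed
.sub_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max, n)
}

#' Simulate a group-level oddball ERP dataset with known ground truth
#'
#' Draws per-subject condition-average ERPs from the generative model
#' described in the package vignette: a condition-specific Nc-like negative
#' deflection (latency-shift effect by default) plus spatially and temporally
#' correlated noise and between-subject gain/offset variability. A fixed seed
#' yields bit-identical output.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return A list with `dataset` (an [erp_dataset()]), `ground_truth` (list:
#'   `d_map` channels x times matrix of true pointwise paired d, `effect_mask`
#'   where `|d| > 0.01`, `mu` the condition means, `amplitude_v`), and
#'   `layout`.
#' @export
simulate_erp_dataset <- function(config = sim_config(), seed = 1) {
  cfg <- config
  stopifnot(inherits(cfg, "sim_config"))
  conds <- names(cfg$n_trials)
  times <- .sim_times(cfg)
  nch <- nrow(cfg$layout); nt <- length(times); ns <- cfg$n_subjects
  amp <- .sim_amplitudes(cfg)
  mu <- .sim_means(cfg, amp)
  dmap <- .sim_true_d(cfg, mu)
  Lspat <- .sim_chol(cfg)
  seeds <- .sub_seeds(seed, ns)
  data <- lapply(conds, function(cn) array(0, c(ns, nch, nt)))
  names(data) <- conds
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  for (s in seq_len(ns)) {
    set.seed(seeds[s])
    gain <- 1 + stats::rnorm(1, 0, cfg$gain_sd)
    offset <- stats::rnorm(nch, 0, cfg$offset_uv * 1e-6)
    for (cn in conds) {
      sig <- cfg$noise_uv * 1e-6 / sqrt(cfg$n_trials[[cn]])
      eps <- sig * .sim_noise(nch, nt, Lspat, .sim_rho(cfg))
      data[[cn]][s, , ] <- offset + gain * mu[[cn]] + eps
    }
  }
  dataset <- erp_dataset(data, cfg$layout$name, times)
  gt <- list(d_map = dmap, effect_mask = abs(dmap) > 0.01, mu = mu,
             amplitude_v = amp, config = cfg, seed = seed)
  list(dataset = dataset, ground_truth = gt, layout = cfg$layout)
}

#' Simulate a null dataset (exchangeable conditions)
#'
#' Both conditions are drawn from the identical generative process: the same
#' deflection shape (the first condition's latency) and amplitude, the same
#' noise law and the same trial count, so condition labels are exchangeable
#' by construction. Used to validate family-wise error control.
#'
#' @inheritParams simulate_erp_dataset
#' @return An [erp_dataset()]; its true d map is identically zero.
#' @export
simulate_null <- function(config = sim_config(), seed = 1) {
  cfg <- config
  cfg$peak_latency[] <- cfg$peak_latency[[1]]
  cfg$n_trials[] <- cfg$n_trials[[1]]
  if (is.null(cfg$amplitude_uv))
    cfg$amplitude_uv <- stats::setNames(rep(-5, length(cfg$n_trials)),
                                        names(cfg$n_trials))
  sim <- simulate_erp_dataset(cfg, seed = seed)
  sim$dataset
}

#' Simulate an oddball event stream
#'
#' Runs of repeated standards interrupted by oddballs: every oddball is
#' preceded by at least one standard, exact trial-type counts are honoured,
#' and after each oddball the sequence continues with probability 0.5 or a
#' new sequence starts (recorded in the `sequence` column, which the epoch
#' selection policy uses to drop first-of-sequence standards).
#'
#' @param config a [sim_config()] (uses `n_trials`, `soa`, `sfreq`).
#' @param seed integer seed.
#' @param lead_in seconds of recording before the first stimulus (default 2).
#' @return A data.frame of class `erp_events` with columns `onset` (s),
#'   `duration` (s), `trial_type`, `sample` (0-based index) and `sequence`.
#' @export
simulate_event_stream <- function(config = sim_config(), seed = 1,
                                  lead_in = 2) {
  cfg <- config
  n_std <- cfg$n_trials[["standard"]]
  n_odd <- cfg$n_trials[["oddball"]]
  if (n_std < n_odd) stop("need at least one standard per oddball")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  # compose the standards into n_odd runs of length >= 1
  extra <- stats::rmultinom(1, n_std - n_odd, rep(1, n_odd))[, 1]
  runs <- 1 + extra
  types <- unlist(lapply(seq_len(n_odd),
                         function(i) c(rep("standard", runs[i]), "oddball")))
  n_ev <- length(types)
  # sequence id: starts at 1; after each oddball, 50% chance of a new sequence
  seq_id <- integer(n_ev)
  cur <- 1L
  for (i in seq_len(n_ev)) {
    seq_id[i] <- cur
    if (types[i] == "oddball" && i < n_ev && stats::runif(1) < 0.5)
      cur <- cur + 1L
  }
  onsets <- lead_in + cumsum(c(0, cfg$soa + stats::runif(n_ev - 1, 0, 0.4)))
  samples <- as.integer(round(onsets * cfg$sfreq))
  ev <- data.frame(onset = samples / cfg$sfreq, duration = 0.5,
                   trial_type = types, sample = samples, sequence = seq_id,
                   stringsAsFactors = FALSE)
  class(ev) <- c("erp_events", "data.frame")
  ev
}

#' Simulate a continuous recording for one subject
#'
#' Background noise (trial-level sd, spatial/temporal correlation as in the
#' epoch-level generator) plus the subject's evoked response added at every
#' stimulus onset. Optionally injects large-amplitude spike artifacts for
#' testing artifact rejection.
#'
#' @param config a [sim_config()].
#' @param seed integer seed (determines events, subject parameters and noise).
#' @param spike_events integer indices of events on which a 500 microvolt
#'   spike is injected at one channel (default none).
#' @return A list with `recording` (class `erp_recording`: `data`
#'   channels x samples in volts, `sfreq`, `channels`), `events` and the
#'   subject's `gain`.
#' @export
simulate_continuous <- function(config = sim_config(), seed = 1,
                                spike_events = integer()) {
  cfg <- config
  events <- simulate_event_stream(cfg, seed = seed)
  times <- .sim_times(cfg)
  nch <- nrow(cfg$layout)
  n_samp <- max(events$sample) + round((cfg$window[2] + 1) * cfg$sfreq)
  amp <- .sim_amplitudes(cfg)
  mu <- .sim_means(cfg, amp)
  Lspat <- .sim_chol(cfg)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed + 1L)
  gain <- 1 + stats::rnorm(1, 0, cfg$gain_sd)
  X <- cfg$noise_uv * 1e-6 * .sim_noise(nch, n_samp, Lspat, .sim_rho(cfg))
  rel <- round(times * cfg$sfreq)  # sample offsets of the epoch grid
  for (i in seq_len(nrow(events))) {
    idx <- events$sample[i] + 1L + rel
    ok <- idx >= 1 & idx <= n_samp
    X[, idx[ok]] <- X[, idx[ok]] + gain * mu[[events$trial_type[i]]][, ok]
  }
  for (i in spike_events) {
    at <- events$sample[i] + 1L + round(0.2 * cfg$sfreq)
    X[1, at:(at + 4)] <- X[1, at:(at + 4)] + 500e-6
  }
  rec <- list(data = X, sfreq = cfg$sfreq, channels = cfg$layout$name,
              units = "V")
  class(rec) <- "erp_recording"
  list(recording = rec, events = events, gain = gain)
}
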