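# Derivatives IO: cleaned per-subject condition averages, rejection logs and
# cluster-test results, kept under <root>/derivatives/<pipeline>/, separate
# from the raw data.

.fmt_num <- function(x) sprintf("%.10g", x)

#' Write a subject's cleaned condition averages to a derivatives folder
#'
#' One tsv per condition (`<sub>_task-<task>_cond-<condition>_ave.tsv`,
#' channels in rows, timepoints in columns headed by the time in seconds)
#' plus a rejection-log tsv.
#'
#' @param average a `subject_average`.
#' @param log the subject's `rejection_log`.
#' @param dir the pipeline derivatives directory.
#' @param subject subject id (`"sub-"` prefixed).
#' @param task task label.
#' @return The subject directory, invisibly.
#' @export
write_subject_derivatives <- function(average, log, dir, subject,
                                      task = "oddball") {
  subdir <- file.path(dir, subject)
  dir.create(subdir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(average)) {
    for (cn in names(average$conditions)) {
      M <- average$conditions[[cn]]
      df <- data.frame(channel = average$channels,
                       matrix(.fmt_num(M), nrow(M), ncol(M)),
                       stringsAsFactors = FALSE, check.names = FALSE)
      names(df) <- c("channel", .fmt_num(average$times))
      write_bids_tsv(df, file.path(subdir, sprintf("%s_task-%s_cond-%s_ave.tsv",
                                                   subject, task, cn)))
    }
    ntr <- data.frame(condition = names(average$n_trials),
                      n_trials = as.integer(average$n_trials))
    write_bids_tsv(ntr, file.path(subdir, sprintf("%s_task-%s_trialcounts.tsv",
                                                  subject, task)))
  }
  logdf <- data.frame(
    subject = log$subject, n_trials_total = log$n_trials_total,
    n_trials_rejected = log$n_trials_rejected,
    rejected_channels = if (length(log$rejected_channels))
      paste(log$rejected_channels, collapse = ",") else NA,
    rejected_trials = if (length(log$rejected_trials))
      paste(log$rejected_trials, collapse = ",") else NA,
    stringsAsFactors = FALSE)
  write_bids_tsv(logdf, file.path(subdir, sprintf("%s_task-%s_rejectlog.tsv",
                                                  subject, task)))
  invisible(subdir)
}

#' Read a preprocessing derivatives tree into a group dataset
#'
#' @param dir the pipeline derivatives directory (as written by
#'   [write_subject_derivatives()]).
#' @param subjects optional subject ids to load (default: all with averages).
#' @return A list with `dataset` (an [erp_dataset()]), `logs` (list of
#'   `rejection_log`) and `n_trials` (matrix subjects x conditions).
#' @export
read_derivatives <- function(dir, subjects = NULL) {
  subs <- sort(grep("^sub-", list.dirs(dir, recursive = FALSE,
                                       full.names = FALSE), value = TRUE))
  logs <- list()
  averages <- list()
  ntr <- list()
  for (sid in subs) {
    subdir <- file.path(dir, sid)
    logf <- list.files(subdir, pattern = "_rejectlog\\.tsv$", full.names = TRUE)
    if (length(logf)) {
      ld <- read_bids_tsv(logf[1])
      lg <- list(subject = ld$subject, n_trials_total = ld$n_trials_total,
                 n_trials_rejected = ld$n_trials_rejected,
                 rejected_trials = if (is.na(ld$rejected_trials)) integer()
                 else as.integer(strsplit(as.character(ld$rejected_trials), ",")[[1]]),
                 rejected_channels = if (is.na(ld$rejected_channels)) character()
                 else strsplit(as.character(ld$rejected_channels), ",")[[1]])
      class(lg) <- "rejection_log"
      logs[[sid]] <- lg
    }
    avef <- list.files(subdir, pattern = "_ave\\.tsv$", full.names = TRUE)
    if (!length(avef)) next
    conds <- sub(".*_cond-([A-Za-z0-9]+)_ave\\.tsv$", "\\1", avef)
    mats <- list()
    times <- NULL; chans <- NULL
    for (k in seq_along(avef)) {
      df <- read_bids_tsv(avef[k])
      chans <- df$channel
      times <- as.numeric(names(df)[-1])
      mats[[conds[k]]] <- as.matrix(df[, -1, drop = FALSE])
    }
    cntf <- list.files(subdir, pattern = "_trialcounts\\.tsv$", full.names = TRUE)
    counts <- if (length(cntf)) {
      cd <- read_bids_tsv(cntf[1])
      stats::setNames(cd$n_trials, cd$condition)
    } else rep(NA_integer_, length(conds))
    avg <- list(conditions = mats, n_trials = counts, channels = chans,
                times = times, sfreq = 1 / stats::median(diff(times)))
    class(avg) <- "subject_average"
    averages[[sid]] <- avg
  }
  if (!is.null(subjects)) averages <- averages[intersect(names(averages), subjects)]
  dataset <- if (length(averages)) combine_subject_averages(averages) else NULL
  list(dataset = dataset, logs = logs,
       n_trials = do.call(rbind, lapply(averages, `[[`, "n_trials")))
}

#' Serialise a cluster test result to json (+ a tsv cluster table)
#'
#' The json embeds the full run configuration and seed so that every result
#' file is reproducible from its own metadata; clusters are stored as sample
#' lists with channel names and times in seconds.
#'
#' @param fit a `cluster_perm_test`.
#' @param path output json path; a sibling `.tsv` cluster table is written
#'   alongside.
#' @return `path`, invisibly.
#' @export
write_cluster_result <- function(fit, path) {
  stopifnot(inherits(fit, "cluster_perm_test"))
  clusters <- lapply(fit$clusters, function(cl) list(
    polarity = cl$polarity, mass = cl$mass, size = cl$size,
    p = cl$p, p_corrected = cl$p_corrected, significant = cl$significant,
    channel = fit$channels[cl$members[, "channel"]],
    time = fit$times[cl$members[, "time"]]
  ))
  obj <- list(
    config = list(conditions = fit$conditions, alpha = fit$alpha,
                  cluster_alpha = fit$cluster_alpha, tails = fit$tails,
                  mode = fit$mode, n_randomizations = fit$n_randomizations,
                  seed = fit$seed, statistic = fit$stat_map$statistic),
    n_subjects = fit$n_subjects, df = fit$stat_map$df, crit = fit$crit,
    channels = fit$channels, times = fit$times, clusters = clusters
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  tab <- summary(fit)$table
  if (nrow(tab)) write_bids_tsv(tab, sub("\\.json$", ".tsv", path))
  invisible(path)
}

#' Read a serialised cluster test result
#'
#' Restores enough structure for effect-size computation and reporting:
#' configuration, grid labels, and clusters with member samples re-indexed
#' against the stored channel/time axes.
#'
#' @param path json path written by [write_cluster_result()].
#' @return A list of class `cluster_result_file` with `config`, `channels`,
#'   `times`, `conditions`, `n_subjects` and `clusters`
#'   (a list of `erp_cluster` objects carrying `p`, `p_corrected`,
#'   `significant`).
#' @export
read_cluster_result <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  channels <- obj$channels
  times <- obj$times
  clusters <- list()
  ncl <- if (is.data.frame(obj$clusters)) nrow(obj$clusters) else length(obj$clusters)
  for (i in seq_len(ncl)) {
    cl <- if (is.data.frame(obj$clusters)) lapply(obj$clusters, `[[`, i)
          else obj$clusters[[i]]
    ch <- match(unlist(cl$channel), channels)
    tt <- vapply(unlist(cl$time), function(z) which.min(abs(times - z)), integer(1))
    out <- list(members = cbind(channel = ch, time = tt),
                channels = sort(unique(channels[ch])),
                time_range = range(times[tt]),
                mass = cl$mass, polarity = cl$polarity, size = cl$size,
                p = cl$p, p_corrected = cl$p_corrected,
                significant = cl$significant)
    class(out) <- "erp_cluster"
    clusters[[i]] <- out
  }
  out <- list(config = obj$config, channels = channels, times = times,
              conditions = obj$config$conditions,
              n_subjects = obj$n_subjects, clusters = clusters)
  class(out) <- "cluster_result_file"
  out
}
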