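# BIDS-EEG dataset trees: naming, writing, reading, advisory validation.
# Hierarchy is project/subject[/session]/datatype; derivatives live under
# root/derivatives/<pipeline>/, never inside raw subject folders. Tabular
# metadata is tab-separated with a header row and "n/a" for missing values.

BIDS_NAME_RE <- "^sub-[A-Za-z0-9]+(_ses-[A-Za-z0-9]+)?_task-[A-Za-z0-9]+_(eeg|events|channels)\\.(vhdr|vmrk|eeg|tsv|json)$"

.check_label <- function(label, what) {
  if (!is.character(label) || length(label) != 1 || !nzchar(label) ||
      !grepl("^[A-Za-z0-9]+$", label))
    stop("invalid ", what, " label '", label,
         "': labels must be nonempty and alphanumeric")
  label
}

#' Compose a BIDS file name
#'
#' `sub-<label>[_ses-<label>]_task-<label>_<suffix>`; labels must be
#' alphanumeric. The session segment is present iff `session` is given.
#'
#' @param subject,task,session alphanumeric labels (session optional).
#' @param suffix one of `"eeg"`, `"events"`, `"channels"`.
#' @param ext optional extension (with or without leading dot).
#' @return The composed file name (no directory).
#' @examples
#' bids_filename("K0109", "audiovisual", suffix = "eeg")
#' # "sub-K0109_task-audiovisual_eeg"
#' @export
bids_filename <- function(subject, task, session = NULL, suffix = "eeg",
                          ext = NULL) {
  .check_label(subject, "subject")
  .check_label(task, "task")
  if (!suffix %in% c("eeg", "events", "channels"))
    stop("suffix must be one of: eeg, events, channels")
  parts <- paste0("sub-", subject)
  if (!is.null(session)) {
    .check_label(session, "session")
    parts <- c(parts, paste0("ses-", session))
  }
  parts <- c(parts, paste0("task-", task), suffix)
  name <- paste(parts, collapse = "_")
  if (!is.null(ext)) name <- paste0(name, sub("^\\.?", ".", ext))
  name
}

write_bids_tsv <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    v <- df[[j]]
    v <- as.character(v)
    v[is.na(v)] <- "n/a"
    df[[j]] <- v
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "n/a")
  invisible(path)
}

read_bids_tsv <- function(path) {
  utils::read.delim(path, na.strings = "n/a", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

.default_channels_df <- function(recording) {
  data.frame(name = recording$channels, type = "EEG", units = "uV",
             status = "good", stringsAsFactors = FALSE)
}

#' Write a BIDS-EEG dataset tree
#'
#' Emits `dataset_description.json`, `participants.tsv` (plus a
#' `participants.json` data dictionary when supplied), and per subject an
#' `eeg/` datatype folder with the recording (BrainVision triplet or
#' tab-separated), its `*_eeg.json` sidecar, `*_events.tsv` and
#' `*_channels.tsv`. Missing tabular values are serialised as `"n/a"`. The
#' session level is emitted only when `session` is given.
#'
#' @param dataset a list describing the dataset:
#'   * `name`: dataset name (required),
#'   * `participants`: data.frame with `participant_id` (`"sub-"` prefixed,
#'     unique) and optionally `age` (days), `sex`, extra columns,
#'   * `participants_json`: optional named list data dictionary,
#'   * `subjects`: named list (by participant_id) with elements `recording`
#'     (an `erp_recording`), `events` (data.frame), optional `channels`
#'     data.frame,
#'   * `eeg_json`: optional named list merged into each `*_eeg.json`.
#' @param root output directory (created).
#' @param task task label (alphanumeric).
#' @param session optional session label applied to all subjects.
#' @param format `"brainvision"` (default) or `"tsv"` (tab-separated
#'   samples x channels, an internal open format handy for text fixtures).
#' @return A `bids_layout` (see [read_bids_dataset()]'s `layout`), invisibly.
#' @export
write_bids_dataset <- function(dataset, root, task = "oddball",
                               session = NULL,
                               format = c("brainvision", "tsv")) {
  format <- match.arg(format)
  .check_label(task, "task")
  if (is.null(dataset$name)) stop("curation error: missing required field 'name'")
  p <- dataset$participants
  if (is.null(p) || !"participant_id" %in% names(p))
    stop("curation error: missing required field 'participants$participant_id'")
  if (anyDuplicated(p$participant_id))
    stop("curation error: duplicate participant_id")
  if ("age" %in% names(p) && any(!is.na(p$age) & p$age < 0))
    stop("curation error: negative age")
  subjects <- dataset$subjects
  if (is.null(subjects) || !all(p$participant_id %in% names(subjects)))
    stop("curation error: missing required field 'subjects' entry for some participant")
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  dd <- list(Name = dataset$name, BIDSVersion = "1.8.0",
             DatasetType = "raw")
  jsonlite::write_json(dd, file.path(root, "dataset_description.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  write_bids_tsv(p, file.path(root, "participants.tsv"))
  if (!is.null(dataset$participants_json))
    jsonlite::write_json(dataset$participants_json,
                         file.path(root, "participants.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  for (pid in p$participant_id) {
    sub <- subjects[[pid]]
    if (is.null(sub$recording))
      stop("curation error: missing required field 'recording' for ", pid)
    rec <- sub$recording
    if (is.null(rec$sfreq))
      stop("curation error: missing required field 'sfreq' for ", pid)
    label <- sub("^sub-", "", pid)
    subdir <- file.path(root, pid)
    if (!is.null(session)) subdir <- file.path(subdir, paste0("ses-", session))
    eegdir <- file.path(subdir, "eeg")
    dir.create(eegdir, recursive = TRUE, showWarnings = FALSE)
    base <- function(suffix, ext = NULL)
      file.path(eegdir, bids_filename(label, task, session, suffix, ext))
    events <- sub$events
    if (is.null(events))
      stop("curation error: missing required field 'events' for ", pid)
    write_bids_tsv(events, base("events", "tsv"))
    channels <- sub$channels
    if (is.null(channels)) channels <- .default_channels_df(rec)
    write_bids_tsv(channels, base("channels", "tsv"))
    ej <- list(TaskName = task,
               SamplingFrequency = rec$sfreq,
               EEGReference = "left mastoid",
               PowerLineFrequency = 50,
               SoftwareFilters = "n/a",
               EEGChannelCount = length(rec$channels),
               RecordingDuration = ncol(rec$data) / rec$sfreq)
    if (!is.null(dataset$eeg_json)) ej <- utils::modifyList(ej, dataset$eeg_json)
    jsonlite::write_json(ej, base("eeg", "json"), auto_unbox = TRUE,
                         pretty = TRUE)
    if (format == "brainvision") {
      write_brainvision(rec, events, base("eeg"))
    } else {
      M <- t(rec$data) * 1e6
      colnames(M) <- rec$channels
      write_bids_tsv(as.data.frame(M), base("eeg", "tsv"))
    }
  }
  invisible(bids_layout(root))
}

#' Model the file tree of a BIDS dataset
#'
#' @param root dataset root.
#' @return A `bids_layout`: list with `root`, `files` (relative paths),
#'   `subjects` (sub-* folder names), `has_derivatives`.
#' @export
bids_layout <- function(root) {
  files <- list.files(root, recursive = TRUE)
  subjects <- grep("^sub-[A-Za-z0-9]+$", list.dirs(root, recursive = FALSE,
                                                   full.names = FALSE),
                   value = TRUE)
  out <- list(root = root, files = files, subjects = subjects,
              has_derivatives = dir.exists(file.path(root, "derivatives")))
  class(out) <- "bids_layout"
  out
}

#' @export
print.bids_layout <- function(x, ...) {
  cat(sprintf("BIDS layout at %s: %d subjects, %d files%s\n", x$root,
              length(x$subjects), length(x$files),
              if (x$has_derivatives) " (+derivatives)" else ""))
  invisible(x)
}

#' Read a BIDS-EEG dataset
#'
#' @param root dataset root; must contain `dataset_description.json`.
#' @return A list of class `bids_dataset`: `name`, `participants`,
#'   `participants_json`, `subjects` (named list with `recording`, `events`,
#'   `channels`, per-subject `warnings`), `task`, `layout`, `warnings`.
#'   Unreadable optional files degrade to warnings; a missing
#'   `dataset_description.json` is an error.
#' @export
read_bids_dataset <- function(root) {
  dd_path <- file.path(root, "dataset_description.json")
  if (!file.exists(dd_path))
    stop("not a BIDS dataset: missing dataset_description.json in ", root)
  dd <- jsonlite::read_json(dd_path)
  warnings <- character()
  p_path <- file.path(root, "participants.tsv")
  participants <- NULL
  if (file.exists(p_path)) participants <- read_bids_tsv(p_path)
  else warnings <- c(warnings, "missing participants.tsv")
  pj_path <- file.path(root, "participants.json")
  participants_json <- if (file.exists(pj_path)) jsonlite::read_json(pj_path) else NULL
  layout <- bids_layout(root)
  task <- NA_character_
  subjects <- list()
  for (pid in layout$subjects) {
    swarn <- character()
    eegdirs <- list.dirs(file.path(root, pid), recursive = TRUE)
    eegdir <- eegdirs[basename(eegdirs) == "eeg"]
    if (!length(eegdir)) {
      subjects[[pid]] <- list(warnings = "no eeg datatype folder")
      next
    }
    eegdir <- eegdir[1]
    fls <- list.files(eegdir)
    vhdr <- grep("_eeg\\.vhdr$", fls, value = TRUE)
    eegtsv <- grep("_eeg\\.tsv$", fls, value = TRUE)
    rec <- NULL; events <- NULL
    if (length(vhdr)) {
      bv <- read_brainvision(file.path(eegdir, vhdr[1]))
      rec <- bv$recording
      task <- sub(".*_task-([A-Za-z0-9]+)_.*", "\\1", vhdr[1])
    } else if (length(eegtsv)) {
      ej <- grep("_eeg\\.json$", fls, value = TRUE)
      sfreq <- if (length(ej))
        jsonlite::read_json(file.path(eegdir, ej[1]))$SamplingFrequency
      else NA
      M <- read_bids_tsv(file.path(eegdir, eegtsv[1]))
      rec <- list(data = t(as.matrix(M)) * 1e-6, sfreq = sfreq,
                  channels = colnames(M), units = "V")
      class(rec) <- "erp_recording"
      task <- sub(".*_task-([A-Za-z0-9]+)_.*", "\\1", eegtsv[1])
    } else {
      swarn <- c(swarn, "no EEG recording found")
    }
    evf <- grep("_events\\.tsv$", fls, value = TRUE)
    if (length(evf)) {
      events <- tryCatch(read_bids_tsv(file.path(eegdir, evf[1])),
                         error = function(e) {
                           swarn <<- c(swarn, paste("unreadable events.tsv:",
                                                    conditionMessage(e)))
                           NULL
                         })
    } else swarn <- c(swarn, "missing events.tsv")
    chf <- grep("_channels\\.tsv$", fls, value = TRUE)
    channels <- if (length(chf)) read_bids_tsv(file.path(eegdir, chf[1])) else NULL
    subjects[[pid]] <- list(recording = rec, events = events,
                            channels = channels, warnings = swarn)
    warnings <- c(warnings, if (length(swarn)) paste0(pid, ": ", swarn))
  }
  out <- list(name = dd$Name, participants = participants,
              participants_json = participants_json, subjects = subjects,
              task = task, layout = layout, warnings = warnings)
  class(out) <- "bids_dataset"
  out
}

#' @export
print.bids_dataset <- function(x, ...) {
  cat(sprintf("BIDS dataset '%s': %d subjects, task '%s'\n", x$name,
              length(x$subjects), x$task))
  if (length(x$warnings)) cat("warnings:\n",
                              paste(" -", x$warnings, collapse = "\n"), "\n")
  invisible(x)
}

.vreport <- function(severity, code, message, path = NA_character_) {
  data.frame(severity = severity, code = code, message = message,
             path = path, stringsAsFactors = FALSE)
}

#' Validate a BIDS-EEG dataset tree
#'
#' Advisory, non-mutating validation: required files and naming-grammar
#' violations are errors, recommended practice (e.g. a data dictionary for a
#' participants column) yields warnings. Problems are report rows, never R
#' errors; the report is deterministic.
#'
#' @param root dataset root.
#' @return A data.frame of class `bids_validation` with columns `severity`
#'   (`"error"`/`"warning"`), `code`, `message`, `path`. Zero error rows
#'   means the layout passes.
#' @export
validate_bids_layout <- function(root) {
  rep <- list()
  add <- function(...) rep[[length(rep) + 1L]] <<- .vreport(...)
  if (!dir.exists(root)) {
    add("error", "NO_DATASET", "root directory does not exist", root)
  } else {
    dd <- file.path(root, "dataset_description.json")
    if (!file.exists(dd)) {
      add("error", "NO_DATASET_DESCRIPTION",
          "missing dataset_description.json", "dataset_description.json")
    } else {
      ok <- tryCatch({jsonlite::read_json(dd); TRUE},
                     error = function(e) FALSE)
      if (!ok) add("error", "INVALID_JSON",
                   "dataset_description.json does not parse",
                   "dataset_description.json")
    }
    pt <- file.path(root, "participants.tsv")
    has_age <- FALSE
    if (!file.exists(pt)) {
      add("error", "NO_PARTICIPANTS", "missing participants.tsv",
          "participants.tsv")
    } else {
      p <- tryCatch(read_bids_tsv(pt), error = function(e) NULL)
      if (is.null(p)) {
        add("error", "INVALID_TSV", "participants.tsv does not parse",
            "participants.tsv")
      } else {
        if (!"participant_id" %in% names(p))
          add("error", "NO_PARTICIPANT_ID",
              "participants.tsv lacks participant_id column",
              "participants.tsv")
        has_age <- "age" %in% names(p)
      }
    }
    pj <- file.path(root, "participants.json")
    if (has_age) {
      dict_ok <- file.exists(pj) &&
        "age" %in% names(jsonlite::read_json(pj))
      if (!dict_ok)
        add("warning", "NO_DICTIONARY",
            "column 'age' has no data dictionary entry (units, e.g. days)",
            "participants.json")
    }
    subs <- grep("^sub-[A-Za-z0-9]+$",
                 list.dirs(root, recursive = FALSE, full.names = FALSE),
                 value = TRUE)
    for (pid in sort(subs)) {
      subroot <- file.path(root, pid)
      dirs <- list.dirs(subroot, recursive = TRUE, full.names = FALSE)
      if (any(basename(dirs) == "derivatives"))
        add("error", "DERIVATIVES_IN_RAW",
            "derivatives must be kept separate from raw data",
            file.path(pid, dirs[basename(dirs) == "derivatives"][1]))
      fls <- list.files(subroot, recursive = TRUE)
      in_eeg <- grepl("(^|/)eeg/[^/]+$", fls)
      for (f in sort(fls[in_eeg])) {
        bn <- basename(f)
        if (grepl("_desc-", bn)) {
          add("error", "DERIVATIVES_IN_RAW",
              "derivative file placed in raw subject folder",
              file.path(pid, f))
        } else if (!grepl(BIDS_NAME_RE, bn)) {
          msg <- if (grepl("^sub-", bn) && !grepl("_task-", bn))
            "file name lacks the required 'task-' entity"
          else "file name violates the BIDS naming convention"
          add("error", "NAMING", msg, file.path(pid, f))
        } else if (!startsWith(bn, paste0(pid, "_"))) {
          add("error", "NAMING",
              "file subject label does not match its folder",
              file.path(pid, f))
        }
      }
      eegs <- fls[grepl("_eeg\\.(vhdr|tsv)$", basename(fls))]
      if (!length(eegs))
        add("error", "NO_RECORDING", "subject has no EEG recording", pid)
      tsvs <- fls[in_eeg & grepl("\\.tsv$", fls)]
      for (f in sort(tsvs)) {
        ok <- tryCatch({read_bids_tsv(file.path(subroot, f)); TRUE},
                       error = function(e) FALSE)
        if (!ok) add("error", "INVALID_TSV", "tsv file does not parse",
                     file.path(pid, f))
      }
      if (!any(grepl("_events\\.tsv$", basename(fls))))
        add("warning", "NO_EVENTS", "subject has no events.tsv", pid)
    }
  }
  out <- if (length(rep)) do.call(rbind, rep) else
    .vreport(character(0), character(0), character(0), character(0))
  class(out) <- c("bids_validation", "data.frame")
  out
}

#' @export
print.bids_validation <- function(x, ...) {
  ne <- sum(x$severity == "error"); nw <- sum(x$severity == "warning")
  cat(sprintf("BIDS validation: %d error(s), %d warning(s)\n", ne, nw))
  for (i in seq_len(nrow(x)))
    cat(sprintf("  [%s] %s: %s (%s)\n", x$severity[i], x$code[i],
                x$message[i], x$path[i]))
  invisible(x)
}
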