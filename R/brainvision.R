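# Minimal BrainVision triplet support: .vhdr / .vmrk INI-style text headers
# plus a multiplexed IEEE float32 little-endian .eeg binary. Covers exactly
# the subset this package writes; resolution-scaled integer formats are not
# supported on read.

#' Write a recording as a BrainVision triplet
#'
#' @param recording an `erp_recording` (`data` channels x samples in volts,
#'   `sfreq`, `channels`).
#' @param events optional event data.frame with `trial_type` and `sample`
#'   (0-based); written as Stimulus markers.
#' @param basepath path without extension; `.vhdr`, `.vmrk`, `.eeg` are
#'   appended.
#' @return `basepath` invisibly.
#' @export
write_brainvision <- function(recording, events = NULL, basepath) {
  base <- basename(basepath)
  nch <- nrow(recording$data)
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "; created by erpcluster",
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", base, ".eeg"),
    paste0("MarkerFile=", base, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nch),
    paste0("SamplingInterval=", format(1e6 / recording$sfreq, scientific = FALSE)),
    "",
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(nch), recording$channels)
  )
  writeLines(enc2utf8(hdr), paste0(basepath, ".vhdr"), useBytes = TRUE)
  mrk <- c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", base, ".eeg"),
    "",
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0,00000000000000000000"
  )
  if (!is.null(events) && nrow(events)) {
    mrk <- c(mrk, sprintf("Mk%d=Stimulus,%s,%d,1,0",
                          seq_len(nrow(events)) + 1L,
                          events$trial_type, events$sample + 1L))
  }
  writeLines(enc2utf8(mrk), paste0(basepath, ".vmrk"), useBytes = TRUE)
  con <- file(paste0(basepath, ".eeg"), "wb")
  on.exit(close(con))
  # multiplexed = channels fastest; data is channels x samples column-major
  writeBin(as.vector(recording$data) * 1e6, con, size = 4L,
           endian = "little")
  invisible(basepath)
}

.parse_ini <- function(lines) {
  out <- list()
  section <- ""
  for (ln in lines) {
    ln <- sub(";.*$", "", ln)
    ln <- trimws(ln)
    if (!nchar(ln)) next
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      out[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE) && nchar(section)) {
      key <- sub("=.*$", "", ln)
      val <- sub("^[^=]*=", "", ln)
      out[[section]][[key]] <- val
    }
  }
  out
}

#' Read a BrainVision triplet
#'
#' @param vhdr_path path to the `.vhdr` header file.
#' @return A list with `recording` (an `erp_recording`, volts) and `events`
#'   (data.frame with `onset`, `duration`, `trial_type`, `sample`; empty when
#'   the marker file carries no Stimulus markers).
#' @export
read_brainvision <- function(vhdr_path) {
  ini <- .parse_ini(readLines(vhdr_path, encoding = "UTF-8", warn = FALSE))
  ci <- ini[["Common Infos"]]
  if (is.null(ci)) stop("not a BrainVision header: ", vhdr_path)
  if (!identical(ci$DataFormat, "BINARY") ||
      !identical(ci$DataOrientation, "MULTIPLEXED"))
    stop("only BINARY/MULTIPLEXED BrainVision data is supported")
  if (!identical(ini[["Binary Infos"]]$BinaryFormat, "IEEE_FLOAT_32"))
    stop("only IEEE_FLOAT_32 BrainVision data is supported")
  nch <- as.integer(ci$NumberOfChannels)
  sfreq <- 1e6 / as.numeric(ci$SamplingInterval)
  chinfo <- ini[["Channel Infos"]]
  channels <- vapply(seq_len(nch), function(i) {
    strsplit(chinfo[[paste0("Ch", i)]], ",", fixed = TRUE)[[1]][1]
  }, character(1))
  dir <- dirname(vhdr_path)
  eeg_path <- file.path(dir, ci$DataFile)
  nbytes <- file.info(eeg_path)$size
  vals <- readBin(eeg_path, "numeric", n = nbytes / 4, size = 4L,
                  endian = "little")
  data <- matrix(vals * 1e-6, nrow = nch)
  rec <- list(data = data, sfreq = sfreq, channels = channels, units = "V")
  class(rec) <- "erp_recording"
  events <- data.frame(onset = numeric(0), duration = numeric(0),
                       trial_type = character(0), sample = integer(0))
  mrk_path <- file.path(dir, ci$MarkerFile)
  if (!is.null(ci$MarkerFile) && file.exists(mrk_path)) {
    mi <- .parse_ini(readLines(mrk_path, encoding = "UTF-8", warn = FALSE))[["Marker Infos"]]
    if (!is.null(mi)) {
      rows <- lapply(mi, function(v) strsplit(v, ",", fixed = TRUE)[[1]])
      stim <- Filter(function(r) r[1] == "Stimulus", rows)
      if (length(stim)) {
        sample <- vapply(stim, function(r) as.integer(r[3]) - 1L, integer(1))
        events <- data.frame(
          onset = sample / sfreq,
          duration = vapply(stim, function(r) as.numeric(r[4]), numeric(1)) / sfreq,
          trial_type = vapply(stim, `[`, character(1), 2),
          sample = sample, stringsAsFactors = FALSE)
      }
    }
  }
  list(recording = rec, events = events)
}
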