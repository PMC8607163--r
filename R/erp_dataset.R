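#' Group-level ERP dataset
#'
#' Container for per-subject, per-condition averaged ERPs: one
#' `subjects x channels x timepoints` array per condition, a common channel
#' set and time axis in seconds relative to stimulus onset.
#'
#' @param data named list of numeric 3-d arrays, one per condition, all with
#'   identical dimensions `c(n_subjects, n_channels, n_times)`. Values are in
#'   volts.
#' @param channels character vector of channel names (length = dim 2).
#' @param times numeric vector of timepoints in seconds (length = dim 3),
#'   strictly increasing.
#' @param subjects optional subject identifiers (length = dim 1).
#' @return An object of class `erp_dataset`.
#' @export
erp_dataset <- function(data, channels, times, subjects = NULL) {
  if (!is.list(data) || is.null(names(data)) || any(names(data) == ""))
    stop("data must be a named list of condition arrays")
  dims <- dim(data[[1]])
  if (length(dims) != 3) stop("condition arrays must be subjects x channels x timepoints")
  for (nm in names(data)) {
    if (!identical(dim(data[[nm]]), dims))
      stop("condition '", nm, "' has mismatching dimensions")
    storage.mode(data[[nm]]) <- "double"
  }
  if (length(channels) != dims[2]) stop("channels length must match dim 2")
  if (length(times) != dims[3]) stop("times length must match dim 3")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (is.null(subjects)) subjects <- sprintf("sub-%02d", seq_len(dims[1]))
  if (length(subjects) != dims[1]) stop("subjects length must match dim 1")
  x <- list(data = data, channels = as.character(channels),
            times = as.numeric(times), subjects = as.character(subjects),
            conditions = names(data))
  class(x) <- "erp_dataset"
  x
}

#' @export
print.erp_dataset <- function(x, ...) {
  cat(sprintf("ERP dataset: %d subjects, %d channels, %d timepoints (%.3f..%.3f s)\n",
              length(x$subjects), length(x$channels), length(x$times),
              min(x$times), max(x$times)))
  cat("conditions:", paste(x$conditions, collapse = ", "), "\n")
  invisible(x)
}

#' Subset an ERP dataset by channels and/or a time window
#'
#' @param x an `erp_dataset`.
#' @param channels optional character vector of channels to keep.
#' @param time_window optional `c(t_min, t_max)` in seconds (closed interval).
#' @return An `erp_dataset`.
#' @export
subset_erp <- function(x, channels = NULL, time_window = NULL) {
  stopifnot(inherits(x, "erp_dataset"))
  ci <- seq_along(x$channels)
  if (!is.null(channels)) {
    ci <- match(channels, x$channels)
    if (anyNA(ci)) stop("unknown channel(s): ",
                        paste(channels[is.na(ci)], collapse = ", "))
  }
  ti <- seq_along(x$times)
  if (!is.null(time_window)) {
    ti <- which(x$times >= time_window[1] & x$times <= time_window[2])
    if (!length(ti)) stop("time_window selects no timepoints")
  }
  data <- lapply(x$data, function(a) a[, ci, ti, drop = FALSE])
  erp_dataset(data, x$channels[ci], x$times[ti], x$subjects)
}
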