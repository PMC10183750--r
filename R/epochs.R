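#' Epoched EEG dataset
#'
#' Container for a subject's epoched multichannel EEG: a numeric array
#' `trials x channels x samples` (microvolts), the sampling rate, a uniform
#' time axis relative to stimulus onset, channel names, and per-trial
#' labels (task, cognate status, correctness).
#'
#' @param data numeric array trials x channels x samples.
#' @param sfreq sampling rate (samples/s).
#' @param times numeric vector of per-sample latencies (s); must be strictly
#'   increasing with uniform step `1/sfreq`.
#' @param channels character vector of channel names.
#' @param task,cognate,correct per-trial labels; recycled if length 1.
#' @param subject_id identifier.
#' @return object of class `eeg_epochs`.
#' @export
epoched_dataset <- function(data, sfreq, times, channels,
                            task = "naming", cognate = "cognate",
                            correct = TRUE, subject_id = "S01") {
  stopifnot(is.array(data), length(dim(data)) == 3)
  n_trials <- dim(data)[1]
  rec <- function(v) if (length(v) == 1) rep(v, n_trials) else v
  x <- structure(list(data = data, sfreq = sfreq, times = as.numeric(times),
                      channels = as.character(channels),
                      task = rec(task), cognate = rec(cognate),
                      correct = rec(correct), subject_id = subject_id),
                 class = "eeg_epochs")
  validate_epochs(x)
  x
}

validate_epochs <- function(x, check_finite = TRUE) {
  d <- dim(x$data)
  if (length(x$times) != d[3])
    stop("times length does not match the sample dimension")
  if (length(x$channels) != d[2])
    stop("channel names do not match the channel dimension")
  dt <- diff(x$times)
  if (any(dt <= 0) || max(abs(dt - 1 / x$sfreq)) > 1e-9)
    stop("times must be strictly increasing with uniform step 1/sfreq")
  for (f in c("task", "cognate", "correct"))
    if (length(x[[f]]) != d[1])
      stop("label '", f, "' does not have one entry per trial")
  if (check_finite && !all(is.finite(x$data)))
    stop("data contains non-finite values")
  invisible(x)
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat("<eeg_epochs> subject ", x$subject_id, ": ", d[1], " trials x ", d[2],
      " channels x ", d[3], " samples @ ", x$sfreq, " Hz, t in [",
      round(min(x$times), 3), ", ", round(max(x$times), 3), "] s\n", sep = "")
  invisible(x)
}

#' Subset trials of an epoched dataset
#' @param x an `eeg_epochs`.
#' @param trials logical or integer trial index.
#' @export
subset_trials <- function(x, trials) {
  x$data <- x$data[trials, , , drop = FALSE]
  for (f in c("task", "cognate", "correct")) x[[f]] <- x[[f]][trials]
  x
}

EPOCH_SCHEMA_VERSION <- 1L

#' Read and write epoched datasets
#'
#' The on-disk container is a flat little-endian float64 binary (the array
#' in R column-major order, trials varying fastest) plus a JSON metadata
#' sidecar carrying the dimensions, time axis, labels and a schema version,
#' so the metadata stays diffable. `read_epochs(write_epochs(x, p))` is a
#' lossless round trip.
#'
#' @param x an `eeg_epochs`.
#' @param path base path; `.dat` and `.json` extensions are appended.
#' @rdname epochs_io
#' @export
write_epochs <- function(x, path) {
  validate_epochs(x, check_finite = FALSE)
  con <- file(paste0(path, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.double(x$data), con, size = 8, endian = "little")
  meta <- list(schema_version = EPOCH_SCHEMA_VERSION, dim = dim(x$data),
               dim_order = c("trial", "channel", "sample"),
               sfreq = x$sfreq, times = x$times, channels = x$channels,
               task = x$task, cognate = x$cognate, correct = x$correct,
               subject_id = x$subject_id)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname epochs_io
#' @export
read_epochs <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(as.integer(meta$schema_version), EPOCH_SCHEMA_VERSION))
    stop("epoch container schema version ", meta$schema_version,
         " is not supported (expected ", EPOCH_SCHEMA_VERSION, ")")
  dat_path <- paste0(path, ".dat")
  n <- prod(meta$dim)
  size <- file.info(dat_path)$size
  if (is.na(size) || size != 8 * n)
    stop("epoch data file is truncated or does not match the sidecar (",
         size, " bytes for ", n, " values)")
  con <- file(dat_path, "rb")
  on.exit(close(con))
  vals <- readBin(con, "double", n = n, size = 8, endian = "little")
  data <- array(vals, dim = meta$dim)
  epoched_dataset(data, sfreq = meta$sfreq, times = meta$times,
                  channels = meta$channels, task = meta$task,
                  cognate = meta$cognate, correct = as.logical(meta$correct),
                  subject_id = meta$subject_id)
}
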