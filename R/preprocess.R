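#' Zero-phase Butterworth filtering
#'
#' Two-pass (forward-backward) IIR Butterworth filter, the standard
#' non-causal filter for continuous EEG. The two passes double the
#' effective attenuation and cancel the phase response.
#'
#' @param x numeric vector, or matrix with one signal per row.
#' @param sfreq sampling rate (Hz).
#' @param kind `"bandpass"` or `"bandstop"`.
#' @param edges_hz length-2 vector of band edges (Hz).
#' @param order filter order per pass (default 4).
#' @return filtered signal, same shape as `x`.
#' @export
butter_filter <- function(x, sfreq, kind = c("bandpass", "bandstop"),
                          edges_hz, order = 4) {
  kind <- match.arg(kind)
  if (any(edges_hz <= 0) || any(edges_hz >= sfreq / 2))
    stop("band edges must lie strictly inside (0, sfreq/2)")
  if (!all(is.finite(x))) stop("signal contains non-finite values")
  flt <- signal::butter(order, sort(edges_hz) / (sfreq / 2),
                        type = if (kind == "bandpass") "pass" else "stop")
  if (any(abs(polyroot(rev(flt$a))) >= 1 + 1e-8))
    stop("unstable filter design at order ", order,
         "; use a lower order or a second-order-sections cascade")
  apply_rows <- function(v) signal::filtfilt(flt, v)
  if (is.matrix(x)) t(apply(x, 1, apply_rows)) else apply_rows(x)
}

#' Epoch a continuous recording with zero padding
#'
#' Cuts epochs around event samples, keeping the signal inside `window`
#' and literal zeros elsewhere, so that each epoch spans `pad` (default
#' -5 to +5 s). The long zero-padded epochs confine wavelet edge effects
#' to the padding; with 5-cycle wavelets the analysis windows inside
#' +/-1 s are unaffected down to 1 Hz.
#'
#' Events whose full window falls outside the recording are dropped and
#' listed in the `dropped_events` attribute.
#'
#' @param continuous list as returned by [read_brainvision()] (`data`
#'   channels x samples, `sfreq`, `channels`).
#' @param event_samples integer vector of stimulus-onset samples (1-based).
#' @param window signal window around onset (s), default `c(-1, 1)`.
#' @param pad full epoch extent (s), default `c(-5, 5)`.
#' @param ... labels passed to [epoched_dataset()] (task, cognate, correct,
#'   subject_id), already reduced to the retained events.
#' @return an `eeg_epochs`.
#' @export
epoch_and_pad <- function(continuous, event_samples, window = c(-1, 1),
                          pad = c(-5, 5), ...) {
  sfreq <- continuous$sfreq
  n_samp <- ncol(continuous$data)
  lo <- round(window[1] * sfreq); hi <- round(window[2] * sfreq) - 1
  ok <- (event_samples + lo) >= 1 & (event_samples + hi) <= n_samp
  dropped <- event_samples[!ok]
  if (length(dropped))
    message(length(dropped), " event(s) too close to the recording edge dropped")
  keep <- event_samples[ok]
  if (!length(keep)) stop("no event has a full window inside the recording")
  times <- seq(round(pad[1] * sfreq), round(pad[2] * sfreq) - 1) / sfreq
  n_chan <- nrow(continuous$data)
  data <- array(0, dim = c(length(keep), n_chan, length(times)))
  inside <- which(times >= window[1] & times < window[2])
  for (i in seq_along(keep)) {
    idx <- keep[i] + lo:hi
    data[i, , inside] <- continuous$data[, idx]
  }
  out <- epoched_dataset(data, sfreq = sfreq, times = times,
                         channels = continuous$channels, ...)
  attr(out, "dropped_events") <- dropped
  out
}

#' Zero-pad already-epoched data
#'
#' Extends epochs (e.g. synthetic -1..+1 s epochs) with literal zeros to
#' the requested extent, matching the padding convention of
#' [epoch_and_pad()].
#'
#' @param epochs an `eeg_epochs`.
#' @param pad target extent (s).
#' @return an `eeg_epochs` on the padded time axis.
#' @export
pad_epochs <- function(epochs, pad = c(-5, 5)) {
  sfreq <- epochs$sfreq
  times <- seq(round(pad[1] * sfreq), round(pad[2] * sfreq) - 1) / sfreq
  if (min(epochs$times) < min(times) || max(epochs$times) > max(times))
    stop("pad extent must contain the existing time axis")
  d <- dim(epochs$data)
  data <- array(0, dim = c(d[1], d[2], length(times)))
  idx <- round((epochs$times - times[1]) * sfreq) + 1
  data[, , idx] <- epochs$data
  epochs$data <- data
  epochs$times <- times
  epochs
}

#' Reject high-amplitude trials
#'
#' Automated stand-in for visual artifact screening: removes every trial
#' whose peak-to-peak amplitude inside the signal window exceeds the
#' threshold on any channel.
#'
#' @param epochs an `eeg_epochs`.
#' @param threshold peak-to-peak threshold in microvolts (default 150).
#' @param window time window checked (s), default `c(-1, 1)`.
#' @return list with `epochs` (retained trials) and `report`, a
#'   `preprocess_report` with rejection counts.
#' @export
reject_trials <- function(epochs, threshold = 150, window = c(-1, 1)) {
  stopifnot(threshold > 0)
  sel <- epochs$times >= window[1] & epochs$times < window[2]
  x <- epochs$data[, , sel, drop = FALSE]
  d <- dim(x)
  m <- matrix(x, d[1] * d[2], d[3])
  cols <- asplit(m, 2)
  p2p <- matrix(do.call(pmax, cols) - do.call(pmin, cols), d[1], d[2])
  bad <- apply(p2p > threshold, 1, any)
  if (all(bad))
    stop("all trials rejected; peak-to-peak threshold ", threshold,
         " uV appears mis-set")
  n_total <- length(bad)
  report <- preprocess_report(n_trials_rejected = sum(bad),
                              n_trials_total = n_total)
  list(epochs = subset_trials(epochs, !bad), report = report)
}

preprocess_report <- function(n_trials_rejected = 0L, n_trials_total = 0L,
                              channels_interpolated = character(),
                              filters_applied = character()) {
  structure(list(
    n_trials_rejected = n_trials_rejected,
    n_trials_total = n_trials_total,
    fraction_rejected = if (n_trials_total > 0)
      n_trials_rejected / n_trials_total else 0,
    channels_interpolated = channels_interpolated,
    filters_applied = filters_applied), class = "preprocess_report")
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat("<preprocess_report> ", x$n_trials_rejected, "/", x$n_trials_total,
      " trials rejected (", round(100 * x$fraction_rejected, 2), "%); ",
      length(x$channels_interpolated), " channel(s) interpolated\n", sep = "")
  invisible(x)
}

#' Serialize a preprocessing report to JSON
#' @param report a `preprocess_report`.
#' @param path output path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Interpolate bad channels from their triangulation neighbours
#'
#' Replaces each bad channel, sample by sample, with the
#' inverse-planar-distance weighted mean of its good Delaunay neighbours
#' (nearest-triangulation interpolation).
#'
#' @param epochs an `eeg_epochs`.
#' @param bad_channels character vector of channel names to rebuild.
#' @param montage an `eeg_montage` covering the epoch channels.
#' @return the epochs with bad channels replaced.
#' @export
interpolate_channels <- function(epochs, bad_channels, montage) {
  idx <- match(epochs$channels, montage$names)
  if (anyNA(idx)) stop("unknown channel: ",
                       paste(epochs$channels[is.na(idx)], collapse = ", "))
  adj <- montage$neighbors[idx, idx, drop = FALSE]
  pos <- montage$pos2d[idx, , drop = FALSE]
  bad <- match(bad_channels, epochs$channels)
  if (anyNA(bad)) stop("unknown channel: ",
                       paste(bad_channels[is.na(bad)], collapse = ", "))
  good <- setdiff(seq_along(epochs$channels), bad)
  for (b in bad) {
    nb <- intersect(which(adj[b, ]), good)
    if (length(nb) < 2)
      stop("channel ", epochs$channels[b],
           " has fewer than 2 good neighbours; cannot interpolate")
    d <- sqrt(rowSums((pos[nb, , drop = FALSE] -
                         matrix(pos[b, ], length(nb), 2, byrow = TRUE))^2))
    w <- (1 / d) / sum(1 / d)
    acc <- 0
    for (k in seq_along(nb)) acc <- acc + w[k] * epochs$data[, nb[k], ]
    epochs$data[, b, ] <- acc
  }
  epochs
}

#' Re-reference epochs to the channel average
#'
#' Subtracts, at every sample, the mean across channels. Idempotent; leaves
#' channel differences unchanged.
#'
#' @param epochs an `eeg_epochs` with at least 2 channels.
#' @return re-referenced epochs.
#' @export
rereference_average <- function(epochs) {
  if (dim(epochs$data)[2] < 2) stop("average reference needs >= 2 channels")
  d <- dim(epochs$data)
  mu <- rowSums(aperm(epochs$data, c(1, 3, 2)), dims = 2) / d[2]
  epochs$data <- epochs$data - aperm(array(mu, c(d[1], d[3], d[2])),
                                     c(1, 3, 2))
  epochs
}

#' Standard preprocessing chain for epoched data
#'
#' Applies, in the fixed order the analysis assumes, trial rejection,
#' optional bad-channel interpolation, and average re-referencing, and
#' returns the processed epochs together with a `preprocess_report`.
#' (Filtering and epoching of continuous recordings happen upstream via
#' [butter_filter()] and [epoch_and_pad()].)
#'
#' @param epochs an `eeg_epochs`.
#' @param montage an `eeg_montage` (needed when interpolating).
#' @param reject_threshold peak-to-peak rejection threshold (microvolts).
#' @param bad_channels channels to interpolate before re-referencing.
#' @return list with `epochs` and `report`.
#' @export
preprocess_epochs <- function(epochs, montage = NULL, reject_threshold = 150,
                              bad_channels = character()) {
  rej <- reject_trials(epochs, threshold = reject_threshold)
  out <- rej$epochs
  if (length(bad_channels)) {
    if (is.null(montage)) stop("interpolation needs a montage")
    out <- interpolate_channels(out, bad_channels, montage)
  }
  out <- rereference_average(out)
  report <- rej$report
  report$channels_interpolated <- bad_channels
  list(epochs = out, report = report)
}
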