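#' Morlet time-frequency decomposition
#'
#' Complex Morlet wavelet power (width 5 cycles by default) computed by
#' FFT-domain convolution, sampled on a decimated time grid (20 ms steps
#' by default). The analytic kernel has unit tone gain: a sinusoid of
#' amplitude `a` at a wavelet's centre frequency yields power `a^2`.
#' Per-trial power is retained.
#'
#' @param epochs an `eeg_epochs`. The epoch must be long enough for the
#'   wavelet at the lowest frequency (5 cycles at 1 Hz need the 10 s
#'   padded epochs produced by [pad_epochs()]).
#' @param freqs frequencies in Hz (default 1-40 in 1 Hz steps).
#' @param n_cycles wavelet width in cycles.
#' @param t_step output time step in seconds (must be a multiple of the
#'   sampling step).
#' @param channels optional channel-name subset.
#' @param trials optional trial index.
#' @param tmin,tmax optional crop of the output time grid.
#' @return an `eeg_tfr`: `power` array trials x channels x freqs x times,
#'   the grids, `stage = "raw"`, and the per-trial labels.
#' @export
morlet_tfr <- function(epochs, freqs = 1:40, n_cycles = 5, t_step = 0.020,
                       channels = NULL, trials = NULL,
                       tmin = NULL, tmax = NULL) {
  sfreq <- epochs$sfreq
  if (any(freqs >= sfreq / 2)) stop("frequencies must be below Nyquist")
  if (any(freqs <= 0)) stop("frequencies must be positive")
  dur <- length(epochs$times) / sfreq
  if (n_cycles / min(freqs) > dur)
    stop("epoch too short for a ", n_cycles, "-cycle wavelet at ",
         min(freqs), " Hz; zero-pad the epochs first")
  decim <- round(t_step * sfreq)
  if (abs(decim - t_step * sfreq) > 1e-9 || decim < 1)
    stop("t_step must be a positive multiple of the sampling step")
  if (is.null(trials)) trials <- seq_len(dim(epochs$data)[1])
  if (is.null(channels)) channels <- epochs$channels
  ch_idx <- match(channels, epochs$channels)
  if (anyNA(ch_idx))
    stop("unknown channel: ", paste(channels[is.na(ch_idx)], collapse = ", "))

  x <- epochs$data[trials, ch_idx, , drop = FALSE]
  n_tr <- dim(x)[1]; n_ch <- dim(x)[2]; n_s <- dim(x)[3]
  mat <- aperm(x, c(3, 1, 2))
  dim(mat) <- c(n_s, n_tr * n_ch)
  cube <- morlet_power_cpp(mat, sfreq, as.numeric(freqs), n_cycles,
                           as.integer(decim))
  m <- dim(cube)[1]
  times <- epochs$times[seq(1, n_s, by = decim)]
  pow <- array(cube, dim = c(m, n_tr, n_ch, length(freqs)))
  pow <- aperm(pow, c(2, 3, 4, 1))
  keep <- rep(TRUE, m)
  if (!is.null(tmin)) keep <- keep & times >= tmin - 1e-9
  if (!is.null(tmax)) keep <- keep & times <= tmax + 1e-9
  pow <- pow[, , , keep, drop = FALSE]
  structure(list(power = pow, freqs = as.numeric(freqs), times = times[keep],
                 channels = channels, stage = "raw",
                 task = epochs$task[trials], cognate = epochs$cognate[trials],
                 correct = epochs$correct[trials],
                 subject_id = epochs$subject_id, groups = NULL),
            class = "eeg_tfr")
}

#' @export
print.eeg_tfr <- function(x, ...) {
  d <- dim(x$power)
  cat("<eeg_tfr> [", paste(d, collapse = " x "), "] (",
      if (is.null(x$groups)) "trials" else "groups",
      " x channels x freqs x times), stage: ", x$stage, "\n", sep = "")
  invisible(x)
}

#' Iterative 1/f (aperiodic) spectral fit
#'
#' For every trial-channel-time triple, fits a least-squares line to
#' log power versus log frequency. The fit is refined iteratively:
#' frequencies whose residual exceeds `k` residual SDs are excluded and
#' the line refit until the excluded set stabilizes (or `max_iter`), so
#' oscillatory peaks do not bias the aperiodic estimate. Cells with
#' non-positive power (zero padding) are masked.
#'
#' @param tfr a raw `eeg_tfr`.
#' @param k exclusion constant in residual SDs (default 2).
#' @param max_iter maximum refinement iterations (default 10).
#' @return a `fractal_fit` with `slope` and `intercept` arrays matching the
#'   non-frequency dims of the power array, and an `excluded` logical array
#'   flagging frequencies left out of each final fit.
#' @export
fit_fractal <- function(tfr, k = 2, max_iter = 10) {
  if (tfr$stage != "raw") stop("fit_fractal expects a raw-power TFR")
  d <- dim(tfr$power)
  nf <- d[3]
  lx <- log(tfr$freqs)
  # arrange as freq x (trial*channel*time)
  Y <- aperm(tfr$power, c(3, 1, 2, 4))
  dim(Y) <- c(nf, prod(d[-3]))
  usable <- is.finite(Y) & Y > .Machine$double.xmin
  Y <- log(pmax(Y, .Machine$double.xmin))
  Y[!usable] <- 0

  fit_once <- function(W) {
    n <- colSums(W)
    sx <- colSums(W * lx); sxx <- colSums(W * lx^2)
    sy <- colSums(W * Y);  sxy <- colSums(W * lx * Y)
    den <- n * sxx - sx^2
    slope <- ifelse(den > 0, (n * sxy - sx * sy) / den, 0)
    intercept <- ifelse(n > 0, (sy - slope * sx) / n, NA_real_)
    list(slope = slope, intercept = intercept, n = n)
  }

  # Progressive peeling: at each pass, frequencies whose residual exceeds
  # k residual-SDs *above* the current line leave the fitted set for good
  # (oscillations only add power, so only positive outliers are peeled),
  # until the excluded set stabilizes. Columns that would drop below 3
  # usable frequencies stop peeling instead (non-iterative fallback).
  W <- usable
  few <- colSums(W) < 3
  f0 <- fit_once(W)
  slope <- f0$slope; intercept <- f0$intercept
  fell_back <- FALSE
  for (it in seq_len(max_iter)) {
    pred <- outer(lx, slope) + rep(intercept, each = nf)
    R <- (Y - pred) * W
    rsd <- sqrt(colSums(R^2) / pmax(colSums(W) - 2, 1))
    Wnew <- W & (Y - pred) <= rep(k * pmax(rsd, 1e-12), each = nf)
    short <- colSums(Wnew) < 3
    if (any(short)) {
      Wnew[, short] <- W[, short]
      fell_back <- fell_back || any(short & !few)
    }
    if (identical(Wnew, W)) break
    W <- Wnew
    f1 <- fit_once(W)
    slope <- f1$slope; intercept <- f1$intercept
  }
  if (fell_back)
    warning("iterative exclusion would leave < 3 frequencies for some ",
            "fits; peeling stopped early there")
  rest <- d[-3]
  out <- list(
    slope = array(slope, dim = rest),
    intercept = array(intercept, dim = rest),
    excluded = aperm(array(!W & usable, dim = c(nf, rest)), c(2, 3, 1, 4)),
    freqs = tfr$freqs, times = tfr$times, channels = tfr$channels)
  med <- stats::median(slope[is.finite(slope)])
  if (is.finite(med) && med > 0)
    warning("median fitted aperiodic slope is positive; ",
            "input may not be physiological power")
  structure(out, class = "fractal_fit")
}

#' Subtract the aperiodic fit from a TFR
#'
#' Removes the fitted 1/f component in log space (residual of log power
#' about the fitted line) and returns the result on a linear scale, i.e.
#' the ratio of observed to fitted aperiodic power, so that the subsequent
#' baseline normalization is a well-defined relative change.
#'
#' @param tfr the raw `eeg_tfr` the fit was computed from.
#' @param fit the matching `fractal_fit`.
#' @return an `eeg_tfr` with `stage = "fractal_corrected"`.
#' @export
subtract_fractal <- function(tfr, fit) {
  if (!identical(tfr$freqs, fit$freqs) || !identical(tfr$times, fit$times) ||
      !identical(tfr$channels, fit$channels))
    stop("fractal fit grid does not match the TFR grid")
  d <- dim(tfr$power)
  nf <- d[3]
  lx <- log(tfr$freqs)
  pred <- outer(lx, as.vector(fit$slope)) +
    rep(as.vector(fit$intercept), each = nf)
  P <- aperm(tfr$power, c(3, 1, 2, 4))
  dim(P) <- c(nf, prod(d[-3]))
  corr <- P / exp(pred)
  corr <- array(corr, dim = c(nf, d[-3]))
  tfr$power <- aperm(corr, c(2, 3, 1, 4))
  tfr$stage <- "fractal_corrected"
  tfr
}

#' Average a per-trial TFR within conditions
#'
#' Averages power across (by default, correct) trials within task x
#' cognate cells.
#'
#' @param tfr an `eeg_tfr` with per-trial power.
#' @param correct_only drop incorrect trials first (default TRUE).
#' @return an `eeg_tfr` whose first dimension indexes condition cells,
#'   with a `groups` tibble describing them.
#' @export
average_tfr <- function(tfr, correct_only = TRUE) {
  if (!is.null(tfr$groups)) stop("TFR is already condition-averaged")
  keep <- if (correct_only) tfr$correct else rep(TRUE, length(tfr$correct))
  if (!any(keep)) stop("no (correct) trials to average")
  cells <- unique(data.frame(task = tfr$task[keep], cognate = tfr$cognate[keep],
                             stringsAsFactors = FALSE))
  cells <- cells[order(cells$task, cells$cognate), , drop = FALSE]
  d <- dim(tfr$power)
  out <- array(NA_real_, dim = c(nrow(cells), d[2], d[3], d[4]))
  for (i in seq_len(nrow(cells))) {
    sel <- keep & tfr$task == cells$task[i] & tfr$cognate == cells$cognate[i]
    out[i, , , ] <- colMeans(tfr$power[sel, , , , drop = FALSE], dims = 1)
  }
  tfr$power <- out
  tfr$groups <- tibble::as_tibble(cells)
  tfr$task <- tfr$cognate <- tfr$correct <- NULL
  tfr
}

#' Baseline normalization (relative change)
#'
#' Per channel and frequency, expresses power as
#' `(P(t) - mean(baseline)) / mean(baseline)` on the linear scale, so a
#' value of -0.21 means a 21% power decrease against the pre-stimulus
#' baseline.
#'
#' @param tfr an `eeg_tfr` (raw or fractal-corrected).
#' @param baseline baseline window in seconds (default -0.7 to -0.2).
#' @return an `eeg_tfr` with `stage = "baseline_normalized"`.
#' @export
baseline_normalize <- function(tfr, baseline = c(-0.7, -0.2)) {
  if (tfr$stage == "baseline_normalized")
    stop("TFR is already baseline-normalized")
  sel <- tfr$times >= baseline[1] - 1e-9 & tfr$times <= baseline[2] + 1e-9
  if (!any(sel)) stop("baseline window contains no time points")
  d <- dim(tfr$power)
  base <- tfr$power[, , , sel, drop = FALSE]
  mu <- rowMeans(aperm(base, c(1, 2, 3, 4)), dims = 3)
  if (any(mu <= 0)) stop("baseline mean power is non-positive; ",
                         "baseline must lie inside the unpadded epoch")
  tfr$power <- tfr$power / array(mu, dim = d) - 1
  tfr$stage <- "baseline_normalized"
  tfr
}

#' Band power over a region of interest
#'
#' Mean of (typically baseline-normalized) power over a channel set, a
#' frequency band and a time window, for each trial or condition cell.
#'
#' @param tfr an `eeg_tfr`.
#' @param band length-2 frequency interval (Hz), inclusive.
#' @param window length-2 time interval (s), inclusive.
#' @param channels channel names to average (default all).
#' @return tibble with one row per first-dimension entry and a `power`
#'   column.
#' @export
band_power <- function(tfr, band, window, channels = NULL) {
  if (is.null(channels)) channels <- tfr$channels
  ch <- match(channels, tfr$channels)
  if (anyNA(ch))
    stop("unknown channel: ", paste(channels[is.na(ch)], collapse = ", "))
  fs <- which(tfr$freqs >= band[1] - 1e-9 & tfr$freqs <= band[2] + 1e-9)
  ts <- which(tfr$times >= window[1] - 1e-9 & tfr$times <= window[2] + 1e-9)
  if (!length(ch) || !length(fs) || !length(ts))
    stop("empty channel/frequency/time selection")
  sub <- tfr$power[, ch, fs, ts, drop = FALSE]
  val <- apply(sub, 1, mean)
  if (!is.null(tfr$groups)) {
    out <- tfr$groups
    out$power <- val
  } else {
    out <- tibble::tibble(trial = seq_along(val), task = tfr$task,
                          cognate = tfr$cognate, correct = tfr$correct,
                          power = val)
  }
  out
}
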