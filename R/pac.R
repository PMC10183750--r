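#' Find the most prominent spectral peak in a band
#'
#' Scans a mean power spectrum for local maxima inside the band and
#' returns the one with the greatest prominence (height above the higher
#' of the two flanking minima). When the band contains no interior local
#' maximum, the band's maximum point is returned with a warning.
#'
#' @param freqs frequency grid (Hz).
#' @param power mean power spectrum on that grid.
#' @param band length-2 search band (Hz), inclusive.
#' @return list of class `band_peak`: `frequency`, `prominence`, `band`.
#' @export
find_band_peak <- function(freqs, power, band) {
  sel <- which(freqs >= band[1] - 1e-9 & freqs <= band[2] + 1e-9)
  if (length(sel) < 3) stop("band must cover at least 3 spectral points")
  f <- freqs[sel]; p <- power[sel]
  n <- length(p)
  peaks <- which(diff(sign(diff(p))) == -2) + 1     # interior local maxima
  if (!length(peaks)) {
    warning("no interior local maximum in band [", band[1], ", ", band[2],
            "] Hz; returning the band maximum")
    i <- which.max(p)
    return(structure(list(frequency = f[i], prominence = 0, band = band),
                     class = "band_peak"))
  }
  prom <- vapply(peaks, function(i) {
    left <- if (i > 1) min(p[1:(i - 1)]) else p[1]
    right <- if (i < n) min(p[(i + 1):n]) else p[n]
    p[i] - max(left, right)
  }, 0)
  i <- peaks[which.max(prom)]
  structure(list(frequency = f[i], prominence = max(prom), band = band),
            class = "band_peak")
}

#' Balanced trial subsampling across conditions
#'
#' Draws, for each resampling iteration, the same number of trials from
#' every condition: `m = floor(fraction * min(condition counts))` without
#' replacement. Subsampling below the smallest condition varies which
#' trials of the minimum condition enter each iteration and prevents any
#' condition from always contributing all of its trials.
#'
#' @param trial_sets named list of per-condition trial index vectors
#'   (correct trials).
#' @param fraction subsample fraction of the smallest count (default 0.8).
#' @param n_iterations number of resampling iterations.
#' @param seed RNG seed.
#' @return list with `m` and `draws`: per iteration, a named list of
#'   per-condition index vectors of length `m`.
#' @export
subsample_trials <- function(trial_sets, fraction = 0.8, n_iterations = 100,
                             seed = 1L) {
  counts <- vapply(trial_sets, length, 1L)
  if (any(counts < 2)) stop("every condition needs >= 2 correct trials")
  m <- floor(fraction * min(counts))
  if (m < 1) stop("subsampling would select < 1 trial per condition")
  set.seed(seed)
  draws <- lapply(seq_len(n_iterations), function(i)
    lapply(trial_sets, function(idx) sort(sample(idx, m))))
  list(m = m, draws = draws)
}

#' Narrow-band phase and amplitude via the analytic signal
#'
#' Filters the signal with zero-phase frequency-domain Gaussian kernels
#' centred on the theta and beta peaks (spectral SDs `theta_bw_sd` and
#' `beta_bw_sd`), takes the analytic signal, and returns the
#' instantaneous theta phase and beta amplitude envelope.
#'
#' @param x numeric signal vector.
#' @param sfreq sampling rate (Hz).
#' @param theta_peak,beta_peak filter centre frequencies (Hz).
#' @param theta_bw_sd,beta_bw_sd spectral SDs of the Gaussian filters
#'   (Hz); defaults 0.5 and 5.
#' @return list with `phase` (radians in (-pi, pi]) and `amplitude`
#'   (>= 0), both the length of `x`.
#' @export
phase_amplitude_series <- function(x, sfreq, theta_peak, beta_peak,
                                   theta_bw_sd = 0.5, beta_bw_sd = 5) {
  for (f in c(theta_peak, beta_peak))
    if (f <= 0 || f >= sfreq / 2)
      stop("filter centre frequencies must lie inside (0, sfreq/2)")
  if (beta_peak + 3 * beta_bw_sd >= sfreq / 2)
    stop("beta filter extends beyond the Nyquist margin")
  zt <- gaussian_analytic_filter(x, sfreq, theta_peak, theta_bw_sd)
  zb <- gaussian_analytic_filter(x, sfreq, beta_peak, beta_bw_sd)
  list(phase = Arg(zt), amplitude = Mod(zb))
}

gaussian_analytic_filter <- function(x, sfreq, f0, sd_hz) {
  n <- length(x)
  f <- (seq_len(n) - 1) * sfreq / n
  H <- ifelse(f > 0 & f <= sfreq / 2, 2 * exp(-(f - f0)^2 / (2 * sd_hz^2)), 0)
  stats::fft(stats::fft(x) * H, inverse = TRUE) / n
}

# extraction segment for MI: the task window, extended symmetrically to at
# least two cycles of the phase-providing frequency for filter stability
pac_segment_index <- function(times, window, theta_freq, n_cycles_min = 2) {
  len <- max(diff(window), n_cycles_min / theta_freq)
  mid <- mean(window)
  which(times >= mid - len / 2 - 1e-9 & times <= mid + len / 2 + 1e-9)
}

#' Modulation index from phase and amplitude series
#'
#' Bins the amplitude series by phase into `n_bins` equidistant bins,
#' normalizes the bin means to a distribution `p`, and returns the
#' Kullback-Leibler distance of `p` from uniform, normalized by `log
#' n_bins`: `MI = (log N - H(p)) / log N`, 0 for a uniform profile and 1
#' when all amplitude concentrates in one bin. Empty bins contribute via
#' the `0 * log 0 = 0` convention.
#'
#' @param phase phase series (radians).
#' @param amplitude amplitude series (same length, >= 0).
#' @param n_bins number of phase bins (default 12, i.e. 30 degrees).
#' @return list with `mi`, `bin_means`, `bin_centers` (radians).
#' @export
modulation_index <- function(phase, amplitude, n_bins = 12) {
  if (length(phase) != length(amplitude))
    stop("phase and amplitude series must have equal length")
  if (length(phase) < n_bins)
    stop("series shorter than the number of phase bins")
  if (all(amplitude == 0)) stop("all-zero amplitude series")
  edges <- seq(-pi, pi, length.out = n_bins + 1)
  bin <- findInterval(phase, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  means <- vapply(seq_len(n_bins), function(b) {
    v <- amplitude[bin == b]
    if (length(v)) mean(v) else 0
  }, 0)
  p <- means / sum(means)
  h <- -sum(ifelse(p > 0, p * log(p), 0))
  list(mi = (log(n_bins) - h) / log(n_bins), bin_means = means,
       bin_centers = (edges[-1] + edges[-(n_bins + 1)]) / 2)
}

#' Subject-level theta-beta PAC by condition
#'
#' Implements the full coupling analysis for one subject: find the
#' subject's theta and beta spectral peaks per task on the
#' fractal-corrected ROI spectrum, balance trial counts across the four
#' conditions by 80% subsampling of the smallest correct-trial count,
#' filter each trial and ROI electrode around the peaks, bin beta
#' amplitude by theta phase on the task's analysis window (extended to at
#' least two theta cycles), and average the per-trial-electrode MI over
#' electrodes, trials and resampling iterations.
#'
#' @param epochs the subject's `eeg_epochs` (all four conditions).
#' @param cfg an `analysis_config`.
#' @param tfr optional precomputed raw per-trial `eeg_tfr` covering the
#'   ROI channels (otherwise computed here).
#' @param seed RNG seed for the subsampling draws.
#' @return list of class `pac_result`: `peaks` (per task), `mi` tibble
#'   (task, cognate, mi), per-condition bin profiles, and subsample
#'   metadata.
#' @export
pac_condition_mean <- function(epochs, cfg = analysis_config(), tfr = NULL,
                               seed = 1L) {
  ct <- cond_table()
  rois <- list(naming = cfg$rois$naming, size = cfg$rois$size)
  windows <- list(naming = cfg$windows$naming_roi, size = cfg$windows$size_roi)

  # correct-trial index per condition
  trial_sets <- lapply(seq_len(4), function(j)
    which(epochs$task == ct$task[j] & epochs$cognate == ct$cognate[j] &
            epochs$correct))
  names(trial_sets) <- ct$key
  sub <- subsample_trials(trial_sets, fraction = cfg$subsample_fraction,
                          n_iterations = cfg$n_subsample_iterations,
                          seed = seed)

  # subject peaks per task from the fractal-corrected ROI spectrum
  peaks <- list()
  for (task in c("naming", "size")) {
    roi <- intersect(rois[[task]], epochs$channels)
    tr <- which(epochs$task == task & epochs$correct)
    spec <- roi_mean_spectrum(epochs, roi, windows[[task]], cfg, trials = tr,
                              tfr = tfr)
    peaks[[task]] <- list(
      theta = find_band_peak(spec$freqs, spec$power, cfg$bands$theta),
      beta = find_band_peak(spec$freqs, spec$power, cfg$bands$beta_pac))
  }

  # MI per trial (mean over ROI electrodes), then average over the draws
  mi_trial <- setNames(vector("list", 4), ct$key)
  profiles <- setNames(vector("list", 4), ct$key)
  for (j in seq_len(4)) {
    task <- ct$task[j]
    roi <- intersect(rois[[task]], epochs$channels)
    ch_idx <- match(roi, epochs$channels)
    f_t <- peaks[[task]]$theta$frequency
    f_b <- peaks[[task]]$beta$frequency
    seg <- pac_segment_index(epochs$times, windows[[task]], f_t)
    used <- sort(unique(unlist(lapply(sub$draws, `[[`, ct$key[j]))))
    vals <- setNames(numeric(length(used)), used)
    prof <- 0
    for (tr in used) {
      mi_e <- vapply(ch_idx, function(c) {
        pa <- phase_amplitude_series(epochs$data[tr, c, ], epochs$sfreq,
                                     f_t, f_b,
                                     theta_bw_sd = cfg$theta_filter_sd,
                                     beta_bw_sd = cfg$beta_filter_sd)
        # beta power (squared envelope) is what gets phase-binned
        r <- modulation_index(pa$phase[seg], pa$amplitude[seg]^2,
                              n_bins = cfg$n_phase_bins)
        prof <<- prof + r$bin_means
        r$mi
      }, 0)
      vals[as.character(tr)] <- mean(mi_e)
    }
    mi_trial[[j]] <- vals
    profiles[[j]] <- prof / sum(prof) * cfg$n_phase_bins
  }

  mi <- vapply(seq_len(4), function(j) {
    mean(vapply(sub$draws, function(d)
      mean(mi_trial[[j]][as.character(d[[ct$key[j]]])]), 0))
  }, 0)
  structure(list(
    peaks = peaks,
    mi = tibble::tibble(subject = epochs$subject_id, task = ct$task,
                        cognate = ct$cognate, mi = mi),
    bin_profiles = profiles,
    subsample = list(m = sub$m, n_iterations = cfg$n_subsample_iterations,
                     seed = seed)), class = "pac_result")
}

# trial-averaged fractal-corrected power spectrum over ROI channels and a
# time window (used for subject peak finding)
roi_mean_spectrum <- function(epochs, roi, window, cfg, trials, tfr = NULL) {
  if (is.null(tfr)) {
    ep <- pad_epochs(subset_trials(epochs, trials), pad = c(-3, 3))
    tfr <- morlet_tfr(ep, freqs = cfg$freqs, n_cycles = cfg$n_cycles,
                      t_step = cfg$t_step, channels = roi,
                      tmin = window[1] - 0.1, tmax = window[2] + 0.1)
    trials_use <- seq_len(dim(tfr$power)[1])
  } else {
    trials_use <- trials
  }
  tsub <- tfr
  tsub$power <- tfr$power[trials_use, , , , drop = FALSE]
  for (f in c("task", "cognate", "correct")) tsub[[f]] <- tfr[[f]][trials_use]
  avg <- average_tfr(tsub)
  # pool the task's two cells before fitting
  pooled <- avg
  pooled$power <- array(colMeans(avg$power, dims = 1),
                        c(1, dim(avg$power)[-1]))
  pooled$groups <- tibble::tibble(task = "pooled", cognate = "pooled")
  fit <- fit_fractal(pooled, k = cfg$fractal_k,
                     max_iter = cfg$fractal_max_iter)
  corr <- subtract_fractal(pooled, fit)
  ch <- match(intersect(roi, corr$channels), corr$channels)
  ts <- which(corr$times >= window[1] - 0.1 - 1e-9 &
                corr$times <= window[2] + 0.1 + 1e-9)
  sub <- corr$power[, ch, , ts, drop = FALSE]
  list(freqs = corr$freqs, power = apply(sub, 3, mean))
}

#' @export
print.pac_result <- function(x, ...) {
  cat("<pac_result> subject ", x$mi$subject[1], ", m = ", x$subsample$m,
      " trials/condition, ", x$subsample$n_iterations, " iterations\n",
      sep = "")
  print(x$mi)
  invisible(x)
}
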