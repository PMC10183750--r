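#' Configuration of the synthetic EEG + behavior generator
#'
#' Defines the cohort the generator emulates: 18 subjects, 38-channel
#' 10-20 cap at 500 Hz, two tasks (picture naming, size judgment) x two
#' cognate conditions x 32 trials, epochs -1..+1 s around stimulus onset.
#' Signals combine a 1/f aperiodic background, white sensor noise,
#' theta (5 Hz) and beta (29 Hz) oscillations with condition- and
#' task-specific power changes confined to task-specific windows and
#' regions of interest, a theta-phase-modulated beta carrier
#' (phase-amplitude coupling), and behavioral accuracy/RT with a cognate
#' advantage. The default condition means are the group-level values the
#' analysis pipeline is expected to recover.
#'
#' Condition order everywhere is naming-noncognate, naming-cognate,
#' size-noncognate, size-cognate.
#'
#' @param ... named overrides of any default.
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(...) {
  cfg <- list(
    n_subjects = 18L,
    trials_per_condition = 32L,
    sfreq = 500,
    epoch_window = c(-1, 1),
    montage = "study38",
    channels = NULL,                 # NULL = all montage channels
    aperiodic_exponent = 1,
    aperiodic_amplitude = 10,        # background SD, microvolts
    noise_sd = 2,                    # white sensor noise SD, microvolts
    osc_freqs = c(theta = 5, beta = 29),
    osc_amplitudes = c(theta = 7, beta = 3, pac = 12),
    trial_amp_nu = 0.4,              # lognormal trial-amplitude jitter
    beta_rel_change = c(naming_noncognate = -0.13, naming_cognate = -0.21,
                        size_noncognate = -0.15, size_cognate = -0.22),
    beta_rel_sd = c(0.13, 0.10, 0.16, 0.13),
    theta_rel_change = c(naming_noncognate = 0.47, naming_cognate = 0.55,
                         size_noncognate = 0.46, size_cognate = 0.36),
    theta_rel_sd = c(0.23, 0.34, 0.27, 0.22),
    between_sd_scale = 0.25,
    effect_windows = list(naming = c(0.160, 0.260), size = c(0.260, 0.380)),
    effect_rois = list(
      naming = c("T3", "C3", "CP3", "CP4", "P3", "P4", "Pz", "POz", "PO2",
                 "Oz", "O2"),
      size = c("T5", "Cz", "C3", "C4", "CP3", "CP4", "P3", "P4")),
    neighbor_falloff = 0.5,
    pac_enabled = TRUE,
    pac_target_mi = c(naming_noncognate = 0.028, naming_cognate = 0.029,
                      size_noncognate = 0.032, size_cognate = 0.031),
    pac_subject_cv = 0.05,
    theta_filter_sd = 0.5,
    beta_filter_sd = 5,
    rt_mean_ms = c(naming_noncognate = 848, naming_cognate = 799,
                   size_noncognate = 805, size_cognate = 795),
    rt_between_sd_ms = c(115, 120, 147, 142),
    rt_trial_sd_ms = 150,
    rt_floor_ms = 150,
    accuracy = c(naming_noncognate = 0.72, naming_cognate = 0.84,
                 size_noncognate = 0.79, size_cognate = 0.85),
    accuracy_sd = c(0.12, 0.09, 0.10, 0.09),
    baseline_window = c(-0.7, -0.2),
    measure_bands = list(theta = c(3, 7), beta = c(25, 35)),
    n_cycles = 5,
    analysis_freqs = 1:40,       # wavelet grid the injection is calibrated to
    analysis_pad = c(-5, 5),
    transfer_n_mc = 384,
    rng_seed = 1L)
  cfg <- modifyList(cfg, list(...))
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  if (any(cfg$beta_rel_change <= -1) || any(cfg$theta_rel_change <= -1))
    stop("relative power changes must be > -1 (power cannot go negative)")
  if (any(cfg$pac_target_mi < 0) || any(cfg$pac_target_mi >= 1))
    stop("pac_target_mi must lie in [0, 1)")
  if (any(cfg$accuracy <= 0) || any(cfg$accuracy > 1))
    stop("accuracy means must lie in (0, 1]")
  stopifnot(cfg$aperiodic_exponent >= 0)
  invisible(cfg)
}

cond_table <- function() {
  data.frame(task = rep(c("naming", "size"), each = 2),
             cognate = rep(c("noncognate", "cognate"), 2),
             key = c("naming_noncognate", "naming_cognate",
                     "size_noncognate", "size_cognate"),
             stringsAsFactors = FALSE)
}

#' Generate 1/f (aperiodic) background signal
#'
#' Shapes white Gaussian noise in the frequency domain so the expected
#' power spectrum is proportional to `1/f^exponent` (flattened below 1 Hz
#' to avoid the DC singularity), then scales to the requested amplitude
#' (standard deviation).
#'
#' @param n_samples number of samples (>= 2).
#' @param sfreq sampling rate (Hz).
#' @param exponent spectral exponent chi >= 0 (0 = white).
#' @param amplitude target signal SD.
#' @param n_signals number of independent signals.
#' @return numeric vector (or `n_samples` x `n_signals` matrix).
#' @export
generate_background_1f <- function(n_samples, sfreq, exponent = 1,
                                   amplitude = 1, n_signals = 1) {
  if (n_samples < 2) stop("n_samples must be >= 2")
  if (exponent < 0) stop("exponent must be >= 0")
  w <- bg_shaping_weights(n_samples, sfreq, exponent)
  x <- matrix(rnorm(n_samples * n_signals), n_samples, n_signals)
  X <- stats::mvfft(x) * w
  b <- Re(stats::mvfft(X, inverse = TRUE)) / n_samples
  b <- b * amplitude / sqrt(sum(w^2) / n_samples)
  if (n_signals == 1) drop(b) else b
}

bg_shaping_weights <- function(n, sfreq, exponent) {
  f <- (seq_len(n) - 1) * sfreq / n
  f <- ifelse(f > sfreq / 2, sfreq - f, f)   # fold to |f|
  1 / pmax(f, 1)^(exponent / 2)
}

# Smooth effect-window profile: raised-cosine-edged plateau. The plateau
# extends `extend` beyond the nominal window (but starts no earlier than
# `min_onset`) so that, after the wavelet's temporal smoothing, the
# band-power estimate inside the nominal window sits at the plateau value.
effect_profile <- function(times, window, extend, ramp, min_onset = 0.01) {
  from <- max(window[1] - extend, min_onset)
  to <- window[2] + extend
  p <- numeric(length(times))
  p[times >= from & times <= to] <- 1
  up <- times > from - ramp & times < from
  p[up] <- 0.5 * (1 + cos(pi * (from - times[up]) / ramp))
  dn <- times > to & times < to + ramp
  p[dn] <- 0.5 * (1 + cos(pi * (times[dn] - to) / ramp))
  p
}

profile_params <- function(freq) {
  if (freq >= 15) list(extend = 0.05, ramp = 0.03)
  else list(extend = 0.15, ramp = 0.10)
}

#' Inject a band-limited oscillatory effect
#'
#' Adds a sinusoid at `freq` whose amplitude is
#' `baseline_amp * sqrt(1 + rel_change * profile(t))`, so the
#' baseline-relative band-power change inside the effect window equals
#' `rel_change` in expectation (power is amplitude squared). When
#' `channels` is given, the effect is scaled by 1 on those channels, by
#' `neighbor_falloff` on their immediate montage neighbours and 0
#' elsewhere (the baseline oscillation is still added everywhere). The
#' phase of each trial-channel oscillation is random and recorded so a
#' subsequent [inject_pac()] can couple to it.
#'
#' @param epochs an `eeg_epochs`.
#' @param freq oscillation frequency (Hz), inside (0, Nyquist).
#' @param rel_change relative power change (> -1) inside the window.
#' @param window effect window (s); `NULL` for no effect.
#' @param baseline_amp oscillation amplitude outside the window.
#' @param channels ROI channel names (`NULL` = effect everywhere).
#' @param montage montage used to find ROI neighbours.
#' @param neighbor_falloff effect multiplier on ROI neighbours.
#' @param trial_amp trial-wise amplitude multipliers (default 1).
#' @return epochs with the component added.
#' @export
inject_oscillation_effect <- function(epochs, freq, rel_change = 0,
                                      window = NULL, baseline_amp = 1,
                                      channels = NULL, montage = NULL,
                                      neighbor_falloff = 0.5,
                                      trial_amp = NULL) {
  if (freq <= 0 || freq >= epochs$sfreq / 2)
    stop("oscillation frequency must lie inside (0, sfreq/2)")
  if (rel_change <= -1) stop("rel_change must be > -1")
  d <- dim(epochs$data)
  gains <- roi_gains(epochs$channels, channels, montage, neighbor_falloff)
  pp <- profile_params(freq)
  if (!is.null(window) &&
      (window[1] < min(epochs$times) || window[2] > max(epochs$times)))
    stop("effect window must lie inside the epoch")
  prof <- if (is.null(window)) numeric(d[3])
          else effect_profile(epochs$times, window, pp$extend, pp$ramp)
  if (is.null(trial_amp)) trial_amp <- rep(1, d[1])
  phi <- matrix(runif(d[1] * d[2], 0, 2 * pi), d[1], d[2])
  env <- sqrt(1 + outer(gains * rel_change, prof))          # ch x s
  arg <- outer(phi, 2 * pi * freq * epochs$times, "+")      # tr x ch x s
  comp <- baseline_amp * trial_amp *
    aperm(array(env, c(d[2], d[3], d[1])), c(3, 1, 2)) * cos(arg)
  epochs$data <- epochs$data + comp
  ph <- attr(epochs, "injected_phases")
  if (is.null(ph)) ph <- list()
  ph[[format(freq)]] <- phi
  attr(epochs, "injected_phases") <- ph
  epochs
}

roi_gains <- function(all_channels, roi, montage, falloff) {
  if (is.null(roi)) return(rep(1, length(all_channels)))
  if (is.null(montage)) stop("ROI-restricted effects need a montage")
  idx <- match(roi, montage$names)
  if (anyNA(idx)) stop("unknown channel: ",
                       paste(roi[is.na(idx)], collapse = ", "))
  nb <- montage$names[colSums(montage$neighbors[idx, , drop = FALSE]) > 0]
  gains <- numeric(length(all_channels))
  gains[all_channels %in% nb] <- falloff
  gains[all_channels %in% roi] <- 1
  gains
}

#' Inject theta-phase-coupled beta activity
#'
#' Adds a beta-band carrier whose instantaneous amplitude follows
#' `a * (1 + m * cos(phi_theta(t))) / (1 + m)`, where `phi_theta` is the
#' phase of the theta component previously added by
#' [inject_oscillation_effect()] at `theta_freq`.
#'
#' @param epochs an `eeg_epochs` that already carries an injected theta
#'   oscillation at `theta_freq`.
#' @param theta_freq phase-providing frequency (Hz), < `beta_freq`.
#' @param beta_freq carrier frequency (Hz).
#' @param coupling_m modulation depth in `[0, 1]`.
#' @param amplitude carrier base amplitude `a`.
#' @param rel_change,window,channels,montage,neighbor_falloff optional
#'   beta-band effect envelope applied to the carrier (same convention as
#'   [inject_oscillation_effect()]).
#' @return epochs with the coupled carrier added.
#' @export
inject_pac <- function(epochs, theta_freq, beta_freq, coupling_m,
                       amplitude = 1, rel_change = 0, window = NULL,
                       channels = NULL, montage = NULL,
                       neighbor_falloff = 0.5) {
  if (theta_freq >= beta_freq) stop("theta_freq must be below beta_freq")
  if (coupling_m < 0 || coupling_m > 1)
    stop("coupling_m must lie in [0, 1]")
  ph <- attr(epochs, "injected_phases")
  key <- format(theta_freq)
  if (is.null(ph) || is.null(ph[[key]]))
    stop("no injected theta component at ", theta_freq,
         " Hz; call inject_oscillation_effect() first")
  phi_t <- ph[[key]]
  d <- dim(epochs$data)
  gains <- roi_gains(epochs$channels, channels, montage, neighbor_falloff)
  pp <- profile_params(beta_freq)
  prof <- if (is.null(window)) numeric(d[3])
          else effect_profile(epochs$times, window, pp$extend, pp$ramp)
  env <- sqrt(1 + outer(gains * rel_change, prof))          # ch x s
  theta_phase <- outer(phi_t, 2 * pi * theta_freq * epochs$times, "+")
  modul <- (1 + coupling_m * cos(theta_phase)) / (1 + coupling_m)
  phi_b <- matrix(runif(d[1] * d[2], 0, 2 * pi), d[1], d[2])
  carrier <- cos(outer(phi_b, 2 * pi * beta_freq * epochs$times, "+"))
  envf <- aperm(array(env, c(d[2], d[3], d[1])), c(3, 1, 2))
  epochs$data <- epochs$data + amplitude * envf * modul * carrier
  epochs
}

# ---- injection transfer calibration --------------------------------------
#
# The configured condition effects must be what the analysis pipeline
# recovers. The map from an injected relative power change to the value
# the full spectral chain measures is diluted by the wavelet's temporal
# smoothing of the effect window, by aperiodic background power inside the
# measured band, and by what the iterative 1/f fit absorbs of the
# oscillatory bump. Rather than modelling those jointly, the generator
# measures the map empirically: Monte-Carlo single-channel condition
# trials are pushed through the actual chain (Morlet -> 1/f fit and
# subtraction -> trial averaging -> baseline normalization -> band mean)
# on a grid of injected values, and the monotone curve is inverted per
# subject. Curves use fixed internal seeds (common random numbers across
# grid points) and are memoized per configuration.

transfer_cache <- new.env(parent = emptyenv())

# one-channel condition trials with injected changes (r_beta on the beta
# oscillation and carrier envelope, r_theta on theta), measured through
# the spectral chain; returns the band-window mean per band
measure_band_change <- function(r_theta, r_beta, cfg, task, m_carrier,
                                n_mc = 96, seed = 424243L,
                                trials_per_fit = NULL) {
  # measure in groups of trials_per_fit so the 1/f fit operates on means
  # of as many trials as a subject's correct-trial average provides
  if (is.null(trials_per_fit)) trials_per_fit <- n_mc
  n_groups <- max(1L, round(n_mc / trials_per_fit))
  n_mc <- n_groups * trials_per_fit
  set.seed(seed)
  dt <- 1 / cfg$sfreq
  times <- seq(cfg$epoch_window[1], cfg$epoch_window[2] - dt, by = dt)
  n_s <- length(times)
  win <- cfg$effect_windows[[task]]
  f_t <- cfg$osc_freqs[["theta"]]; f_b <- cfg$osc_freqs[["beta"]]
  ppt <- profile_params(f_t); ppb <- profile_params(f_b)
  env_t <- sqrt(pmax(1 + r_theta * effect_profile(times, win, ppt$extend,
                                                  ppt$ramp), 0))
  env_b <- sqrt(pmax(1 + r_beta * effect_profile(times, win, ppb$extend,
                                                 ppb$ramp), 0))
  bg <- generate_background_1f(n_s, cfg$sfreq, cfg$aperiodic_exponent,
                               cfg$aperiodic_amplitude, n_signals = n_mc)
  eps_t <- exp(rnorm(n_mc, 0, cfg$trial_amp_nu) - cfg$trial_amp_nu^2)
  eps_b <- exp(rnorm(n_mc, 0, cfg$trial_amp_nu) - cfg$trial_amp_nu^2)
  x <- matrix(0, n_mc, n_s)
  for (k in seq_len(n_mc)) {
    theta_phase <- 2 * pi * f_t * times + runif(1, 0, 2 * pi)
    x[k, ] <- bg[, k] + rnorm(n_s, 0, cfg$noise_sd) +
      cfg$osc_amplitudes[["theta"]] * eps_t[k] * env_t * cos(theta_phase) +
      cfg$osc_amplitudes[["beta"]] * eps_b[k] * env_b *
        cos(2 * pi * f_b * times + runif(1, 0, 2 * pi)) +
      cfg$osc_amplitudes[["pac"]] * env_b *
        (1 + m_carrier * cos(theta_phase)) / (1 + m_carrier) *
        cos(2 * pi * f_b * times + runif(1, 0, 2 * pi))
  }
  ep <- epoched_dataset(array(x, c(n_mc, 1, n_s)), sfreq = cfg$sfreq,
                        times = times, channels = "ROI", task = task,
                        cognate = rep(sprintf("g%03d", seq_len(n_groups)),
                                      each = trials_per_fit),
                        correct = TRUE)
  tfr <- morlet_tfr(pad_epochs(ep, cfg$analysis_pad),
                    freqs = cfg$analysis_freqs,
                    n_cycles = cfg$n_cycles, t_step = 0.02,
                    tmin = cfg$baseline_window[1] - 0.05,
                    tmax = win[2] + 0.05)
  avg <- average_tfr(tfr)
  fit <- fit_fractal(avg)
  corr <- subtract_fractal(avg, fit)
  norm <- baseline_normalize(corr, baseline = cfg$baseline_window)
  vapply(c("theta", "beta"), function(b)
    mean(band_power(norm, cfg$measure_bands[[b]], win)$power), 0)
}

# Joint injected -> measured transfer surface for one task: both band
# values are measured from the same Monte-Carlo runs on a 2-D grid of
# injected (theta, beta) changes. Grid points use independent seeds so
# the bilinear interpolation averages their Monte-Carlo noise. Memoized
# per configuration.
transfer_surface <- function(cfg, task, m_carrier) {
  jj <- which(cond_table()$task == task)
  trials_per_fit <- max(4L, round(mean(cfg$accuracy[jj]) *
                                    cfg$trials_per_condition))
  key_fields <- list(task = task, m = round(m_carrier, 2),
                     tpf = trials_per_fit,
                     cfg = cfg[c("sfreq", "epoch_window",
                                 "aperiodic_exponent", "aperiodic_amplitude",
                                 "noise_sd", "osc_freqs", "osc_amplitudes",
                                 "trial_amp_nu", "effect_windows",
                                 "baseline_window", "measure_bands",
                                 "n_cycles", "analysis_freqs",
                                 "analysis_pad", "transfer_n_mc")])
  key <- hash_object(key_fields)
  if (!is.null(transfer_cache[[key]])) return(transfer_cache[[key]])
  grid_t <- c(-0.5, 0.1, 0.7, 1.5, 2.6)
  grid_b <- c(-0.95, -0.8, -0.6, -0.35, -0.1, 0.2)
  m_theta <- m_beta <- matrix(0, length(grid_t), length(grid_b))
  for (i in seq_along(grid_t)) for (k in seq_along(grid_b)) {
    v <- measure_band_change(grid_t[i], grid_b[k], cfg, task, m_carrier,
                             n_mc = cfg$transfer_n_mc,
                             seed = 424243L + 97L * i + 13L * k,
                             trials_per_fit = trials_per_fit)
    m_theta[i, k] <- v[["theta"]]
    m_beta[i, k] <- v[["beta"]]
  }
  out <- list(grid_t = grid_t, grid_b = grid_b,
              m_theta = m_theta, m_beta = m_beta)
  transfer_cache[[key]] <- out
  out
}

# 1-D linear interpolation with clamped extrapolation
interp_clamped <- function(xg, yg, x) {
  stats::approx(xg, yg, xout = min(max(x, min(xg)), max(xg)), rule = 2)$y
}

# invert a monotone sampled curve (isotonic-smoothed) at a target value
inverse_on_grid <- function(xg, yg, target) {
  iso <- stats::isoreg(xg, yg)
  yf <- iso$yf
  keep <- !duplicated(yf)
  if (sum(keep) < 2) return(xg[which.min(abs(yf - target))])
  stats::approx(yf[keep], xg[keep], xout = min(max(target, min(yf)),
                                               max(yf)), rule = 2)$y
}

# joint inversion of the two-band transfer surface by fixed point: each
# step solves one band's 1-D inverse with the other band held at its
# current injected value (the cross-band coupling is weak)
invert_joint <- function(surf, target_theta, target_beta, n_iter = 12) {
  r_t <- target_theta; r_b <- target_beta
  for (it in seq_len(n_iter)) {
    curve_b <- vapply(seq_along(surf$grid_b), function(k)
      interp_clamped(surf$grid_t, surf$m_beta[, k], r_t), 0)
    r_b_new <- inverse_on_grid(surf$grid_b, curve_b, target_beta)
    curve_t <- vapply(seq_along(surf$grid_t), function(i)
      interp_clamped(surf$grid_b, surf$m_theta[i, ], r_b_new), 0)
    r_t_new <- inverse_on_grid(surf$grid_t, curve_t, target_theta)
    done <- abs(r_t_new - r_t) < 1e-4 && abs(r_b_new - r_b) < 1e-4
    r_t <- r_t_new; r_b <- r_b_new
    if (done) break
  }
  c(theta = r_t, beta = r_b)
}

# ---- cohort generation ---------------------------------------------------

subject_effects <- function(cfg, i) {
  set.seed((cfg$rng_seed * 1009L + i * 7919L) %% .Machine$integer.max)
  sc <- cfg$between_sd_scale
  # behavioral between-subject variance decomposes into a shared subject
  # baseline (overall speed / ability, the bulk of the reported
  # across-subject SDs) plus small condition-specific deviations, so the
  # within-subject condition contrasts keep realistic paired t statistics
  acc_cond_sd <- 0.04
  rt_cond_sd <- 15
  acc_shared <- sqrt(pmax(mean(cfg$accuracy_sd^2) -
    mean(cfg$accuracy * (1 - cfg$accuracy)) / cfg$trials_per_condition -
    acc_cond_sd^2, 0.02^2))
  rt_shared <- sqrt(pmax(mean(cfg$rt_between_sd_ms^2) -
    cfg$rt_trial_sd_ms^2 / (0.8 * cfg$trials_per_condition) -
    rt_cond_sd^2, 30^2))
  acc_base <- rnorm(1, 0, acc_shared)
  rt_base <- rnorm(1, 0, rt_shared)
  list(
    beta_r = pmax(rnorm(4, cfg$beta_rel_change, sc * cfg$beta_rel_sd), -0.95),
    theta_r = pmax(rnorm(4, cfg$theta_rel_change, sc * cfg$theta_rel_sd),
                   -0.95),
    pac_scale = exp(rnorm(4, 0, cfg$pac_subject_cv) - cfg$pac_subject_cv^2 / 2),
    accuracy = pmin(pmax(cfg$accuracy + acc_base +
                           rnorm(4, 0, acc_cond_sd), 0.2), 1),
    rt_mean = pmax(cfg$rt_mean_ms + rt_base + rnorm(4, 0, rt_cond_sd), 300),
    keys = cond_table()$key)
}

#' Generate a synthetic EEG + behavior cohort
#'
#' Produces one epoched dataset per subject (all four task x cognate
#' cells, `trials_per_condition` trials each) plus a behavioral table.
#' Oscillatory condition effects are injected through an empirically
#' calibrated transfer map, so the configured relative power changes are
#' what the full spectral pipeline recovers in expectation; theta-beta coupling
#' strength is set per condition by [calibrate_coupling()] against the
#' configured modulation-index targets. Everything is deterministic given
#' `rng_seed`.
#'
#' @param cfg a `synthetic_config`.
#' @param verbose print per-subject progress.
#' @return list with `epochs` (list of `eeg_epochs`), `behavior` (tibble:
#'   subject, task, cognate, trial, correct, rt_ms), `montage`, `coupling`
#'   (per-condition calibrated modulation depths) and `config`.
#' @export
generate_cohort <- function(cfg = synthetic_config(), verbose = FALSE) {
  validate_synthetic_config(cfg)
  montage <- load_montage(cfg$montage)
  channels <- if (is.null(cfg$channels)) montage$names else cfg$channels
  miss <- setdiff(channels, montage$names)
  if (length(miss)) stop("unknown channel: ", paste(miss, collapse = ", "))
  ct <- cond_table()

  # coupling depths and injection transfers are calibration constants of
  # the configuration (fixed internal seeds), not cohort randomness, so
  # identically configured cohorts share them via the memoization cache
  coupling <- rep(0, 4); names(coupling) <- ct$key
  if (isTRUE(cfg$pac_enabled)) {
    coupling[] <- vapply(seq_len(4), function(j) {
      ns <- pac_noise_settings(cfg, ct$task[j], ct$key[j])
      calibrate_coupling(cfg$pac_target_mi[j], ns,
                         seed = 98321L + 541L * j)$coupling_m
    }, 0)
  }
  # one joint transfer surface per task at the task-mean coupling depth,
  # built lazily: zero-effect configurations never need one
  surface_env <- new.env(parent = emptyenv())
  surface_for <- function(task) {
    if (is.null(surface_env[[task]])) {
      jj <- which(ct$task == task)
      surface_env[[task]] <-
        transfer_surface(cfg, task, round(mean(coupling[jj]), 2))
    }
    surface_env[[task]]
  }

  n_tr <- cfg$trials_per_condition
  dt <- 1 / cfg$sfreq
  times <- seq(cfg$epoch_window[1], cfg$epoch_window[2] - dt, by = dt)
  n_s <- length(times); n_ch <- length(channels)
  epochs_list <- vector("list", cfg$n_subjects)
  behav <- vector("list", cfg$n_subjects)

  for (i in seq_len(cfg$n_subjects)) {
    eff <- subject_effects(cfg, i)
    set.seed((cfg$rng_seed * 2003L + i * 104729L) %% .Machine$integer.max)
    sub_id <- sprintf("S%02d", i)
    dat <- vector("list", 4)
    rows <- vector("list", 4)
    for (j in seq_len(4)) {
      task <- ct$task[j]
      bg <- generate_background_1f(n_s, cfg$sfreq, cfg$aperiodic_exponent,
                                   cfg$aperiodic_amplitude,
                                   n_signals = n_tr * n_ch)
      dim(bg) <- c(n_s, n_tr, n_ch)
      ep <- epoched_dataset(
        aperm(bg, c(2, 3, 1)) +
          array(rnorm(n_tr * n_ch * n_s, 0, cfg$noise_sd),
                c(n_tr, n_ch, n_s)),
        sfreq = cfg$sfreq, times = times, channels = channels,
        task = task, cognate = ct$cognate[j], subject_id = sub_id)
      if (eff$theta_r[j] == 0 && eff$beta_r[j] == 0) {
        theta_inj <- 0; beta_inj <- 0
      } else {
        inj <- invert_joint(surface_for(task), eff$theta_r[j], eff$beta_r[j])
        theta_inj <- inj[["theta"]]; beta_inj <- inj[["beta"]]
      }
      eps_t <- exp(rnorm(n_tr, 0, cfg$trial_amp_nu) - cfg$trial_amp_nu^2)
      eps_b <- exp(rnorm(n_tr, 0, cfg$trial_amp_nu) - cfg$trial_amp_nu^2)
      ep <- inject_oscillation_effect(ep, cfg$osc_freqs[["theta"]],
        rel_change = theta_inj, window = cfg$effect_windows[[task]],
        baseline_amp = cfg$osc_amplitudes[["theta"]],
        channels = cfg$effect_rois[[task]], montage = montage,
        neighbor_falloff = cfg$neighbor_falloff, trial_amp = eps_t)
      ep <- inject_oscillation_effect(ep, cfg$osc_freqs[["beta"]],
        rel_change = beta_inj, window = cfg$effect_windows[[task]],
        baseline_amp = cfg$osc_amplitudes[["beta"]],
        channels = cfg$effect_rois[[task]], montage = montage,
        neighbor_falloff = cfg$neighbor_falloff, trial_amp = eps_b)
      m_j <- if (isTRUE(cfg$pac_enabled))
        min(coupling[j] * eff$pac_scale[j], 1) else 0
      ep <- inject_pac(ep, cfg$osc_freqs[["theta"]], cfg$osc_freqs[["beta"]],
        coupling_m = m_j, amplitude = cfg$osc_amplitudes[["pac"]],
        rel_change = beta_inj, window = cfg$effect_windows[[task]],
        channels = cfg$effect_rois[[task]], montage = montage,
        neighbor_falloff = cfg$neighbor_falloff)
      attr(ep, "injected_phases") <- NULL
      dat[[j]] <- ep
      correct <- rbinom(n_tr, 1, eff$accuracy[j]) == 1
      rt <- pmax(rnorm(n_tr, eff$rt_mean[j], cfg$rt_trial_sd_ms),
                 cfg$rt_floor_ms)
      rows[[j]] <- tibble::tibble(subject = sub_id, task = task,
                                  cognate = ct$cognate[j],
                                  trial = seq_len(n_tr),
                                  correct = correct, rt_ms = rt)
    }
    all_data <- array(NA_real_, c(4 * n_tr, n_ch, n_s))
    for (j in seq_len(4))
      all_data[((j - 1) * n_tr + 1):(j * n_tr), , ] <- dat[[j]]$data
    beh <- do.call(rbind, rows)
    epochs_list[[i]] <- epoched_dataset(
      all_data, sfreq = cfg$sfreq, times = times, channels = channels,
      task = rep(ct$task, each = n_tr), cognate = rep(ct$cognate, each = n_tr),
      correct = beh$correct, subject_id = sub_id)
    behav[[i]] <- beh
    if (verbose) message("generated subject ", sub_id)
  }
  list(epochs = epochs_list, behavior = do.call(rbind, behav),
       montage = montage, coupling = coupling, config = cfg)
}

#' Write a cohort's behavioral table as TSV
#' @param cohort result of [generate_cohort()].
#' @param path output file.
#' @export
write_behavior <- function(cohort, path) {
  utils::write.table(cohort$behavior, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

# ---- coupling calibration ------------------------------------------------

#' Settings of the single-channel trial model used to calibrate coupling
#'
#' Describes the signal composition of one ROI channel in one condition
#' (background, sensor noise, theta and beta oscillations with that
#' condition's effect envelopes, the PAC carrier) together with the MI
#' estimator's measurement parameters, so [calibrate_coupling()] maps a
#' target modulation index onto a coupling depth under the same
#' conditions the cohort realizes.
#'
#' @param cfg a `synthetic_config`.
#' @param task `"naming"` or `"size"`.
#' @param cond_key one of the four condition keys.
#' @param n_trials Monte-Carlo trials per MI evaluation.
#' @return a list of settings.
#' @export
pac_noise_settings <- function(cfg, task = "size",
                               cond_key = "size_noncognate",
                               n_trials = 128) {
  j <- match(cond_key, cond_table()$key)
  if (is.na(j)) stop("unknown condition key: ", cond_key)
  # nominal effect envelopes; the MI is essentially insensitive to the
  # slow within-window power scaling, so the uninverted condition means
  # are used here
  list(cfg = cfg, task = task,
       theta_inj = unname(cfg$theta_rel_change[j]),
       beta_inj = unname(cfg$beta_rel_change[j]),
       n_trials = n_trials)
}

# mean MI of Monte-Carlo single-channel condition trials at coupling m,
# measured exactly like pac_condition_mean() measures the cohort
calibration_mi <- function(m, ns) {
  cfg <- ns$cfg
  dt <- 1 / cfg$sfreq
  times <- seq(cfg$epoch_window[1], cfg$epoch_window[2] - dt, by = dt)
  n_s <- length(times)
  win <- cfg$effect_windows[[ns$task]]
  f_t <- cfg$osc_freqs[["theta"]]; f_b <- cfg$osc_freqs[["beta"]]
  ppt <- profile_params(f_t); ppb <- profile_params(f_b)
  env_t <- sqrt(1 + ns$theta_inj * effect_profile(times, win, ppt$extend,
                                                  ppt$ramp))
  env_b <- sqrt(1 + ns$beta_inj * effect_profile(times, win, ppb$extend,
                                                 ppb$ramp))
  seg <- pac_segment_index(times, win, f_t)
  mis <- vapply(seq_len(ns$n_trials), function(k) {
    phi_t <- runif(1, 0, 2 * pi)
    eps_t <- exp(rnorm(1, 0, cfg$trial_amp_nu) - cfg$trial_amp_nu^2)
    eps_b <- exp(rnorm(1, 0, cfg$trial_amp_nu) - cfg$trial_amp_nu^2)
    theta_phase <- 2 * pi * f_t * times + phi_t
    x <- generate_background_1f(n_s, cfg$sfreq, cfg$aperiodic_exponent,
                                cfg$aperiodic_amplitude) +
      rnorm(n_s, 0, cfg$noise_sd) +
      cfg$osc_amplitudes[["theta"]] * eps_t * env_t * cos(theta_phase) +
      cfg$osc_amplitudes[["beta"]] * eps_b * env_b *
        cos(2 * pi * f_b * times + runif(1, 0, 2 * pi)) +
      cfg$osc_amplitudes[["pac"]] * env_b *
        (1 + m * cos(theta_phase)) / (1 + m) *
        cos(2 * pi * f_b * times + runif(1, 0, 2 * pi))
    pa <- phase_amplitude_series(x, cfg$sfreq, f_t, f_b,
                                 theta_bw_sd = cfg$theta_filter_sd,
                                 beta_bw_sd = cfg$beta_filter_sd)
    modulation_index(pa$phase[seg], pa$amplitude[seg]^2)$mi
  }, 0)
  mean(mis)
}

#' Calibrate the PAC coupling depth for a target modulation index
#'
#' Monotone bisection on the coupling depth `m`: Monte-Carlo trials are
#' generated under the condition's signal model and measured with the
#' package's MI estimator until the mean MI is within `tol` (relative) of
#' the target. Errors when the target lies below the estimator's noise
#' floor or above the MI reachable at `m = 1`.
#'
#' @param target_mi target mean modulation index.
#' @param noise_settings from [pac_noise_settings()].
#' @param tol relative tolerance (default 0.05).
#' @param seed RNG seed for the Monte-Carlo draws.
#' @return list with `coupling_m` and `achieved_mi`.
#' @export
calibrate_coupling <- function(target_mi, noise_settings, tol = 0.05,
                               seed = 1L) {
  eval_mi <- function(m) {
    set.seed(seed)        # common random numbers keep the map monotone
    calibration_mi(m, noise_settings)
  }
  lo <- 0; hi <- 1
  mi_lo <- eval_mi(lo); mi_hi <- eval_mi(hi)
  if (target_mi < mi_lo * (1 - tol))
    stop(sprintf(paste0("target MI %.4f is below the noise floor %.4f; ",
                        "achievable range is [%.4f, %.4f]"),
                 target_mi, mi_lo, mi_lo, mi_hi))
  if (target_mi > mi_hi * (1 + tol))
    stop(sprintf(paste0("target MI %.4f exceeds the maximum %.4f; ",
                        "achievable range is [%.4f, %.4f]"),
                 target_mi, mi_hi, mi_lo, mi_hi))
  if (target_mi <= mi_lo) return(list(coupling_m = 0, achieved_mi = mi_lo))
  m <- 0.5; mi <- eval_mi(m)
  for (it in seq_len(30)) {
    if (abs(mi - target_mi) <= tol * target_mi) break
    if (mi < target_mi) lo <- m else hi <- m
    m <- (lo + hi) / 2
    mi <- eval_mi(m)
  }
  list(coupling_m = m, achieved_mi = mi)
}
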