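# Shared fixtures built in code.

# single-signal epochs object on a -1..+1 s axis at 500 Hz
signal_epochs <- function(signal, sfreq = 500, n_channels = 1,
                          channels = paste0("ch", seq_len(n_channels))) {
  n <- length(signal)
  times <- (seq_len(n) - 1 - n / 2) / sfreq
  data <- array(rep(signal, each = n_channels), c(1, n_channels, n))
  epoched_dataset(data, sfreq = sfreq, times = times, channels = channels)
}

# multi-trial epochs from a trials x samples matrix (one channel)
trials_epochs <- function(x, sfreq = 500, ...) {
  n <- ncol(x)
  times <- (seq_len(n) - 1 - n / 2) / sfreq
  epoched_dataset(array(x, c(nrow(x), 1, n)), sfreq = sfreq, times = times,
                  channels = "ch1", ...)
}

# montage from explicit planar-ish 3-D positions
positions_montage <- function(names, pos3d) {
  tf <- tempfile(fileext = ".tsv")
  df <- data.frame(name = names, x = pos3d[, 1], y = pos3d[, 2],
                   z = pos3d[, 3])
  utils::write.table(df, tf, sep = "\t", row.names = FALSE, quote = FALSE)
  load_montage(tf)
}

# small fast synthetic configuration: no condition effects, no coupling,
# 3 channels -- cheap enough for structural/determinism tests (the zero
# effects mean no transfer surfaces have to be calibrated)
null_synth_config <- function(...) {
  defaults <- list(
    n_subjects = 2L,
    channels = c("Cz", "C3", "C4"),
    beta_rel_change = c(naming_noncognate = 0, naming_cognate = 0,
                        size_noncognate = 0, size_cognate = 0),
    theta_rel_change = c(naming_noncognate = 0, naming_cognate = 0,
                         size_noncognate = 0, size_cognate = 0),
    beta_rel_sd = c(0, 0, 0, 0),
    theta_rel_sd = c(0, 0, 0, 0),
    pac_enabled = FALSE)
  do.call(synthetic_config, utils::modifyList(defaults, list(...)))
}

# independent Delaunay-edge oracle: an edge {p, q} belongs to the Delaunay
# graph iff some disk through p and q contains no other point, i.e. the
# feasibility interval for the circumcentre along the perpendicular
# bisector is nonempty (boundary contacts allowed).
delaunay_edge_oracle <- function(pos2d) {
  n <- nrow(pos2d)
  span <- max(apply(pos2d, 2, function(v) diff(range(v))))
  eps <- 1e-9 * max(span, 1)^2
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    p <- pos2d[i, ]; q <- pos2d[j, ]
    mid <- (p + q) / 2
    d <- c(-(q - p)[2], (q - p)[1])
    d <- d / sqrt(sum(d^2))
    lo <- -Inf; hi <- Inf
    feasible <- TRUE
    for (k in seq_len(n)) {
      if (k == i || k == j) next
      x <- pos2d[k, ]
      a <- sum(p^2) - sum(x^2) - 2 * sum(mid * (p - x))
      b <- -2 * sum(d * (p - x))
      if (abs(b) < 1e-14) {
        if (a > eps) { feasible <- FALSE; break }
      } else if (b > 0) {
        hi <- min(hi, (eps - a) / b)
      } else {
        lo <- max(lo, (eps - a) / b)
      }
      if (lo > hi) { feasible <- FALSE; break }
    }
    adj[i, j] <- adj[j, i] <- feasible
  }
  adj
}

# brute-force FFT band power of one signal in a time window (independent of
# the wavelet path)
fft_band_power <- function(x, sfreq, band, times, window) {
  seg <- x[times >= window[1] & times < window[2]]
  n <- length(seg)
  f <- (seq_len(n) - 1) * sfreq / n
  p <- Mod(stats::fft(seg))^2 / n
  sum(p[f >= band[1] & f <= band[2]])
}
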