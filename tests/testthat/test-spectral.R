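# hand-built raw TFR for fit/subtract/normalize unit checks
make_tfr <- function(power, freqs, times, channels = "Cz") {
  structure(list(power = power, freqs = as.numeric(freqs),
                 times = times, channels = channels, stage = "raw",
                 task = rep("naming", dim(power)[1]),
                 cognate = rep("cognate", dim(power)[1]),
                 correct = rep(TRUE, dim(power)[1]),
                 subject_id = "S", groups = NULL), class = "eeg_tfr")
}

test_that("Morlet power localizes tones and scales quadratically", {
  t <- (0:1999) / 500 - 2
  tone <- function(a, f) a * sin(2 * pi * f * t)
  ep1 <- signal_epochs(tone(1, 10))
  tf1 <- morlet_tfr(ep1, freqs = 2:40, t_step = 0.02)
  prof <- apply(tf1$power[1, 1, , abs(tf1$times) < 0.8], 1, mean)
  expect_equal(tf1$freqs[which.max(prof)], 10)
  ep2 <- signal_epochs(tone(2, 10))
  tf2 <- morlet_tfr(ep2, freqs = 2:40, t_step = 0.02)
  expect_equal(mean(tf2$power[1, 1, 9, abs(tf2$times) < 0.8]) /
                 mean(tf1$power[1, 1, 9, abs(tf1$times) < 0.8]),
               4, tolerance = 1e-6)
  # two-tone signal: peaks within +-1 Hz of both components
  ep3 <- signal_epochs(tone(1, 6) + tone(1, 30))
  tf3 <- morlet_tfr(ep3, freqs = 2:40, t_step = 0.02)
  prof3 <- apply(tf3$power[1, 1, , abs(tf3$times) < 0.8], 1, mean)
  pk <- which(diff(sign(diff(prof3))) == -2) + 1
  pk_f <- tf3$freqs[pk][order(prof3[pk], decreasing = TRUE)][1:2]
  expect_true(any(abs(pk_f - 6) <= 1))
  expect_true(any(abs(pk_f - 30) <= 1))
})

test_that("Morlet power of summed orthogonal bands is nearly additive", {
  t <- (0:1999) / 500 - 2
  a <- sin(2 * pi * 6 * t); b <- sin(2 * pi * 30 * t)
  pw <- function(sig, fidx) {
    tf <- morlet_tfr(signal_epochs(sig), freqs = 2:40, t_step = 0.02)
    mean(tf$power[1, 1, fidx, abs(tf$times) < 0.7])
  }
  expect_equal(pw(a + b, 5), pw(a, 5), tolerance = 0.05)   # 6 Hz bin
  expect_equal(pw(a + b, 29), pw(b, 29), tolerance = 0.05) # 30 Hz bin
})

test_that("Morlet rejects invalid grids", {
  ep <- signal_epochs(rnorm(1000))
  expect_error(morlet_tfr(ep, freqs = c(10, 300)), "Nyquist")
  expect_error(morlet_tfr(ep, freqs = 1:40), "zero-pad")
  expect_error(morlet_tfr(ep, freqs = 10:20, t_step = 0.0031), "t_step")
  expect_error(morlet_tfr(ep, freqs = 10:20, channels = "nope"),
               "unknown channel")
})

test_that("fractal fit recovers an exact power law and flags bumps", {
  f <- 1:40
  times <- seq(-0.5, 0.5, by = 0.02)
  pl <- 100 * f^(-1.5)
  pow <- array(rep(pl, times = length(times)), c(1, 1, 40, length(times)))
  tfr <- make_tfr(pow, f, times)
  fit <- fit_fractal(tfr)
  expect_equal(unique(round(as.vector(fit$slope), 8)), -1.5)
  expect_equal(unique(round(as.vector(fit$intercept), 8)), round(log(100), 8))
  corr <- subtract_fractal(tfr, fit)
  expect_equal(range(corr$power), c(1, 1), tolerance = 1e-8)
  expect_equal(corr$stage, "fractal_corrected")
  # power law + narrow bump at 10 Hz
  bump <- 5 * pl[10] * exp(-(f - 10)^2 / 2)
  pow2 <- array(rep(pl + bump, times = length(times)),
                c(1, 1, 40, length(times)))
  tfr2 <- make_tfr(pow2, f, times)
  fit2 <- fit_fractal(tfr2)
  expect_lt(abs(fit2$slope[1, 1, 1] + 1.5), 0.1)
  expect_true(any(fit2$excluded[1, 1, 8:12, 1]))
  corr2 <- subtract_fractal(tfr2, fit2)
  expect_gt(corr2$power[1, 1, 10, 1], 4)
  expect_equal(mean(corr2$power[1, 1, c(1:4, 25:40), 1]), 1,
               tolerance = 0.15)
})

test_that("white spectra fit flat and aperiodic removal is idempotent", {
  f <- 1:40
  times <- seq(-0.1, 0.1, by = 0.02)
  set.seed(11)
  pow <- array(exp(rnorm(40 * length(times), sd = 0.05)),
               c(1, 1, 40, length(times)))
  tfr <- make_tfr(pow, f, times)
  fit <- fit_fractal(tfr)
  expect_lt(max(abs(fit$slope)), 0.1)
  corr <- subtract_fractal(tfr, fit)
  corr$stage <- "raw"                      # refit the corrected spectrum
  fit2 <- fit_fractal(corr)
  expect_lt(max(abs(fit2$slope)), 0.05)
  # grid mismatch is an error
  fitx <- fit; fitx$freqs <- 2:41
  expect_error(subtract_fractal(tfr, fitx), "grid")
})

test_that("fractal fit recovers generator exponents within 0.1", {
  set.seed(13)
  # fit the iterative aperiodic line to periodogram spectra of generated
  # background (the wavelet's bandwidth grows with frequency, so exponent
  # recovery is checked on a constant-bandwidth spectral estimate)
  recover <- function(chi) {
    mean(replicate(20, {
      x <- generate_background_1f(4000, 500, chi, 5)
      p <- Mod(stats::fft(x))^2 / length(x)
      fgrid <- (seq_along(x) - 1) * 500 / length(x)
      pw <- vapply(2:40, function(f)
        mean(p[abs(fgrid - f) <= 0.25]), 0)
      tfr <- make_tfr(array(pw, c(1, 1, 39, 1)), 2:40, 0)
      -mean(fit_fractal(tfr)$slope)
    }))
  }
  for (chi in c(0.5, 1, 1.5))
    expect_lt(abs(recover(chi) - chi), 0.1)
})

test_that("baseline normalization is the relative change on linear power", {
  f <- 25:35
  times <- seq(-0.8, 0.4, by = 0.02)
  pow <- array(10, c(1, 1, length(f), length(times)))
  post <- times > 0.1
  pow[, , , post] <- 10 * 0.79
  tfr <- make_tfr(pow, f, times)
  tfr$stage <- "fractal_corrected"
  norm <- baseline_normalize(tfr, baseline = c(-0.7, -0.2))
  expect_equal(unique(round(as.vector(norm$power[, , , post]), 10)), -0.21)
  expect_equal(unique(round(as.vector(norm$power[, , , !post]), 10)), 0)
  # stationary input normalizes to zero everywhere
  tfr0 <- make_tfr(array(3, c(1, 1, length(f), length(times))), f, times)
  n0 <- baseline_normalize(tfr0, c(-0.7, -0.2))
  expect_true(all(abs(n0$power) < 1e-12))
  expect_error(baseline_normalize(
    make_tfr(array(-1, c(1, 1, 2, 3)), 1:2, c(-0.6, -0.4, 0)),
    c(-0.7, -0.2)), "non-positive")
})

test_that("normalized power is invariant to global amplitude rescaling", {
  set.seed(14)
  x <- generate_background_1f(1000, 500, 1, 5) +
    2 * sin(2 * pi * 20 * ((0:999) / 500))
  chain <- function(sig) {
    ep <- pad_epochs(signal_epochs(sig), c(-3, 3))
    tf <- morlet_tfr(ep, freqs = 4:40, t_step = 0.02,
                     tmin = -0.75, tmax = 0.45)
    avg <- average_tfr(tf)
    corr <- subtract_fractal(avg, fit_fractal(avg))
    baseline_normalize(corr, c(-0.7, -0.2))
  }
  n1 <- chain(x)
  n2 <- chain(x * 7.3)
  expect_equal(n1$power, n2$power, tolerance = 1e-8)
})

test_that("band_power averages consistently and validates selections", {
  f <- 1:40
  times <- seq(-0.2, 0.4, by = 0.02)
  pow <- array(rnorm(2 * 3 * 40 * length(times)),
               c(2, 3, 40, length(times)))
  tfr <- make_tfr(pow, f, times, channels = c("a", "b", "c"))
  tfr$stage <- "baseline_normalized"
  got <- band_power(tfr, c(25, 35), c(0.1, 0.3), c("a", "c"))
  fs <- 25:35
  ts <- which(times >= 0.1 - 1e-9 & times <= 0.3 + 1e-9)
  manual <- mean(pow[1, c(1, 3), fs, ts])
  expect_equal(got$power[1], manual)
  # order of averaging does not matter on an equal-weight grid
  by_channel <- mean(vapply(c(1, 3), function(c) mean(pow[1, c, fs, ts]), 0))
  expect_equal(got$power[1], by_channel)
  # constant field returns the constant
  tfr2 <- make_tfr(array(0.5, c(1, 1, 40, length(times))), f, times)
  expect_equal(band_power(tfr2, c(3, 7), c(0, 0.2))$power, 0.5)
  expect_error(band_power(tfr, c(50, 60), c(0.1, 0.3)), "empty")
  expect_error(band_power(tfr, c(25, 35), c(0.1, 0.3), "zz"),
               "unknown channel")
})
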