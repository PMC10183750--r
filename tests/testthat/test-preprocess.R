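test_that("bandpass preserves passband tones and bandstop kills line noise", {
  t <- (0:4999) / 500
  tone10 <- sin(2 * pi * 10 * t)
  out <- butter_filter(tone10, 500, "bandpass", c(0.1, 100))
  mid <- 1000:4000
  expect_equal(max(abs(out[mid])), 1, tolerance = 0.01)
  tone50 <- sin(2 * pi * 50 * t)
  out50 <- butter_filter(tone50, 500, "bandstop", c(48, 52))
  expect_lt(max(abs(out50[mid])), 0.05)      # >= 95% attenuation
})

test_that("two-pass filtering is zero-phase (time-reversal symmetry)", {
  set.seed(4)
  x <- rnorm(2000)
  a <- butter_filter(rev(x), 500, "bandpass", c(1, 40))
  b <- rev(butter_filter(x, 500, "bandpass", c(1, 40)))
  # identical up to the slowly decaying low-edge transients (a causal
  # single-pass filter would differ by O(1) in phase)
  expect_lt(max(abs(a - b)[300:1700]), 0.05)
  expect_gt(cor(a[300:1700], b[300:1700]), 0.999)
  expect_error(butter_filter(x, 500, "bandpass", c(0, 300)), "inside")
  expect_error(butter_filter(c(x, NA), 500, "bandpass", c(1, 40)),
               "non-finite")
})

test_that("epoching zero-pads outside the signal window", {
  cont <- list(data = matrix(1, 1, 4000), sfreq = 500, channels = "Cz")
  ep <- epoch_and_pad(cont, event_samples = 2000)
  expect_equal(dim(ep$data), c(1, 1, 5000))
  inside <- ep$times >= -1 & ep$times < 1
  expect_true(all(ep$data[1, 1, inside] == 1))
  expect_true(all(ep$data[1, 1, !inside] == 0))
  expect_equal(sum(inside), 1000)
})

test_that("events too close to the recording edge are dropped and reported", {
  cont <- list(data = matrix(rnorm(2 * 4000), 2), sfreq = 500,
               channels = c("a", "b"))
  expect_message(ep <- epoch_and_pad(cont, c(1L, 2000L)), "dropped")
  expect_equal(dim(ep$data)[1], 1)
  expect_equal(attr(ep, "dropped_events"), 1L)
  expect_error(suppressMessages(epoch_and_pad(cont, 1L)), "no event")
})

test_that("64 events produce 64 ten-second epochs at 500 Hz", {
  cont <- list(data = matrix(rnorm(70000), 1), sfreq = 500, channels = "Cz")
  ev <- as.integer(seq(1000, 69000, length.out = 64))
  ep <- epoch_and_pad(cont, ev)
  expect_equal(dim(ep$data), c(64, 1, 5000))
  expect_equal(range(ep$times), c(-5, 5 - 1 / 500))
})

test_that("peak-to-peak rejection removes exactly the contaminated trial", {
  set.seed(8)
  x <- matrix(rnorm(20 * 1000, sd = 5), 20)
  x[7, 500] <- x[7, 500] + 500
  ep <- trials_epochs(x)
  res <- reject_trials(ep, threshold = 150)
  expect_equal(res$report$n_trials_rejected, 1)
  expect_equal(dim(res$epochs$data)[1], 19)
  expect_equal(res$report$fraction_rejected, 1 / 20)
  # clean data at the default threshold: nothing rejected
  clean <- reject_trials(trials_epochs(matrix(rnorm(10 * 1000, sd = 5), 10)),
                         threshold = 150)
  expect_equal(clean$report$n_trials_rejected, 0)
  # all-rejected is an explicit error
  expect_error(reject_trials(ep, threshold = 1e-6), "mis-set")
})

test_that("interpolation is a convex combination of good neighbours", {
  m <- load_montage("study38")
  nb <- m$names[m$neighbors["Cz", ]]
  n <- 200
  times <- (seq_len(n) - 1 - n / 2) / 500
  chans <- c("Cz", nb)
  set.seed(2)
  data <- array(rnorm(length(chans) * n), c(1, length(chans), n))
  # identical neighbour signals: interpolated channel equals them
  s <- sin(2 * pi * 7 * times)
  for (k in seq_along(nb)) data[1, k + 1, ] <- s
  ep <- epoched_dataset(data, 500, times, chans)
  fixed <- interpolate_channels(ep, "Cz", m)
  expect_equal(fixed$data[1, 1, ], s, tolerance = 1e-12)
  # convexity: always within the neighbour range
  data2 <- array(rnorm(length(chans) * n), c(1, length(chans), n))
  ep2 <- epoched_dataset(data2, 500, times, chans)
  fixed2 <- interpolate_channels(ep2, "Cz", m)
  rng <- apply(ep2$data[1, -1, , drop = FALSE], 3, range)
  expect_true(all(fixed2$data[1, 1, ] >= rng[1, ] - 1e-12 &
                    fixed2$data[1, 1, ] <= rng[2, ] + 1e-12))
})

test_that("equidistant neighbours collapse to a simple mean", {
  # centre channel with 4 symmetric neighbours
  pos <- rbind(c(0, 0, 1),
               c(0.3, 0, 0.954), c(-0.3, 0, 0.954),
               c(0, 0.3, 0.954), c(0, -0.3, 0.954))
  pos <- pos / sqrt(rowSums(pos^2))
  m <- positions_montage(c("ctr", "e1", "e2", "e3", "e4"), pos)
  n <- 100
  times <- (seq_len(n) - 1 - n / 2) / 500
  set.seed(3)
  data <- array(rnorm(5 * n), c(1, 5, n))
  ep <- epoched_dataset(data, 500, times, m$names)
  fixed <- interpolate_channels(ep, "ctr", m)
  expect_equal(fixed$data[1, 1, ], colMeans(data[1, 2:5, ]),
               tolerance = 1e-9)
})

test_that("isolated bad channels cannot be interpolated", {
  m <- load_montage("study38")
  ep <- epoched_dataset(array(rnorm(2 * 2 * 50), c(2, 2, 50)), 500,
                        (0:49 - 25) / 500, c("Cz", "Fz"))
  # Cz's montage neighbours are not present in the data
  expect_error(interpolate_channels(ep, "Cz", m), "fewer than 2")
})

test_that("average reference zeroes channel means and is idempotent", {
  set.seed(6)
  ep <- epoched_dataset(array(rnorm(3 * 5 * 100), c(3, 5, 100)), 500,
                        (0:99 - 50) / 500, paste0("c", 1:5))
  ref <- rereference_average(ep)
  mu <- apply(ref$data, c(1, 3), mean)
  expect_lt(max(abs(mu)), 1e-10)
  twice <- rereference_average(ref)
  expect_equal(twice$data, ref$data, tolerance = 1e-12)
  # bipolar derivations are invariant
  expect_equal(ref$data[, 2, ] - ref$data[, 4, ],
               ep$data[, 2, ] - ep$data[, 4, ], tolerance = 1e-12)
  expect_error(rereference_average(
    epoched_dataset(array(0, c(1, 1, 10)), 500, (0:9) / 500, "a")), ">= 2")
})

test_that("preprocess_epochs preserves trials except explicit rejections", {
  set.seed(10)
  x <- matrix(rnorm(12 * 1000, sd = 5), 12)
  x[3, 200] <- 400
  data2 <- array(0, c(12, 2, 1000))
  data2[, 1, ] <- x
  data2[, 2, ] <- x + rnorm(12 * 1000)
  ep2 <- epoched_dataset(data2, 500, (0:999 - 500) / 500, c("Cz", "Pz"))
  res <- preprocess_epochs(ep2, reject_threshold = 150)
  expect_equal(res$report$n_trials_total, 12)
  expect_equal(dim(res$epochs$data)[1],
               12 - res$report$n_trials_rejected)
  expect_equal(res$report$fraction_rejected,
               res$report$n_trials_rejected / 12)
})
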