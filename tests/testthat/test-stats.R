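# brute-force sums-of-squares oracle for the 2x2 within-subject ANOVA
anova_oracle <- function(d) {
  d$subject <- factor(d$subject); d$A <- factor(d$A); d$B <- factor(d$B)
  gm <- mean(d$value)
  mA <- tapply(d$value, d$A, mean)
  mB <- tapply(d$value, d$B, mean)
  mAB <- tapply(d$value, list(d$A, d$B), mean)
  mS <- tapply(d$value, d$subject, mean)
  mSA <- tapply(d$value, list(d$subject, d$A), mean)
  mSB <- tapply(d$value, list(d$subject, d$B), mean)
  n <- nlevels(d$subject)
  ss_A <- 2 * n * sum((mA - gm)^2)
  ss_B <- 2 * n * sum((mB - gm)^2)
  ss_AB <- n * sum((sweep(sweep(mAB, 1, mA), 2, mB) + gm)^2)
  ss_SA <- 2 * sum((sweep(sweep(mSA, 1, mS), 2, mA) + gm)^2) - 0
  ss_SB <- 2 * sum((sweep(sweep(mSB, 1, mS), 2, mB) + gm)^2) - 0
  ss_S <- 4 * sum((mS - gm)^2)
  ss_tot <- sum((d$value - gm)^2)
  ss_SAB <- ss_tot - ss_A - ss_B - ss_AB - ss_S - ss_SA - ss_SB
  list(F_A = (ss_A / 1) / (ss_SA / (n - 1)),
       F_B = (ss_B / 1) / (ss_SB / (n - 1)),
       F_AB = (ss_AB / 1) / (ss_SAB / (n - 1)),
       pes_A = ss_A / (ss_A + ss_SA),
       pes_B = ss_B / (ss_B + ss_SB),
       pes_AB = ss_AB / (ss_AB + ss_SAB),
       ss = c(ss_A, ss_B, ss_AB, ss_S, ss_SA, ss_SB, ss_SAB),
       ss_tot = ss_tot)
}

toy_table <- function(n = 4, seed = 1) {
  set.seed(seed)
  expand.grid(subject = paste0("s", 1:n), A = c("a1", "a2"),
              B = c("b1", "b2"), stringsAsFactors = FALSE) |>
    transform(value = rnorm(4 * n, sd = 2) +
                ifelse(A == "a2", 1, 0) + ifelse(B == "b2", 0.5, 0))
}

test_that("rm-ANOVA matches the brute-force sums-of-squares oracle", {
  d <- toy_table()
  res <- rm_anova_2x2(d, factors = c("A", "B"))
  orc <- anova_oracle(d)
  expect_equal(res$F, c(orc$F_A, orc$F_B, orc$F_AB), tolerance = 1e-10)
  expect_equal(res$pes, c(orc$pes_A, orc$pes_B, orc$pes_AB),
               tolerance = 1e-10)
  expect_equal(res$df1, c(1, 1, 1))
  expect_equal(res$df2, c(3, 3, 3))
  # SS decomposition is exhaustive (conservation) on random tables
  for (s in 2:4) {
    d2 <- toy_table(n = 6, seed = s)
    orc2 <- anova_oracle(d2)
    expect_equal(sum(orc2$ss), orc2$ss_tot, tolerance = 1e-10)
    res2 <- rm_anova_2x2(d2, factors = c("A", "B"))
    expect_equal(res2$F, c(orc2$F_A, orc2$F_B, orc2$F_AB),
                 tolerance = 1e-10)
  }
})

test_that("rm-ANOVA is translation invariant and handles null factors", {
  d <- toy_table(n = 6, seed = 9)
  r1 <- rm_anova_2x2(d, factors = c("A", "B"))
  d2 <- d; d2$value <- d$value + 100
  r2 <- rm_anova_2x2(d2, factors = c("A", "B"))
  expect_equal(r1$F, r2$F, tolerance = 1e-8)
  # a factor constant within subject x A: its F and pes are null
  mSA <- tapply(d$value, list(d$subject, d$A), mean)
  d4 <- d
  d4$value <- mSA[cbind(d$subject, d$A)]
  r4 <- rm_anova_2x2(d4, factors = c("A", "B"))
  expect_lt(r4$F[2], 1e-10)
  expect_lt(r4$pes[2], 1e-10)
  expect_error(rm_anova_2x2(d[-1, ], factors = c("A", "B")), "complete")
})

test_that("paired t returns d = t/sqrt(n) and a quadrature-checked BF", {
  set.seed(20)
  x <- rnorm(18, 1); y <- rnorm(18)
  res <- paired_t_cohen_bf(x, y)
  expect_equal(res$d, res$t / sqrt(18), tolerance = 1e-12)
  expect_equal(res$df, 17)
  expect_error(paired_t_cohen_bf(x, x + 2), "zero variance")
  # independent quadrature oracle on the transformed axis g = u/(1-u)
  bf_oracle <- function(t, n, r = sqrt(2) / 2) {
    nu <- n - 1
    u <- seq(1e-6, 1 - 1e-6, length.out = 20000)
    g <- u / (1 - u)
    jac <- 1 / (1 - u)^2
    f <- (1 + n * g * r^2)^(-0.5) *
      (1 + t^2 / ((1 + n * g * r^2) * nu))^(-(nu + 1) / 2) *
      (2 * pi)^(-0.5) * g^(-1.5) * exp(-1 / (2 * g)) * jac
    alt <- sum(f) * (u[2] - u[1])
    alt / (1 + t^2 / nu)^(-(nu + 1) / 2)
  }
  expect_equal(bf10_jzs(0, 18), bf_oracle(0, 18), tolerance = 1e-3)
  expect_lt(bf10_jzs(0, 18), 1)
  expect_equal(bf10_jzs(3.2, 18), bf_oracle(3.2, 18), tolerance = 1e-3)
  # BF10 is monotone in |t| at fixed n
  bfs <- vapply(c(0, 1, 2, 3, 5), bf10_jzs, 0, n = 18)
  expect_true(all(diff(bfs) > 0))
})

test_that("one-sample tests apply the Bonferroni threshold", {
  set.seed(21)
  v <- rnorm(18, -0.2, 0.1)
  res <- one_sample_t_bonferroni(v)
  expect_equal(res$alpha_corrected, 0.0125)
  expect_equal(res$d, res$t / sqrt(18), tolerance = 1e-12)
  expect_identical(res$significant, res$p < 0.0125)
  expect_error(one_sample_t_bonferroni(rep(1, 5)), "zero variance")
  # the t CDF route: p for t = -1.075 on 126 df is 0.284
  z <- rnorm(127); z <- (z - mean(z)) / sd(z)
  vals <- z + -1.075 / sqrt(127)
  res2 <- one_sample_t_bonferroni(vals)
  expect_equal(res2$t, -1.075, tolerance = 1e-9)
  expect_equal(round(res2$p, 3), 0.284)
})

test_that("reported effect sizes satisfy d = t/sqrt(n) across the study's tests", {
  printed <- rbind(
    c(-5.366, -1.265), c(-1.286, -0.303),                    # RT contrasts
    c(-4.278, -1.008), c(-9.318, -2.196), c(-4.010, -0.945),
    c(-7.346, -1.731),                                       # beta power
    c(8.93, 2.104), c(6.84, 1.613), c(7.19, 1.695), c(6.95, 1.639),
    c(2.341, 0.552), c(0.272, 0.064),                        # theta
    c(32.23, 7.597), c(29.493, 6.951), c(60.06, 14.156),
    c(48.259, 11.375))                                       # coupling
  expect_true(all(abs(printed[, 1] / sqrt(18) - printed[, 2]) < 0.002))
})

test_that("trimming excludes only RTs beyond two SDs, single pass", {
  beh <- tibble::tibble(subject = "s1", task = "naming",
                        cognate = "cognate", trial = 1:20,
                        correct = TRUE,
                        rt_ms = c(rnorm(19, 700, 30), 1500))
  set.seed(22)
  agg <- trim_and_aggregate(beh)
  rt <- beh$rt_ms
  m <- mean(rt); s <- sd(rt)
  keep <- rt >= m - 2 * s & rt <= m + 2 * s
  expect_equal(agg$rt_mean, mean(rt[keep]))
  expect_equal(agg$n_rt_used, sum(keep))
  expect_false(keep[20])
  # all-equal RTs: everything retained
  beh2 <- beh; beh2$rt_ms <- 700
  expect_equal(trim_and_aggregate(beh2)$rt_mean, 700)
  # accuracy is a plain ratio
  beh3 <- beh; beh3$correct <- c(rep(TRUE, 17), rep(FALSE, 3))
  beh3 <- rbind(beh3, transform(beh3[1:12, ], trial = 21:32,
                                correct = rep(c(TRUE, FALSE), 6)))
  agg3 <- trim_and_aggregate(beh3)
  expect_equal(agg3$accuracy, (17 + 6) / 32)
  beh4 <- beh; beh4$correct <- c(TRUE, rep(FALSE, 19))
  expect_error(trim_and_aggregate(beh4), "fewer than 2 correct")
})

test_that("pearson_r matches the covariance formula", {
  x <- 1:10
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  expect_equal(pearson_r(x, -x)$r, -1, tolerance = 1e-12)
  set.seed(23)
  a <- rnorm(10); b <- rnorm(10)
  res <- pearson_r(a, b)
  manual <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(res$r, manual, tolerance = 1e-12)
  t_manual <- manual * sqrt(8 / (1 - manual^2))
  expect_equal(res$p, 2 * pt(-abs(t_manual), 8), tolerance = 1e-12)
  expect_error(pearson_r(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(pearson_r(c(a, NA), c(b, 1)), "finite")
})
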