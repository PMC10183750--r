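#' Aggregate behavior with +/-2 SD reaction-time trimming
#'
#' Per subject and task x cognate cell: accuracy is the proportion of
#' correct trials; mean RT is computed over correct trials whose RT lies
#' within the cell's correct-trial mean +/- 2 SD (single pass, no
#' re-iteration).
#'
#' @param behavior tibble with columns `subject`, `task`, `cognate`,
#'   `trial`, `correct`, `rt_ms`.
#' @return tibble with `subject`, `task`, `cognate`, `n_trials`,
#'   `accuracy`, `rt_mean`, `n_rt_used`.
#' @export
trim_and_aggregate <- function(behavior) {
  cells <- unique(behavior[, c("subject", "task", "cognate")])
  out <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- behavior$subject == cells$subject[i] &
      behavior$task == cells$task[i] & behavior$cognate == cells$cognate[i]
    b <- behavior[sel, ]
    rt <- b$rt_ms[b$correct]
    if (length(rt) < 2)
      stop("subject ", cells$subject[i], ", ", cells$task[i], "/",
           cells$cognate[i], ": fewer than 2 correct trials")
    m <- mean(rt); s <- sd(rt)
    keep <- rt >= m - 2 * s & rt <= m + 2 * s
    tibble::tibble(subject = cells$subject[i], task = cells$task[i],
                   cognate = cells$cognate[i], n_trials = nrow(b),
                   accuracy = mean(b$correct), rt_mean = mean(rt[keep]),
                   n_rt_used = sum(keep))
  })
  do.call(rbind, out)
}

#' 2 x 2 repeated-measures ANOVA
#'
#' Within-subject two-factor ANOVA fitted via `aov` with
#' `Error(subject/(A*B))` strata; reports F, degrees of freedom, p and
#' partial eta squared (`SS_effect / (SS_effect + SS_error)`) for the two
#' main effects and the interaction.
#'
#' @param data data frame with columns `subject`, the two factor columns
#'   and `value`.
#' @param factors length-2 character vector naming the factor columns
#'   (default `c("task", "cognate")`).
#' @return tibble with one row per effect: `effect`, `df1`, `df2`, `F`,
#'   `p`, `pes`.
#' @export
rm_anova_2x2 <- function(data, factors = c("task", "cognate")) {
  d <- data.frame(subject = factor(data$subject),
                  A = factor(data[[factors[1]]]),
                  B = factor(data[[factors[2]]]),
                  value = data$value)
  if (nlevels(d$A) != 2 || nlevels(d$B) != 2)
    stop("both factors must have exactly 2 levels")
  counts <- table(d$subject, d$A, d$B)
  if (any(counts != 1))
    stop("design must be complete: one value per subject x cell")
  fit <- aov(value ~ A * B + Error(subject / (A * B)), data = d)
  s <- summary(fit)
  tot <- sum((d$value - mean(d$value))^2)
  grab <- function(stratum, term) {
    tab <- s[[stratum]][[1]]
    rn <- trimws(rownames(tab))
    i <- match(term, rn); j <- match("Residuals", rn)
    ss <- tab[i, "Sum Sq"]; sse <- tab[j, "Sum Sq"]
    Fv <- tab[i, "F value"]; pv <- tab[i, "Pr(>F)"]
    # a stratum that carries no variance at all (an effect constant within
    # subject) is reported as a null effect, not as a 0/0 ratio
    if (ss + sse < 1e-10 * max(tot, 1e-300) || !is.finite(Fv)) {
      Fv <- 0; pv <- 1; ss <- 0
    }
    tibble::tibble(effect = term, df1 = tab[i, "Df"], df2 = tab[j, "Df"],
                   F = Fv, p = pv,
                   pes = if (ss + sse > 1e-300) ss / (ss + sse) else 0)
  }
  out <- rbind(grab("Error: subject:A", "A"),
               grab("Error: subject:B", "B"),
               grab("Error: subject:A:B", "A:B"))
  out$effect <- c(factors[1], factors[2],
                  paste(factors[1], factors[2], sep = ":"))
  out
}

#' JZS Bayes factor for a t statistic
#'
#' Default-prior (Jeffreys-Zellner-Siow) Bayes factor BF10 for a one- or
#' paired-sample t test, with a Cauchy prior of scale `r` on the
#' standardized effect, computed by numerical integration over the
#' g-prior mixture.
#'
#' @param t observed t statistic.
#' @param n number of (pairs of) observations.
#' @param r Cauchy prior scale (default 0.707).
#' @return BF10 (evidence for the alternative over the null).
#' @export
bf10_jzs <- function(t, n, r = sqrt(2) / 2) {
  nu <- n - 1
  null_dens <- (1 + t^2 / nu)^(-(nu + 1) / 2)
  integrand <- function(g) {
    (1 + n * g * r^2)^(-1 / 2) *
      (1 + t^2 / ((1 + n * g * r^2) * nu))^(-(nu + 1) / 2) *
      (2 * pi)^(-1 / 2) * g^(-3 / 2) * exp(-1 / (2 * g))
  }
  alt_dens <- integrate(integrand, 0, Inf, rel.tol = 1e-9,
                        stop.on.error = FALSE)$value
  alt_dens / null_dens
}

#' Paired t test with Cohen's d and JZS Bayes factor
#'
#' @param x,y per-subject paired values.
#' @param bf_scale Cauchy prior scale for BF10.
#' @return tibble with `t`, `df`, `p`, `d` (`mean(x - y) / sd(x - y)`,
#'   equal to `t / sqrt(n)`), `bf10`.
#' @export
paired_t_cohen_bf <- function(x, y, bf_scale = sqrt(2) / 2) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  diff <- x - y
  if (sd(diff) <= 1e-12 * max(abs(diff), 1))
    stop("zero variance of paired differences")
  n <- length(diff)
  tt <- stats::t.test(x, y, paired = TRUE)
  t <- unname(tt$statistic)
  tibble::tibble(t = t, df = n - 1, p = tt$p.value, d = t / sqrt(n),
                 bf10 = bf10_jzs(t, n, bf_scale))
}

#' One-sample t tests with Bonferroni control
#'
#' Two-tailed one-sample t test against `mu`, flagged significant at the
#' Bonferroni-corrected level `alpha / n_tests` (0.05 / 4 = 0.0125 for
#' the four condition tests).
#'
#' @param values per-subject values.
#' @param mu null value (default 0).
#' @param n_tests size of the test family (default 4).
#' @param alpha familywise level (default 0.05).
#' @return tibble with `t`, `df`, `p`, `d`, `alpha_corrected`,
#'   `significant`.
#' @export
one_sample_t_bonferroni <- function(values, mu = 0, n_tests = 4,
                                    alpha = 0.05) {
  stopifnot(length(values) >= 2)
  if (sd(values) <= 1e-12 * max(abs(values), 1)) stop("zero variance")
  n <- length(values)
  tt <- stats::t.test(values, mu = mu)
  thr <- alpha / n_tests
  tibble::tibble(t = unname(tt$statistic), df = n - 1, p = tt$p.value,
                 d = unname(tt$statistic) / sqrt(n), alpha_corrected = thr,
                 significant = tt$p.value < thr)
}

#' Pearson correlation with p-value
#'
#' Product-moment correlation; p from the t transform with n - 2 df.
#'
#' @param x,y numeric vectors (n >= 3, finite, nonzero variance).
#' @return tibble with `r`, `n`, `t`, `p`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("inputs must be finite")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance input")
  ct <- stats::cor.test(x, y)
  tibble::tibble(r = unname(ct$estimate), n = length(x),
                 t = unname(ct$statistic), p = ct$p.value)
}
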