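#' Size-matched mini-clusters tiling the scalp outside an ROI
#'
#' For every electrode outside the region of interest, forms the
#' mini-cluster consisting of that electrode plus its `k - 1` nearest
#' non-ROI channels in the planar (2-D projected) sensor space, ties
#' broken by channel-name order. ROI electrodes are excluded from
#' membership as well as from the centres, so the comparison is genuinely
#' against everywhere else on the scalp; the mini-cluster size is matched
#' to the ROI size. The output depends only on the montage, the ROI and
#' `k` — never on iteration order or data.
#'
#' @param montage an `eeg_montage`.
#' @param roi ROI channel names (excluded as centres).
#' @param k mini-cluster size (e.g. 11 for the naming ROI, 8 for the
#'   size-judgment ROI).
#' @return named list (by centre channel) of member-name vectors, each of
#'   length `k`.
#' @export
minicluster_sets <- function(montage, roi, k) {
  if (k > length(montage$names)) stop("k exceeds the number of channels")
  if (k < 1) stop("k must be >= 1")
  miss <- setdiff(roi, montage$names)
  if (length(miss)) stop("unknown channel: ", paste(miss, collapse = ", "))
  centers <- setdiff(montage$names, roi)
  if (k > length(centers))
    stop("k exceeds the number of channels outside the ROI")
  d <- as.matrix(stats::dist(montage$pos2d))
  dimnames(d) <- list(montage$names, montage$names)
  sets <- lapply(centers, function(ctr) {
    others <- setdiff(centers, ctr)
    # order by distance, ties by name
    ord <- others[order(d[ctr, others], others)]
    c(ctr, head(ord, k - 1))
  })
  names(sets) <- centers
  sets
}

#' Scalp distribution of a paired condition effect
#'
#' Computes, for each mini-cluster, the member-averaged band power per
#' subject and condition and the paired t statistic of the
#' noncognate-versus-cognate contrast; the identical statistic is
#' computed on the ROI members. The resulting collection of t values
#' describes the size of the effect across the scalp.
#'
#' @param bp_nc,bp_c subjects x channels matrices of band power
#'   (noncognate, cognate), with channel column names.
#' @param miniclusters from [minicluster_sets()].
#' @param roi ROI channel names.
#' @return object of class `searchlight_dist`: `t_mini` (named vector),
#'   `t_roi`, member sets, and the subject-level difference matrix used
#'   by the permutation test.
#' @export
scalp_effect_distribution <- function(bp_nc, bp_c, miniclusters, roi) {
  chans <- colnames(bp_nc)
  need <- unique(c(unlist(miniclusters), roi))
  miss <- setdiff(need, chans)
  if (length(miss)) stop("missing channels in band power: ",
                         paste(miss, collapse = ", "))
  pair_t <- function(members) {
    x <- rowMeans(bp_nc[, members, drop = FALSE])
    y <- rowMeans(bp_c[, members, drop = FALSE])
    d <- x - y
    mean(d) / (sd(d) / sqrt(length(d)))
  }
  t_mini <- vapply(miniclusters, pair_t, 0)
  t_roi <- pair_t(roi)
  structure(list(t_mini = t_mini, t_roi = t_roi,
                 miniclusters = miniclusters, roi = roi,
                 diff = bp_nc - bp_c), class = "searchlight_dist")
}

#' Permutation p-value of the ROI effect against the scalp distribution
#'
#' Tests whether the ROI's condition effect exceeds what the rest of the
#' scalp produces. The null retains the observed scalp effect
#' distribution: each subject's condition-difference vector is split into
#' the channel-wise group mean and a subject residual, the residuals are
#' sign-flipped within subject, and the maximum absolute mini-cluster t
#' across the scalp is recorded per permutation. The p-value is the
#' (add-one corrected) fraction of permutations whose scalp maximum
#' reaches the observed absolute ROI t; it is small only when the ROI
#' effect stands out from the scalp distribution, and stays large for a
#' spatially uniform effect. The descriptive percentile of the ROI t in
#' the observed mini-cluster distribution is reported alongside.
#'
#' @param dist a `searchlight_dist`.
#' @param n_perm number of permutations (default 2000).
#' @param seed RNG seed.
#' @return list with `p`, `percentile`, `t_roi`, `n_perm`.
#' @export
searchlight_pvalue <- function(dist, n_perm = 2000, seed = 1L) {
  d <- dist$diff
  n <- nrow(d)
  member_idx <- lapply(dist$miniclusters, function(m) match(m, colnames(d)))
  mu <- colMeans(d)
  resid <- sweep(d, 2, mu)
  t_of <- function(dd, idx) {
    v <- rowMeans(dd[, idx, drop = FALSE])
    mean(v) / (sd(v) / sqrt(n))
  }
  set.seed(seed)
  obs <- abs(dist$t_roi)
  cnt <- 0
  for (p in seq_len(n_perm)) {
    flips <- sample(c(-1, 1), n, replace = TRUE)
    dp <- sweep(resid * flips, 2, mu, `+`)
    mx <- max(abs(vapply(member_idx, function(idx) t_of(dp, idx), 0)))
    if (mx >= obs) cnt <- cnt + 1
  }
  list(p = (1 + cnt) / (1 + n_perm),
       percentile = mean(abs(dist$t_mini) <= obs),
       t_roi = dist$t_roi, n_perm = n_perm)
}

#' Serialize a searchlight result to JSON
#' @param dist a `searchlight_dist`.
#' @param pval result of [searchlight_pvalue()].
#' @param path output path.
#' @export
write_searchlight <- function(dist, pval, path) {
  jsonlite::write_json(list(
    roi = dist$roi, t_roi = dist$t_roi,
    miniclusters = dist$miniclusters, t_mini = as.list(dist$t_mini),
    p = pval$p, percentile = pval$percentile, n_perm = pval$n_perm),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
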