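#' Paired t-statistic map
#'
#' Dependent-samples t statistic per element (channel or time point) for
#' a within-subject two-condition contrast.
#'
#' @param a,b subjects x elements matrices of condition values.
#' @return numeric vector of t statistics (one per element). Elements
#'   with zero difference variance but nonzero mean give +/-Inf (treated
#'   as supra-threshold downstream) with a message.
#' @export
paired_tmap <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)), nrow(a) >= 2)
  d <- a - b
  n <- nrow(d)
  m <- colMeans(d)
  s <- apply(d, 2, sd)
  t <- m / (s / sqrt(n))
  zero <- s == 0
  if (any(zero & m != 0)) {
    message(sum(zero & m != 0), " element(s) with zero difference variance; ",
            "t set to +/-Inf")
    t[zero] <- sign(m[zero]) * Inf
  }
  t[zero & m == 0] <- 0
  t
}

#' Threshold a t-map and form clusters
#'
#' Elements with |t| above the two-sided `alpha` quantile of t(df) are
#' supra-threshold. In channel space a supra-threshold channel is kept
#' only if at least `min_nbchan` of its neighbours are supra-threshold
#' with the same sign; retained same-sign connected components (under the
#' adjacency) are the clusters. For temporal clustering pass the
#' chain adjacency and `min_nbchan = 0`.
#'
#' @param t_map numeric vector of element statistics.
#' @param adjacency symmetric logical adjacency matrix.
#' @param df degrees of freedom of the element tests.
#' @param alpha cluster-forming threshold (two-sided).
#' @param min_nbchan minimum same-sign supra-threshold neighbours.
#' @return list of clusters, each with `members` (indices), `size`,
#'   `tsum` and `sign`.
#' @export
find_clusters <- function(t_map, adjacency, df, alpha = 0.05,
                          min_nbchan = 3) {
  crit <- qt(1 - alpha / 2, df)
  out <- list()
  for (sgn in c(1, -1)) {
    supra <- if (sgn > 0) t_map > crit else t_map < -crit
    supra[is.na(supra)] <- FALSE
    if (min_nbchan > 0) {
      nb_count <- as.integer(adjacency %*% supra)
      supra <- supra & nb_count >= min_nbchan
    }
    idx <- which(supra)
    if (!length(idx)) next
    # connected components among retained elements
    comp <- rep(NA_integer_, length(t_map))
    cid <- 0
    for (i in idx) {
      if (!is.na(comp[i])) next
      cid <- cid + 1
      queue <- i
      comp[i] <- cid
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        nb <- idx[adjacency[v, idx] & is.na(comp[idx])]
        comp[nb] <- cid
        queue <- c(queue, nb)
      }
    }
    for (k in seq_len(cid)) {
      members <- which(comp == k)
      out[[length(out) + 1]] <- list(members = members,
                                     size = length(members),
                                     tsum = sum(t_map[members]),
                                     sign = sgn)
    }
  }
  out
}

#' Monte-Carlo cluster-based permutation test
#'
#' Dependent-samples cluster permutation test for a two-condition
#' within-subject design: the element-wise paired t-map is thresholded at
#' `alpha` and clustered under the channel adjacency (minimum
#' same-sign neighbour rule), and cluster significance is assessed
#' against the permutation distribution of the maximum cluster statistic
#' obtained by randomly sign-flipping each subject's condition difference
#' (`n_perm` iterations). The default cluster statistic is cluster size
#' (element count); the summed t is recorded per cluster as well and can
#' be made inferential with `stat = "mass"`. Positive and negative
#' clusters are formed separately.
#'
#' @param a,b subjects x elements matrices (condition A, condition B).
#' @param adjacency symmetric logical adjacency over elements.
#' @param n_perm number of permutations (default 2000).
#' @param alpha cluster-forming threshold.
#' @param min_nbchan minimum neighbour count (0 for temporal clustering).
#' @param stat `"size"` or `"mass"` (absolute summed t).
#' @param seed RNG seed.
#' @return object of class `cluster_result`: `clusters` (members, size,
#'   tsum, sign, p), `max_stat_distribution`, `t_map`, parameters.
#' @export
cluster_permutation_test <- function(a, b, adjacency, n_perm = 2000,
                                     alpha = 0.05, min_nbchan = 3,
                                     stat = c("size", "mass"), seed = 1L) {
  stat <- match.arg(stat)
  n <- nrow(a)
  if (n < 5) warning("fewer than 5 subjects: permutation resolution is poor")
  df <- n - 1
  t_obs <- paired_tmap(a, b)
  clusters <- find_clusters(t_obs, adjacency, df, alpha, min_nbchan)
  cstat <- function(cl) if (stat == "size") cl$size else abs(cl$tsum)
  d <- a - b
  set.seed(seed)
  max_null <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    flips <- sample(c(-1, 1), n, replace = TRUE)
    dp <- d * flips
    tp <- colMeans(dp) / (apply(dp, 2, sd) / sqrt(n))
    tp[is.na(tp)] <- 0
    cl <- find_clusters(tp, adjacency, df, alpha, min_nbchan)
    max_null[p] <- if (length(cl)) max(vapply(cl, cstat, 0)) else 0
  }
  for (k in seq_along(clusters)) {
    obs <- cstat(clusters[[k]])
    clusters[[k]]$p <- (1 + sum(max_null >= obs)) / (1 + n_perm)
  }
  structure(list(clusters = clusters, max_stat_distribution = max_null,
                 t_map = t_obs, stat = stat, alpha = alpha,
                 min_nbchan = min_nbchan, n_perm = n_perm, df = df,
                 element_names = colnames(a)),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result> ", length(x$clusters), " cluster(s), ",
      x$n_perm, " permutations, stat = ", x$stat, "\n", sep = "")
  for (cl in x$clusters)
    cat(sprintf("  %s cluster: size %d, t-sum %.2f, p = %.4f\n",
                if (cl$sign > 0) "positive" else "negative",
                cl$size, cl$tsum, cl$p))
  invisible(x)
}

#' Tidy a cluster result into a one-row-per-cluster tibble
#' @param x a `cluster_result`.
#' @param ... unused.
#' @return tibble with one row per cluster.
#' @export
tidy_clusters <- function(x, ...) {
  if (!length(x$clusters))
    return(tibble::tibble(sign = character(), size = integer(),
                          tsum = numeric(), p = numeric(),
                          members = list()))
  tibble::tibble(
    sign = vapply(x$clusters, function(c) if (c$sign > 0) "positive"
                  else "negative", ""),
    size = vapply(x$clusters, `[[`, 1L, "size"),
    tsum = vapply(x$clusters, `[[`, 0, "tsum"),
    p = vapply(x$clusters, `[[`, 0, "p"),
    members = lapply(x$clusters, function(c)
      if (!is.null(x$element_names)) x$element_names[c$members]
      else c$members))
}

#' Cluster-based permutation test over a time course
#'
#' Same machinery as [cluster_permutation_test()] with
#' temporal-contiguity adjacency (and no minimum-neighbour rule).
#'
#' @param a,b subjects x timepoints matrices.
#' @param times time axis (s), used to report intervals.
#' @param ... passed to [cluster_permutation_test()].
#' @return a `cluster_result` with an extra `intervals` tibble of
#'   significant (p < 0.05) time ranges.
#' @export
timecourse_cluster_test <- function(a, b, times, ...) {
  nt <- ncol(a)
  adj <- matrix(FALSE, nt, nt)
  if (nt > 1) {
    adj[cbind(seq_len(nt - 1), seq_len(nt - 1) + 1)] <- TRUE
    adj <- adj | t(adj)
  }
  res <- cluster_permutation_test(a, b, adj, min_nbchan = 0, ...)
  sig <- Filter(function(cl) cl$p < 0.05, res$clusters)
  res$intervals <- tibble::tibble(
    from = vapply(sig, function(cl) times[min(cl$members)], 0),
    to = vapply(sig, function(cl) times[max(cl$members)], 0),
    sign = vapply(sig, function(cl) cl$sign, 0),
    p = vapply(sig, function(cl) cl$p, 0))
  res$times <- times
  res
}
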