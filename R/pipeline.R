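#' Full spectral chain for one subject
#'
#' Preprocessed epochs -> zero-padding -> Morlet TFR (per trial) ->
#' correct-trial condition averaging -> iterative 1/f fit (one line per
#' channel-time pair) and subtraction -> baseline normalization. Returns
#' the baseline-normalized, condition-averaged TFR.
#'
#' @param epochs the subject's (already preprocessed) `eeg_epochs`.
#' @param cfg an `analysis_config`.
#' @param channels channel subset to decompose (default all).
#' @param freqs wavelet frequencies (default `cfg$freqs`, 1-40 Hz).
#' @param pad zero-padding extent in seconds (default -5..5; must
#'   accommodate `cfg$n_cycles` at `min(freqs)`).
#' @param tmin,tmax output time crop (defaults cover the baseline and the
#'   analysis windows).
#' @return an `eeg_tfr`, stage `baseline_normalized`, one row per
#'   task x cognate cell.
#' @export
spectral_chain <- function(epochs, cfg = analysis_config(), channels = NULL,
                           freqs = cfg$freqs, pad = c(-5, 5),
                           tmin = -0.75, tmax = 0.45) {
  if (!is.null(channels)) {
    ch_idx <- match(channels, epochs$channels)
    if (anyNA(ch_idx))
      stop("unknown channel: ",
           paste(channels[is.na(ch_idx)], collapse = ", "))
    epochs$data <- epochs$data[, ch_idx, , drop = FALSE]
    epochs$channels <- channels
  }
  padded <- pad_epochs(epochs, pad = pad)
  tfr <- morlet_tfr(padded, freqs = freqs, n_cycles = cfg$n_cycles,
                    t_step = cfg$t_step, tmin = tmin, tmax = tmax)
  # one aperiodic fit per channel-time pair on the condition-averaged raw
  # power; correcting the average equals averaging the corrected trials
  avg <- average_tfr(tfr, correct_only = TRUE)
  fit <- fit_fractal(avg, k = cfg$fractal_k, max_iter = cfg$fractal_max_iter)
  corr <- subtract_fractal(avg, fit)
  baseline_normalize(corr, baseline = cfg$windows$baseline)
}

#' Condition-level band power for a whole cohort
#'
#' Runs preprocessing and the spectral chain per subject and extracts the
#' task-specific ROI band power (and, optionally, per-channel power and
#' ROI time courses) for the requested bands.
#'
#' @param cohort result of [generate_cohort()] (or a compatible list with
#'   `epochs` and `montage`).
#' @param cfg an `analysis_config`.
#' @param bands named list of band limits to extract (defaults: beta
#'   25-35, theta 3-7).
#' @param channels channels to decompose (default: union of the two task
#'   ROIs; use `cohort$montage$names` for all).
#' @param freqs,pad passed to [spectral_chain()].
#' @param per_channel also return per-channel band power in the task
#'   windows (needed by cluster and searchlight tests).
#' @param timecourse also return ROI-mean band-power time courses.
#' @param preprocess run [preprocess_epochs()] first (default TRUE).
#' @param verbose print progress.
#' @return list with `roi` (tibble: subject, task, cognate, band, power),
#'   optionally `channel` (tibble incl. channel) and `timecourse`
#'   (tibble incl. time).
#' @export
cohort_condition_power <- function(cohort, cfg = analysis_config(),
                                   bands = list(beta = c(25, 35),
                                                theta = c(3, 7)),
                                   channels = NULL, freqs = cfg$freqs,
                                   pad = c(-5, 5), per_channel = FALSE,
                                   timecourse = FALSE, preprocess = TRUE,
                                   verbose = FALSE) {
  rois <- list(naming = cfg$rois$naming, size = cfg$rois$size)
  windows <- list(naming = cfg$windows$naming_roi,
                  size = cfg$windows$size_roi)
  if (is.null(channels))
    channels <- intersect(cohort$epochs[[1]]$channels,
                          unique(unlist(rois)))
  roi_rows <- list(); ch_rows <- list(); tc_rows <- list()
  for (ep in cohort$epochs) {
    if (preprocess)
      ep <- preprocess_epochs(ep, montage = cohort$montage,
                              reject_threshold = cfg$reject_threshold)$epochs
    tfr <- spectral_chain(ep, cfg, channels = channels, freqs = freqs,
                          pad = pad)
    for (task in c("naming", "size")) {
      roi <- intersect(rois[[task]], channels)
      win <- windows[[task]]
      for (bn in names(bands)) {
        bp <- band_power(tfr, bands[[bn]], win, roi)
        bp <- bp[bp$task == task, ]
        roi_rows[[length(roi_rows) + 1]] <- tibble::tibble(
          subject = ep$subject_id, task = task, cognate = bp$cognate,
          band = bn, power = bp$power)
        if (per_channel) {
          for (ch in channels) {
            bpc <- band_power(tfr, bands[[bn]], win, ch)
            bpc <- bpc[bpc$task == task, ]
            ch_rows[[length(ch_rows) + 1]] <- tibble::tibble(
              subject = ep$subject_id, task = task, cognate = bpc$cognate,
              band = bn, channel = ch, power = bpc$power)
          }
        }
        if (timecourse) {
          for (tp in tfr$times[tfr$times >= -0.1]) {
            bpt <- band_power(tfr, bands[[bn]], c(tp, tp), roi)
            bpt <- bpt[bpt$task == task, ]
            tc_rows[[length(tc_rows) + 1]] <- tibble::tibble(
              subject = ep$subject_id, task = task, cognate = bpt$cognate,
              band = bn, time = tp, power = bpt$power)
          }
        }
      }
    }
    if (verbose) message("spectral chain done: ", ep$subject_id)
  }
  out <- list(roi = do.call(rbind, roi_rows))
  if (per_channel) out$channel <- do.call(rbind, ch_rows)
  if (timecourse) out$timecourse <- do.call(rbind, tc_rows)
  out
}

#' Subjects-by-channels band-power matrices for a paired contrast
#'
#' Reshapes the per-channel output of [cohort_condition_power()] into the
#' two subjects x channels matrices the cluster and searchlight tests
#' consume.
#'
#' @param channel_tbl the `channel` tibble from
#'   [cohort_condition_power()].
#' @param task,band selection.
#' @return list with matrices `nc` and `c` (subjects x channels).
#' @export
contrast_matrices <- function(channel_tbl, task, band) {
  sel <- channel_tbl[channel_tbl$task == task & channel_tbl$band == band, ]
  subjects <- sort(unique(sel$subject))
  chans <- unique(sel$channel)
  shape <- function(cog) {
    s <- sel[sel$cognate == cog, ]
    m <- matrix(NA_real_, length(subjects), length(chans),
                dimnames = list(subjects, chans))
    m[cbind(match(s$subject, subjects), match(s$channel, chans))] <- s$power
    m
  }
  list(nc = shape("noncognate"), c = shape("cognate"))
}

hash_object <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(x, tf)
  unname(tools::md5sum(tf))
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> preprocess -> spectral -> cluster/searchlight
#' -> PAC -> behavioral statistics on a synthetic cohort, writing every
#' result table under `out_dir` and returning a run manifest. A single
#' seed drives all stages through fixed per-stage offsets.
#'
#' @param syn_cfg a `synthetic_config`.
#' @param cfg an `analysis_config`.
#' @param out_dir output directory (created if missing).
#' @param stages character subset of
#'   `c("simulate", "spectral", "cluster", "searchlight", "pac", "stats")`.
#' @param seed integer seed overriding both configs' `rng_seed`.
#' @param channels channels to decompose (default all montage channels).
#' @param freqs,pad spectral grid (defaults: 1-40 Hz, -5..5 s padding).
#' @param verbose progress messages.
#' @return the run manifest (list), invisibly; results are in `out_dir`.
#' @export
run_pipeline <- function(syn_cfg = synthetic_config(),
                         cfg = analysis_config(), out_dir = "oscillatr_out",
                         stages = c("simulate", "spectral", "cluster",
                                    "searchlight", "pac", "stats"),
                         seed = NULL, channels = NULL, freqs = cfg$freqs,
                         pad = c(-5, 5), verbose = TRUE) {
  t0 <- Sys.time()
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (!is.null(seed)) {
    syn_cfg$rng_seed <- as.integer(seed)
    cfg$rng_seed <- as.integer(seed)
  }
  say <- function(...) if (verbose) message(...)
  timings <- list(); outputs <- character()
  emit <- function(obj, name) {
    path <- file.path(out_dir, name)
    if (grepl("\\.tsv$", name))
      utils::write.table(obj, path, sep = "\t", row.names = FALSE,
                         quote = FALSE)
    else jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                              force = TRUE)
    outputs <<- c(outputs, path)
  }

  if (!"simulate" %in% stages)
    stop("stage 'simulate' is required: downstream stages need its epochs")
  say("simulating cohort (seed ", syn_cfg$rng_seed, ")")
  cohort <- generate_cohort(syn_cfg)
  emit(cohort$behavior, "behavior.tsv")
  timings$simulate <- as.numeric(Sys.time() - t0, units = "secs")

  results <- list()
  if (any(c("spectral", "cluster", "searchlight") %in% stages)) {
    say("spectral chain")
    need_channels <- "cluster" %in% stages || "searchlight" %in% stages
    pw <- cohort_condition_power(
      cohort, cfg, channels = channels, freqs = freqs, pad = pad,
      per_channel = need_channels, verbose = verbose)
    emit(pw$roi, "band_power.tsv")
    if (need_channels) emit(pw$channel, "band_power_channels.tsv")
    results$power <- pw

    if ("spectral" %in% stages) {
      stat_rows <- list()
      for (task in c("naming", "size")) for (bn in unique(pw$roi$band)) {
        for (cog in c("noncognate", "cognate")) {
          v <- pw$roi$power[pw$roi$task == task & pw$roi$band == bn &
                              pw$roi$cognate == cog]
          st <- one_sample_t_bonferroni(v, alpha = 4 * cfg$bonferroni_alpha)
          stat_rows[[length(stat_rows) + 1]] <- tibble::tibble(
            task = task, band = bn, cognate = cog, mean_power = mean(v),
            t = st$t, df = st$df, p = st$p, d = st$d,
            significant = st$significant)
        }
      }
      results$power_tests <- do.call(rbind, stat_rows)
      emit(results$power_tests, "power_one_sample_tests.tsv")
      for (bn in unique(pw$roi$band)) {
        dat <- pw$roi[pw$roi$band == bn, ]
        dat$value <- dat$power
        an <- rm_anova_2x2(dat)
        an$band <- bn
        results$power_anova <- rbind(results$power_anova, an)
      }
      emit(results$power_anova, "power_anova.tsv")
    }

    if ("cluster" %in% stages) {
      say("cluster permutation tests")
      cl_rows <- list()
      for (task in c("naming", "size")) {
        mm <- contrast_matrices(pw$channel, task, "beta")
        adj <- cohort$montage$neighbors[colnames(mm$nc), colnames(mm$nc)]
        res <- cluster_permutation_test(
          mm$nc, mm$c, adj, n_perm = cfg$n_permutations,
          alpha = cfg$cluster_alpha, min_nbchan = cfg$min_neighbor_channels,
          seed = cfg$rng_seed + 11L)
        cl <- tidy_clusters(res)
        if (nrow(cl)) cl$task <- task
        cl_rows[[task]] <- cl
        emit(list(task = task, clusters = cl,
                  max_stat = res$max_stat_distribution),
             paste0("cluster_", task, ".json"))
      }
      results$clusters <- cl_rows
    }

    if ("searchlight" %in% stages) {
      say("searchlight")
      sl <- list()
      for (task in c("naming", "size")) {
        roi <- intersect(cfg$rois[[task]], unique(pw$channel$channel))
        mm <- contrast_matrices(pw$channel, task, "beta")
        mc <- minicluster_sets(cohort$montage, cfg$rois[[task]],
                               k = length(cfg$rois[[task]]))
        mc <- Filter(length, lapply(mc, intersect, colnames(mm$nc)))
        dist <- scalp_effect_distribution(mm$nc, mm$c, mc, roi)
        pv <- searchlight_pvalue(dist, n_perm = cfg$n_permutations,
                                 seed = cfg$rng_seed + 13L)
        sl[[task]] <- list(dist = dist, p = pv)
        write_searchlight(dist, pv,
                          file.path(out_dir,
                                    paste0("searchlight_", task, ".json")))
      }
      results$searchlight <- sl
    }
  }

  if ("pac" %in% stages) {
    say("phase-amplitude coupling")
    pac_rows <- lapply(seq_along(cohort$epochs), function(i)
      pac_condition_mean(cohort$epochs[[i]], cfg,
                         seed = cfg$rng_seed + 17L + i)$mi)
    results$pac <- do.call(rbind, pac_rows)
    emit(results$pac, "pac_mi.tsv")
    dat <- results$pac; dat$value <- dat$mi
    results$pac_anova <- rm_anova_2x2(dat)
    emit(results$pac_anova, "pac_anova.tsv")
  }

  if ("stats" %in% stages) {
    say("behavioral statistics")
    agg <- trim_and_aggregate(cohort$behavior)
    emit(agg, "behavior_aggregated.tsv")
    rt <- agg; rt$value <- rt$rt_mean
    acc <- agg; acc$value <- acc$accuracy
    results$rt_anova <- rm_anova_2x2(rt)
    results$acc_anova <- rm_anova_2x2(acc)
    emit(results$rt_anova, "rt_anova.tsv")
    emit(results$acc_anova, "accuracy_anova.tsv")
    planned <- list()
    for (task in c("naming", "size")) {
      w <- function(cog) {
        s <- rt[rt$task == task & rt$cognate == cog, ]
        s$rt_mean[order(s$subject)]
      }
      pt <- paired_t_cohen_bf(w("cognate"), w("noncognate"))
      pt$task <- task
      planned[[task]] <- pt
    }
    results$planned_rt <- do.call(rbind, planned)
    emit(results$planned_rt, "rt_planned_tests.tsv")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("oscillatr")),
    seed = syn_cfg$rng_seed,
    config_hash = hash_object(list(syn = unclass(syn_cfg),
                                   ana = unclass(cfg))),
    stages = stages,
    outputs = outputs,
    elapsed_s = as.numeric(Sys.time() - t0, units = "secs"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(results, list(manifest = manifest, cohort = cohort)))
}
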