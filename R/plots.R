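#' Plot a scalp topography of per-channel values
#'
#' Simple sensor-space topography on the planar projection (points
#' coloured by value, labelled by channel). Requires ggplot2.
#'
#' @param montage an `eeg_montage`.
#' @param values named numeric vector (names = channels).
#' @param title plot title.
#' @return a ggplot object.
#' @export
plot_topography <- function(montage, values, title = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_topography needs the ggplot2 package")
  idx <- match(names(values), montage$names)
  if (anyNA(idx)) stop("unknown channel: ",
                       paste(names(values)[is.na(idx)], collapse = ", "))
  df <- data.frame(x = montage$pos2d[idx, 1], y = montage$pos2d[idx, 2],
                   channel = names(values), value = as.numeric(values))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$value)) +
    ggplot2::geom_point(size = 6) +
    ggplot2::geom_text(ggplot2::aes(label = .data$channel), vjust = -1.2,
                       size = 2.5, colour = "black") +
    ggplot2::scale_colour_gradient2(low = "blue", mid = "white",
                                    high = "red") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = title, x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a time-frequency representation for one channel
#'
#' @param tfr an `eeg_tfr`.
#' @param channel channel name.
#' @param index first-dimension index (trial or condition cell).
#' @return a ggplot object.
#' @export
plot_tfr <- function(tfr, channel, index = 1) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_tfr needs the ggplot2 package")
  ch <- match(channel, tfr$channels)
  if (is.na(ch)) stop("unknown channel: ", channel)
  m <- tfr$power[index, ch, , ]
  df <- expand.grid(freq = tfr$freqs, time = tfr$times)
  df$power <- as.vector(m)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$freq,
                                   fill = .data$power)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red") +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)",
                  fill = tfr$stage) +
    ggplot2::theme_minimal()
}

#' Plot phase-bin amplitude profiles from a PAC result
#'
#' @param pac a `pac_result`.
#' @return a ggplot object.
#' @export
plot_pac_profile <- function(pac) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_pac_profile needs the ggplot2 package")
  keys <- names(pac$bin_profiles)
  df <- do.call(rbind, lapply(keys, function(k) {
    prof <- pac$bin_profiles[[k]]
    data.frame(condition = k,
               phase_deg = seq(-165, 165, by = 30)[seq_along(prof)],
               amplitude = prof)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phase_deg, y = .data$amplitude)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(x = "theta phase (degrees)",
                  y = "normalized beta amplitude") +
    ggplot2::theme_minimal()
}
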