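#' Read a BrainVision recording
#'
#' Parses the `.vhdr` INI header, the `.vmrk` marker file and the binary
#' `.eeg` payload of a BrainVision triplet. Supported dialects are
#' multiplexed binary IEEE float32 or int16 (with per-channel resolution);
#' signal values are returned in microvolts.
#'
#' @param header_path path to the `.vhdr` file.
#' @return list with `data` (channels x samples matrix, microvolts),
#'   `sfreq`, `channels`, and `events` (tibble with `sample`, `type`,
#'   `description`).
#' @export
read_brainvision <- function(header_path) {
  if (!file.exists(header_path)) stop("header file not found: ", header_path)
  hdr <- parse_ini(readLines(header_path, warn = FALSE))
  ci <- hdr[["Common Infos"]]
  if (is.null(ci)) stop("malformed header: no [Common Infos] section")
  if (!identical(toupper(ci[["DataFormat"]]), "BINARY"))
    stop("unsupported data format: ", ci[["DataFormat"]])
  if (!identical(toupper(ci[["DataOrientation"]]), "MULTIPLEXED"))
    stop("unsupported binary layout: orientation ", ci[["DataOrientation"]])
  n_chan <- as.integer(ci[["NumberOfChannels"]])
  sfreq <- 1e6 / as.numeric(ci[["SamplingInterval"]])
  dir <- dirname(header_path)
  data_path <- file.path(dir, ci[["DataFile"]])
  marker_path <- file.path(dir, ci[["MarkerFile"]])
  if (!file.exists(data_path)) stop("missing sidecar file: ", data_path)
  if (!file.exists(marker_path)) stop("missing sidecar file: ", marker_path)

  fmt <- toupper(hdr[["Binary Infos"]][["BinaryFormat"]])
  ch <- hdr[["Channel Infos"]]
  if (length(ch) != n_chan)
    stop("channel-count mismatch: header declares ", n_chan,
         " channels but lists ", length(ch))
  ch <- ch[order(as.integer(sub("^Ch", "", names(ch))))]
  parts <- lapply(ch, function(v) strsplit(v, ",", fixed = TRUE)[[1]])
  ch_names <- unname(vapply(parts, `[`, "", 1))
  resolution <- unname(vapply(parts, function(p)
    if (length(p) >= 3 && nzchar(p[3])) as.numeric(p[3]) else 1, 0))

  bytes <- file.info(data_path)$size
  unit <- switch(fmt,
    "IEEE_FLOAT_32" = 4L,
    "INT_16" = 2L,
    stop("unsupported binary layout: BinaryFormat ", fmt))
  if (bytes %% (unit * n_chan) != 0)
    stop("truncated data file: ", bytes, " bytes is not a whole number of ",
         n_chan, "-channel frames")
  n_samp <- bytes / (unit * n_chan)
  con <- file(data_path, "rb")
  on.exit(close(con))
  if (fmt == "IEEE_FLOAT_32") {
    raw <- readBin(con, "double", n = n_chan * n_samp, size = 4,
                   endian = "little")
  } else {
    raw <- readBin(con, "integer", n = n_chan * n_samp, size = 2,
                   signed = TRUE, endian = "little")
  }
  data <- matrix(raw, nrow = n_chan) * resolution

  events <- parse_vmrk(readLines(marker_path, warn = FALSE))
  list(data = data, sfreq = sfreq, channels = ch_names, events = events)
}

parse_ini <- function(lines) {
  lines <- sub(";.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list(); sect <- NULL
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      sect <- sub("^\\[(.*)\\]$", "\\1", ln)
      out[[sect]] <- list()
    } else if (grepl("=", ln, fixed = TRUE) && !is.null(sect)) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      out[[sect]][[trimws(kv[1])]] <- trimws(paste(kv[-1], collapse = "="))
    }
  }
  out
}

parse_vmrk <- function(lines) {
  mk <- grep("^Mk[0-9]+=", trimws(lines), value = TRUE)
  if (!length(mk))
    return(tibble::tibble(sample = integer(), type = character(),
                          description = character()))
  parts <- lapply(mk, function(ln) {
    strsplit(sub("^Mk[0-9]+=", "", ln), ",", fixed = TRUE)[[1]]
  })
  tibble::tibble(
    sample = vapply(parts, function(p) as.integer(p[3]), 1L),
    type = vapply(parts, `[`, "", 1),
    description = vapply(parts, `[`, "", 2))
}

#' Write a BrainVision fixture triplet
#'
#' Minimal writer used to build test fixtures and round-trip checks for
#' [read_brainvision()].
#'
#' @param data channels x samples matrix (microvolts).
#' @param sfreq sampling rate.
#' @param channels channel names.
#' @param events data frame with `sample`, `type`, `description`.
#' @param path base path without extension.
#' @param format `"IEEE_FLOAT_32"` or `"INT_16"`.
#' @param resolution microvolts per unit for the int16 dialect.
#' @return the `.vhdr` path, invisibly.
#' @export
write_brainvision <- function(data, sfreq, channels, events, path,
                              format = c("IEEE_FLOAT_32", "INT_16"),
                              resolution = 0.1) {
  format <- match.arg(format)
  base <- basename(path)
  hdr <- c("Brain Vision Data Exchange Header File Version 1.0",
           "[Common Infos]",
           paste0("DataFile=", base, ".eeg"),
           paste0("MarkerFile=", base, ".vmrk"),
           "DataFormat=BINARY",
           "DataOrientation=MULTIPLEXED",
           paste0("NumberOfChannels=", nrow(data)),
           paste0("SamplingInterval=", format(1e6 / sfreq, scientific = FALSE)),
           "[Binary Infos]",
           paste0("BinaryFormat=", format),
           "[Channel Infos]",
           vapply(seq_len(nrow(data)), function(i)
             paste0("Ch", i, "=", channels[i], ",,",
                    if (format == "INT_16") resolution else 1, ",uV"),
             ""))
  writeLines(hdr, paste0(path, ".vhdr"))
  mrk <- c("Brain Vision Data Exchange Marker File, Version 1.0",
           "[Marker Infos]",
           if (nrow(events))
             vapply(seq_len(nrow(events)), function(i)
               paste0("Mk", i, "=", events$type[i], ",", events$description[i],
                      ",", events$sample[i], ",1,0"), ""))
  writeLines(mrk, paste0(path, ".vmrk"))
  con <- file(paste0(path, ".eeg"), "wb")
  on.exit(close(con))
  if (format == "IEEE_FLOAT_32") {
    writeBin(as.numeric(data), con, size = 4, endian = "little")
  } else {
    writeBin(as.integer(round(data / resolution)), con, size = 2,
             endian = "little")
  }
  invisible(paste0(path, ".vhdr"))
}
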