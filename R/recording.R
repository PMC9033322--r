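#' Multichannel recording container
#'
#' A `recording` bundles a channels-by-samples amplitude matrix (microvolts)
#' with its sampling rate, channel names and epoch start time. It is the
#' carrier passed between every stage of the pipeline: epoching, ICA,
#' feature extraction.
#'
#' Sample indexing is 0-based: sample `i` of a recording with start time
#' `t0` occurs at time `t0 + i / fs` seconds. Time windows are half-open
#' `[start, end)`.
#'
#' @param data numeric matrix, channels x samples.
#' @param fs sampling rate in Hz (positive scalar).
#' @param channel_names character vector, one name per row of `data`.
#'   Defaults to `ch1, ch2, ...`.
#' @param t0 epoch start time in seconds (default 0).
#'
#' @return An object of class `recording`.
#' @examples
#' rec <- recording(matrix(rnorm(256), nrow = 2), fs = 128)
#' n_samples(rec)
#' duration(rec)
#' @export
recording <- function(data, fs, channel_names = NULL, t0 = 0) {
  if (is.vector(data)) data <- matrix(data, nrow = 1)
  stopifnot(is.matrix(data), is.numeric(data))
  if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a single positive number (Hz)")
  }
  if (is.null(channel_names)) {
    channel_names <- paste0("ch", seq_len(nrow(data)))
  }
  if (length(channel_names) != nrow(data)) {
    stop(sprintf(
      "channel_names has length %d but data has %d rows",
      length(channel_names), nrow(data)
    ))
  }
  structure(
    list(
      data = data, fs = as.numeric(fs),
      channel_names = as.character(channel_names), t0 = as.numeric(t0)
    ),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf(
    "<recording> %d channel(s) x %d samples @ %g Hz (%.3f s, t0 = %g s)\n",
    n_channels(x), n_samples(x), x$fs, duration(x), x$t0
  ))
  cat("channels:", paste(utils::head(x$channel_names, 8), collapse = ", "),
      if (n_channels(x) > 8) "..." else "", "\n")
  invisible(x)
}

#' @rdname recording
#' @param rec a `recording`.
#' @export
n_channels <- function(rec) nrow(rec$data)

#' @rdname recording
#' @export
n_samples <- function(rec) ncol(rec$data)

#' @rdname recording
#' @export
duration <- function(rec) n_samples(rec) / rec$fs

#' Convert a recording to a long tibble
#'
#' One row per (channel, sample) with the absolute time of each sample,
#' convenient for ggplot2 and dplyr work.
#'
#' @param x a `recording`.
#' @param ... unused.
#' @return A tibble with columns `channel`, `time`, `amplitude`.
#' @method as_tibble recording
#' @export
as_tibble.recording <- function(x, ...) {
  idx <- seq_len(n_samples(x)) - 1L
  tibble::tibble(
    channel = rep(x$channel_names, each = n_samples(x)),
    time = rep(x$t0 + idx / x$fs, times = n_channels(x)),
    amplitude = as.vector(t(x$data))
  )
}

#' Plot a recording as stacked channel traces
#'
#' @param object a `recording`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot recording
#' @export
autoplot.recording <- function(object, ...) {
  df <- as_tibble.recording(object)
  df$channel <- factor(df$channel, levels = object$channel_names)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$amplitude)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel), scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = expression(paste("amplitude (", mu, "V)")))
}

#' Read and write recordings in the channel-matrix text format
#'
#' The channel-matrix format stores one channel per row, values separated by
#' tabs (or commas), with a JSON sidecar `<path>.json` carrying
#' `{"fs": <Hz>, "channels": [...], "t0": <s>}`. [read_recording()] also
#' accepts EDF files (extension `.edf`), dispatching to [read_edf()].
#'
#' @param path file to read or write. The sidecar is `<path>.json`.
#' @return [read_recording()] returns a `recording`;
#'   [write_recording()] returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' write_recording(recording(matrix(1:10 / 7, nrow = 2), fs = 5), f)
#' read_recording(f)
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.edf$", path, ignore.case = TRUE)) {
    return(read_edf(path))
  }
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    stop("missing JSON sidecar for channel-matrix file: ", sidecar)
  }
  meta <- tryCatch(
    jsonlite::fromJSON(sidecar),
    error = function(e) stop("malformed sidecar JSON in ", sidecar, ": ",
                             conditionMessage(e))
  )
  if (is.null(meta$fs) || !is.numeric(meta$fs) || meta$fs <= 0) {
    stop("sidecar ", sidecar, " must declare a positive numeric \"fs\"")
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sep <- if (any(grepl("\t", lines))) "\t" else ","
  rows <- lapply(strsplit(lines, sep, fixed = TRUE), as.numeric)
  lens <- lengths(rows)
  if (length(unique(lens)) > 1) {
    stop(sprintf(
      "inconsistent row lengths in %s: %s", path,
      paste(unique(lens), collapse = ", ")
    ))
  }
  data <- do.call(rbind, rows)
  chans <- if (!is.null(meta$channels)) as.character(meta$channels) else NULL
  recording(data, fs = meta$fs, channel_names = chans,
            t0 = if (!is.null(meta$t0)) meta$t0 else 0)
}

#' @rdname read_recording
#' @param rec a `recording` to write.
#' @param digits significant digits used when formatting samples (default 17,
#'   enough for an exact double round trip).
#' @export
write_recording <- function(rec, path, digits = 17) {
  stopifnot(inherits(rec, "recording"))
  txt <- apply(rec$data, 1, function(row) {
    paste(formatC(row, digits = digits, format = "g"), collapse = "\t")
  })
  writeLines(txt, path)
  jsonlite::write_json(
    list(fs = rec$fs, channels = rec$channel_names, t0 = rec$t0),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
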