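#' Trial timing specification
#'
#' Describes how a raw trial epoch is cut down for analysis: the total trial
#' length, the analysis window selected from it, and the length of the
#' non-overlapping feature windows the analysis segment is divided into.
#'
#' The default follows the DEAP-style layout this package targets: a 63-s
#' trial of which the last 40 s (`[23, 63)`) are analysed in 5-s windows.
#' Early parts of a trial are routinely discarded as unstable, and 40 s is
#' an integer multiple of the 5-s window.
#'
#' @param trial_seconds total epoch length in seconds.
#' @param analysis_window numeric length-2 `(start_s, end_s)` selected for
#'   analysis, half-open `[start_s, end_s)` relative to trial start.
#' @param win_seconds feature-window length in seconds.
#' @return A `trial_spec` object.
#' @examples
#' trial_spec() # the 63 s / last 40 s / 5 s default
#' @export
trial_spec <- function(trial_seconds = 63,
                       analysis_window = c(trial_seconds - 40, trial_seconds),
                       win_seconds = 5) {
  stopifnot(length(analysis_window) == 2)
  start_s <- analysis_window[1]; end_s <- analysis_window[2]
  if (!(0 <= start_s && start_s < end_s && end_s <= trial_seconds)) {
    stop("analysis_window must satisfy 0 <= start < end <= trial_seconds")
  }
  if (win_seconds <= 0) stop("win_seconds must be positive")
  structure(
    list(trial_seconds = trial_seconds,
         analysis_window = c(start_s, end_s),
         win_seconds = win_seconds),
    class = "trial_spec"
  )
}

#' @export
print.trial_spec <- function(x, ...) {
  cat(sprintf("<trial_spec> trial %g s, analysis [%g, %g) s, windows %g s\n",
              x$trial_seconds, x$analysis_window[1], x$analysis_window[2],
              x$win_seconds))
  invisible(x)
}

#' Select the analysis segment of a trial
#'
#' Cuts the half-open time window `[start_s, end_s)` of the trial spec out
#' of a recording. No filtering or resampling is performed; fractional
#' sample boundaries are resolved by rounding to the nearest sample.
#'
#' @param rec a `recording`.
#' @param spec a [trial_spec()]; its `analysis_window` is interpreted
#'   relative to the recording's `t0`.
#' @return A `recording` covering the analysis window, with `t0` updated.
#' @examples
#' rec <- recording(matrix(rnorm(2 * 63 * 128), nrow = 2), fs = 128)
#' seg <- select_segment(rec, trial_spec())
#' n_samples(seg) # 40 s x 128 Hz = 5120
#' @export
select_segment <- function(rec, spec = trial_spec()) {
  stopifnot(inherits(rec, "recording"), inherits(spec, "trial_spec"))
  start_s <- spec$analysis_window[1]; end_s <- spec$analysis_window[2]
  i0 <- round(start_s * rec$fs)          # 0-based, inclusive
  i1 <- round(end_s * rec$fs)            # 0-based, exclusive
  if (i1 > n_samples(rec)) {
    stop(sprintf(
      "analysis window [%g, %g) s needs %d samples but recording has %d (short by %d)",
      start_s, end_s, i1, n_samples(rec), i1 - n_samples(rec)
    ))
  }
  recording(
    rec$data[, (i0 + 1):i1, drop = FALSE],
    fs = rec$fs, channel_names = rec$channel_names,
    t0 = rec$t0 + i0 / rec$fs
  )
}

#' Divide a recording into non-overlapping windows
#'
#' Returns `floor(duration / win_seconds)` consecutive windows; a trailing
#' remainder shorter than `win_seconds` is dropped. A recording shorter than
#' one window yields an empty list.
#'
#' @param rec a `recording`.
#' @param win_seconds window length in seconds.
#' @return A list of `recording` windows.
#' @examples
#' rec <- recording(matrix(rnorm(12 * 128), nrow = 1), fs = 128)
#' length(segment_windows(rec, 5)) # 2; trailing 2 s discarded
#' @export
segment_windows <- function(rec, win_seconds) {
  stopifnot(inherits(rec, "recording"))
  if (win_seconds <= 0) stop("win_seconds must be positive")
  n_win_samp <- round(win_seconds * rec$fs)
  n_win <- n_samples(rec) %/% n_win_samp
  if (n_win == 0) return(list())
  lapply(seq_len(n_win), function(k) {
    cols <- ((k - 1) * n_win_samp + 1):(k * n_win_samp)
    recording(
      rec$data[, cols, drop = FALSE],
      fs = rec$fs, channel_names = rec$channel_names,
      t0 = rec$t0 + (k - 1) * n_win_samp / rec$fs
    )
  })
}
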