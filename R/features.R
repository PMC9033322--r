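#' EEG rhythm-band schemes
#'
#' A band scheme is a tibble of named, non-overlapping, strictly increasing
#' frequency intervals over which spectral energy is aggregated. Intervals
#' are half-open `[f_lo, f_hi)`; as the single exception, a band whose upper
#' edge equals the Nyquist frequency also receives the Nyquist bin, so that
#' schemes covering the whole spectrum partition it exactly.
#'
#' The default names the conventional rhythms with a three-way beta split:
#' delta `[1,4)`, theta `[4,8)`, alpha `[8,13)`, beta1 `[13,16)`,
#' beta2 `[16,20)`, beta3 `[20,30)`, gamma `[30,45)` Hz. Band edges —
#' especially the beta sub-band edges, for which no universal standard
#' exists — are configuration, not constants.
#'
#' @param bands a data frame with columns `band`, `f_lo`, `f_hi` (Hz).
#' @return A validated `band_scheme` tibble.
#' @examples
#' default_bands()
#' @export
band_scheme <- function(bands) {
  b <- tibble::as_tibble(bands)
  stopifnot(all(c("band", "f_lo", "f_hi") %in% names(b)))
  b <- b[order(b$f_lo), ]
  if (any(b$f_lo >= b$f_hi) || any(b$f_lo < 0)) {
    stop("each band needs 0 <= f_lo < f_hi")
  }
  if (nrow(b) > 1 && any(b$f_hi[-nrow(b)] > b$f_lo[-1])) {
    stop("bands must be non-overlapping and strictly increasing")
  }
  if (anyDuplicated(b$band)) stop("band names must be unique")
  class(b) <- c("band_scheme", class(b))
  b
}

#' @rdname band_scheme
#' @export
default_bands <- function() {
  band_scheme(tibble::tibble(
    band = c("delta", "theta", "alpha", "beta1", "beta2", "beta3", "gamma"),
    f_lo = c(1, 4, 8, 13, 16, 20, 30),
    f_hi = c(4, 8, 13, 16, 20, 30, 45)
  ))
}

#' Periodogram band energies of one window
#'
#' Removes the window mean, takes the discrete Fourier transform with no
#' zero padding, and sums the periodogram over the bins falling in each band
#' of the scheme. The total is the power over all bins in `(0, fs/2]`;
#' relative energy is band / total. No Welch averaging is done inside a
#' window — averaging across the non-overlapping windows of a trial
#' ([average_band_features()]) plays that role.
#'
#' @param x single-channel numeric vector (one window), or a one-channel
#'   `recording` (then `fs` is taken from it).
#' @param fs sampling rate in Hz.
#' @param scheme a [band_scheme()].
#' @return A tibble with one row per band: `band`, `f_lo`, `f_hi`, `energy`,
#'   `rel_energy`, plus attributes `total` (power over all positive bins)
#'   and `degenerate` (`TRUE` for an all-constant window, where relative
#'   energies are undefined and returned as `NA`).
#' @examples
#' fs <- 128
#' x <- sin(2 * pi * 10 * seq(0, 5 - 1 / fs, by = 1 / fs))
#' be <- band_energy(x, fs)
#' be[be$band == "alpha", "rel_energy"] # ~ 1
#' @export
band_energy <- function(x, fs, scheme = default_bands()) {
  if (inherits(x, "recording")) {
    if (n_channels(x) != 1) stop("band_energy expects a single channel")
    fs <- x$fs; x <- drop(x$data)
  }
  n <- length(x)
  if (n < 2) stop("window must have at least 2 samples")
  if (fs <= 0) stop("fs must be positive")
  x <- x - mean(x)
  P <- Mod(stats::fft(x))^2 / n
  f <- (seq_len(n) - 1) * fs / n
  pos <- f > 0 & f <= fs / 2 + 1e-12
  total <- sum(P[pos])
  degenerate <- total <= .Machine$double.eps * n
  nyq <- fs / 2
  energy <- vapply(seq_len(nrow(scheme)), function(b) {
    lo <- scheme$f_lo[b]; hi <- scheme$f_hi[b]
    inb <- f >= lo & f < hi
    if (abs(hi - nyq) < 1e-12) inb <- inb | abs(f - nyq) < 1e-12
    sum(P[inb & pos])
  }, numeric(1))
  out <- tibble::tibble(
    band = scheme$band, f_lo = scheme$f_lo, f_hi = scheme$f_hi,
    energy = energy,
    rel_energy = if (degenerate) NA_real_ else energy / total
  )
  attr(out, "total") <- total
  attr(out, "degenerate") <- degenerate
  out
}

#' Average band energies across a trial's windows
#'
#' Takes the arithmetic mean of each band's energy and relative energy
#' across the per-window tables, excluding degenerate (all-constant)
#' windows.
#'
#' @param window_tables a list of [band_energy()] tables from the same
#'   trial and scheme.
#' @return A tibble shaped like one [band_energy()] table, with attributes
#'   `n_windows` (used) and `n_excluded`. Errors if no usable window
#'   remains.
#' @export
average_band_features <- function(window_tables) {
  stopifnot(is.list(window_tables), length(window_tables) >= 1)
  degen <- vapply(window_tables, function(t) isTRUE(attr(t, "degenerate")),
                  logical(1))
  usable <- window_tables[!degen]
  if (length(usable) == 0) {
    stop("no usable (non-degenerate) windows in trial; trial dropped")
  }
  out <- usable[[1]]
  out$energy <- rowMeans(vapply(usable, `[[`, numeric(nrow(out)), "energy"))
  out$rel_energy <- rowMeans(vapply(usable, `[[`, numeric(nrow(out)),
                                    "rel_energy"))
  attr(out, "total") <- mean(vapply(usable, attr, numeric(1), "total"))
  attr(out, "degenerate") <- FALSE
  attr(out, "n_windows") <- length(usable)
  attr(out, "n_excluded") <- sum(degen)
  out
}

#' Entropy estimator parameters
#'
#' @param m embedding (template) dimension, at least 1.
#' @param r_frac matching tolerance as a fraction of the series' standard
#'   deviation.
#' @param scales integer coarse-graining scale factors for the multiscale
#'   estimator.
#' @return An `entropy_params` list. Defaults `m = 2`, `r_frac = 0.2`,
#'   scales 1–10 are the values in routine physiological use.
#' @export
entropy_params <- function(m = 2, r_frac = 0.2, scales = 1:10) {
  stopifnot(m >= 1, r_frac > 0, all(scales >= 1), all(scales == round(scales)))
  structure(list(m = as.integer(m), r_frac = r_frac,
                 scales = as.integer(scales)),
            class = "entropy_params")
}

#' Sample entropy
#'
#' The negative log of the conditional probability that subsequences
#' matching for `m` points (Chebyshev distance at most `r`) also match for
#' `m + 1` points: `-log(A / B)`, where `B` counts matching template pairs
#' of length `m` and `A` of length `m + 1`, over the same `n - m` template
#' start points, self-matches excluded.
#'
#' When either count is zero the statistic is undefined; `NA` is returned
#' with attribute `reason` rather than an infinity.
#'
#' @param x numeric series, length greater than `m + 1`.
#' @param m template length.
#' @param r amplitude tolerance (same units as `x`); defaults to
#'   `0.2 * sd(x)`.
#' @return Non-negative scalar, or flagged `NA` when undefined.
#' @examples
#' sample_entropy(rep(1, 50)) # perfectly regular: 0
#' @export
sample_entropy <- function(x, m = 2, r = 0.2 * stats::sd(x)) {
  n <- length(x)
  if (n <= m + 1) stop("need length(x) > m + 1")
  if (!is.finite(r) || r <= 0) {
    # constant series has sd 0; treat as perfectly regular only if truly flat
    if (stats::sd(x) == 0) return(0)
    stop("r must be positive")
  }
  cnt <- sampen_counts_cpp(as.numeric(x), as.integer(m), as.numeric(r))
  B <- cnt[1]; A <- cnt[2]
  if (B == 0 || A == 0) {
    out <- NA_real_
    attr(out, "reason") <- if (B == 0) "no length-m matches (B = 0)" else
      "no length-(m+1) matches (A = 0)"
    return(out)
  }
  -log(A / B)
}

#' Approximate entropy
#'
#' `Phi_m(r) - Phi_{m+1}(r)` with self-matches included in the correlation
#' sums, so the statistic is finite for every valid input.
#'
#' @inheritParams sample_entropy
#' @return Finite scalar.
#' @export
approximate_entropy <- function(x, m = 2, r = 0.2 * stats::sd(x)) {
  n <- length(x)
  if (n <= m + 1) stop("need length(x) > m + 1")
  if (!is.finite(r) || r <= 0) {
    if (stats::sd(x) == 0) return(0)
    stop("r must be positive")
  }
  apen_cpp(as.numeric(x), as.integer(m), as.numeric(r))
}

#' Composite multiscale entropy
#'
#' At scale `tau` the series is coarse-grained by averaging `tau`
#' consecutive samples; unlike plain multiscale entropy, all `tau` distinct
#' offsets are coarse-grained and their sample entropies averaged, which
#' stabilises the estimate at large scales. The tolerance `r` is fixed from
#' the original series' standard deviation and reused at every scale.
#'
#' @param x numeric series.
#' @param params an [entropy_params()].
#' @return A tibble with one row per scale: `scale`, `entropy` (mean over
#'   defined offsets; `NA` when every offset is undefined), `n_offsets`
#'   (offsets contributing).
#' @examples
#' set.seed(1)
#' composite_multiscale_entropy(rnorm(600), entropy_params(scales = 1:4))
#' @export
composite_multiscale_entropy <- function(x, params = entropy_params()) {
  stopifnot(inherits(params, "entropy_params"))
  n <- length(x)
  need <- max(params$scales) * (params$m + 2)
  if (n < need) {
    stop("series too short: need at least max(scales) * (m + 2) = ", need,
         " samples, got ", n)
  }
  r <- params$r_frac * stats::sd(x)
  purrr::map_dfr(params$scales, function(tau) {
    if (tau == 1L) {
      se <- sample_entropy(x, m = params$m, r = r)
      return(tibble::tibble(scale = 1L, entropy = as.numeric(se),
                            n_offsets = as.integer(!is.na(se))))
    }
    vals <- vapply(seq_len(tau) - 1L, function(off) {
      idx <- seq.int(1L + off, n)
      nb <- length(idx) %/% tau
      cg <- colMeans(matrix(x[idx[seq_len(nb * tau)]], nrow = tau))
      as.numeric(sample_entropy(cg, m = params$m, r = r))
    }, numeric(1))
    ok <- !is.na(vals)
    tibble::tibble(
      scale = tau,
      entropy = if (any(ok)) mean(vals[ok]) else NA_real_,
      n_offsets = sum(ok)
    )
  })
}

#' Extract the per-trial, per-channel feature table
#'
#' Runs the full feature pipeline on one or more trials: optional analysis-
#' segment selection, division into non-overlapping windows, per-window band
#' energies averaged across windows, and (optionally) sample entropy,
#' approximate entropy and composite multiscale entropy computed on each
#' channel's full analysis segment (entropy estimates are unstable on short
#' windows, so the segment — not the 5-s window — is the default unit).
#'
#' @param trials a `recording` or list of recordings (one per trial).
#' @param spec optional [trial_spec()]; when supplied each trial is first
#'   cut to its analysis window.
#' @param win_seconds feature-window length in seconds (default 5).
#' @param scheme a [band_scheme()].
#' @param entropy an [entropy_params()] to add the entropy family, or
#'   `NULL` to skip it (band features only).
#' @param labels optional per-trial class labels added as a `label` column.
#' @return A tibble with one row per (trial, channel): `trial`, `channel`,
#'   `label` (if given), `n_windows`, `total_energy`, one `<band>_energy`
#'   and `<band>_rel` column per band, and when `entropy` is supplied
#'   `sampen`, `apen` and `cmse_s<tau>` columns. Rows whose entropies are
#'   undefined carry `NA` there; trials with no usable window are dropped
#'   with a message.
#' @examples
#' trials <- replicate(2, recording(matrix(rnorm(2 * 1280), 2), fs = 128),
#'                     simplify = FALSE)
#' extract_features(trials, entropy = NULL)
#' @export
extract_features <- function(trials, spec = NULL, win_seconds = 5,
                             scheme = default_bands(),
                             entropy = entropy_params(), labels = NULL) {
  if (inherits(trials, "recording")) trials <- list(trials)
  if (!is.null(labels) && length(labels) != length(trials)) {
    stop("labels must have one entry per trial")
  }
  rows <- purrr::imap(trials, function(rec, ti) {
    if (!is.null(spec)) rec <- select_segment(rec, spec)
    wins <- segment_windows(rec, win_seconds)
    if (length(wins) == 0) {
      message("trial ", ti, ": shorter than one window, dropped")
      return(NULL)
    }
    purrr::map_dfr(seq_len(n_channels(rec)), function(ch) {
      tabs <- lapply(wins, function(w) band_energy(w$data[ch, ], rec$fs, scheme))
      avg <- tryCatch(average_band_features(tabs), error = function(e) NULL)
      if (is.null(avg)) {
        message("trial ", ti, " channel ", rec$channel_names[ch],
                ": all windows degenerate, dropped")
        return(NULL)
      }
      row <- tibble::tibble(
        trial = ti, channel = rec$channel_names[ch],
        n_windows = attr(avg, "n_windows"),
        total_energy = attr(avg, "total")
      )
      for (b in seq_len(nrow(avg))) {
        row[[paste0(avg$band[b], "_energy")]] <- avg$energy[b]
        row[[paste0(avg$band[b], "_rel")]] <- avg$rel_energy[b]
      }
      if (!is.null(entropy)) {
        seg <- rec$data[ch, ]
        r <- entropy$r_frac * stats::sd(seg)
        row$sampen <- as.numeric(sample_entropy(seg, entropy$m, r))
        row$apen <- approximate_entropy(seg, entropy$m, r)
        cm <- composite_multiscale_entropy(seg, entropy)
        for (s in seq_len(nrow(cm))) {
          row[[paste0("cmse_s", cm$scale[s])]] <- cm$entropy[s]
        }
      }
      row
    })
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(labels) && nrow(out) > 0) {
    out$label <- labels[out$trial]
    out <- dplyr::relocate(out, "label", .after = "channel")
  }
  out
}

#' Reshape a feature table to one row per trial
#'
#' Pivots the per-(trial, channel) table wide so each trial is a single
#' feature vector with `channel_feature` columns, the shape the classifier
#' consumes. Rows (trials) containing undefined features are dropped with a
#' message.
#'
#' @param features output of [extract_features()].
#' @param channels restrict to these channel names (default all).
#' @return A tibble, one row per trial: `trial`, `label` (if present), then
#'   feature columns.
#' @export
features_wide <- function(features, channels = NULL) {
  df <- features
  if (!is.null(channels)) df <- dplyr::filter(df, .data$channel %in% channels)
  drop_cols <- intersect(c("n_windows", "total_energy"), names(df))
  df <- dplyr::select(df, -dplyr::all_of(drop_cols))
  has_label <- "label" %in% names(df)
  ids <- c("trial", if (has_label) "label")
  wide <- tidyr::pivot_wider(
    df,
    id_cols = dplyr::all_of(ids),
    names_from = "channel",
    values_from = -dplyr::all_of(c(ids, "channel")),
    names_glue = "{channel}_{.value}"
  )
  feat_cols <- setdiff(names(wide), ids)
  bad <- !stats::complete.cases(wide[feat_cols])
  if (any(bad)) {
    message(sum(bad), " trial(s) dropped for undefined feature values")
    wide <- wide[!bad, ]
  }
  wide
}

#' Write / read a feature table as CSV
#'
#' @param features a feature tibble.
#' @param path CSV path.
#' @return [write_features()] returns `path` invisibly; [read_features()] a
#'   tibble.
#' @export
write_features <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
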