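#' Bank of independent benchmark sources
#'
#' Builds the deterministic / stochastic source signals mixed by
#' [make_bss_benchmark()]. Every source is standardised to zero mean and
#' unit variance; the sources are mutually independent by construction.
#'
#' The default bank is the three-source separation benchmark used
#' throughout the package's validation: an 8 Hz sine, a 13 Hz sawtooth and
#' uniform white noise, 60 s at 128 Hz.
#'
#' @param kinds character vector drawn from `sine`, `sawtooth`, `square`,
#'   `chirp`, `uniform_noise`, `gaussian_noise`, `laplacian_noise`.
#' @param freqs frequencies in Hz (ignored for the noise kinds; for `chirp`
#'   the sweep ends at twice this value).
#' @param duration seconds.
#' @param fs sampling rate, Hz.
#' @param seed integer seed for the stochastic sources.
#' @return A `source_bank`: list with the standardised `S` (sources x
#'   samples), `kinds`, `freqs`, `fs`, `duration`, `seed`.
#' @export
source_bank <- function(kinds = c("sine", "sawtooth", "uniform_noise"),
                        freqs = c(8, 13, NA), duration = 60, fs = 128,
                        seed = 1) {
  stopifnot(length(kinds) == length(freqs), duration > 0, fs > 0)
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  set.seed(seed)
  S <- t(vapply(seq_along(kinds), function(i) {
    f <- freqs[i]
    s <- switch(match.arg(kinds[i], c("sine", "sawtooth", "square", "chirp",
                                      "uniform_noise", "gaussian_noise",
                                      "laplacian_noise")),
      sine = sin(2 * pi * f * t),
      sawtooth = 2 * ((f * t) %% 1) - 1,
      square = sign(sin(2 * pi * f * t)),
      chirp = sin(2 * pi * (f * t + f * t^2 / (2 * duration))),
      uniform_noise = stats::runif(n, -1, 1),
      gaussian_noise = stats::rnorm(n),
      laplacian_noise = {
        u <- stats::runif(n, -0.5, 0.5)
        -sign(u) * log(1 - 2 * abs(u))
      }
    )
    (s - mean(s)) / stats::sd(s)
  }, numeric(n)))
  structure(list(S = S, kinds = kinds, freqs = freqs, fs = fs,
                 duration = duration, seed = seed),
            class = "source_bank")
}

#' Mixed-observation benchmark with ground truth
#'
#' Draws a seeded random mixing matrix `A` (standard-normal entries,
#' resampled with an incremented sub-seed if numerically rank deficient),
#' forms `X = A S` plus optional white sensor noise, and returns both the
#' mixed `recording` and the full ground truth for evaluation oracles.
#' Deterministic given `seed`.
#'
#' @param bank a [source_bank()].
#' @param n_channels number of observation channels, at least the number of
#'   sources.
#' @param noise_sd additive Gaussian sensor-noise SD (0 = noiseless).
#' @param seed integer seed for `A` and the noise.
#' @param A fixed mixing matrix (channels x sources) overriding the seeded
#'   random draw.
#' @return A list: `recording` (the mixtures) and `ground_truth` (list with
#'   `A`, `S`, `noise_sd`, `seed`, `condition_number`).
#' @examples
#' bench <- make_bss_benchmark(seed = 42)
#' dim(bench$ground_truth$A)
#' @export
make_bss_benchmark <- function(bank = source_bank(), n_channels = nrow(bank$S),
                               noise_sd = 0, seed = 1, A = NULL) {
  k <- nrow(bank$S)
  if (n_channels < k) stop("n_channels must be >= number of sources (", k, ")")
  if (!is.null(A)) {
    stopifnot(nrow(A) == n_channels, ncol(A) == k)
    if (qr(A)$rank < k) stop("supplied mixing matrix is rank deficient")
    set.seed(seed)
    X <- A %*% bank$S
    if (noise_sd > 0) {
      X <- X + matrix(stats::rnorm(length(X), sd = noise_sd),
                      n_channels, ncol(X))
    }
    return(list(
      recording = recording(X, fs = bank$fs),
      ground_truth = list(A = A, S = bank$S, noise_sd = noise_sd,
                          seed = seed, condition_number = kappa(A, exact = TRUE))
    ))
  }
  sub <- 0L
  repeat {
    set.seed(seed + sub)
    A <- matrix(stats::rnorm(n_channels * k), n_channels, k)
    kap <- kappa(A, exact = TRUE)
    if (qr(A)$rank == k && kap < 1e6) break
    message("sampled mixing matrix rank deficient / ill conditioned; ",
            "resampling with sub-seed ", sub + 1L)
    sub <- sub + 1L
  }
  X <- A %*% bank$S
  if (noise_sd > 0) {
    X <- X + matrix(stats::rnorm(length(X), sd = noise_sd),
                    n_channels, ncol(X))
  }
  list(
    recording = recording(X, fs = bank$fs),
    ground_truth = list(A = A, S = bank$S, noise_sd = noise_sd,
                        seed = seed + sub, condition_number = kap)
  )
}

#' Pink (1/f) noise
#'
#' Gaussian noise shaped in the frequency domain so spectral power falls as
#' 1/f, the canonical broadband background of EEG. Standardised to zero
#' mean, unit variance. Uses the current RNG state (callers seed).
#'
#' @param n samples.
#' @return Numeric vector of length `n`.
#' @export
pink_noise <- function(n) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- c(1, seq_len(n - 1))               # avoid dividing the DC bin by 0
  f <- pmin(f, n - f + 1)                 # symmetric: mirror for neg freqs
  W <- W / sqrt(f)
  p <- Re(stats::fft(W, inverse = TRUE)) / n
  (p - mean(p)) / stats::sd(p)
}

#' Band-limited Gaussian noise
#'
#' White Gaussian noise restricted to `[f_lo, f_hi)` Hz by a frequency-
#' domain brick-wall mask; standardised. Uses the current RNG state.
#'
#' @param n samples.
#' @param fs sampling rate, Hz.
#' @param f_lo,f_hi band edges, Hz.
#' @return Numeric vector of length `n`.
#' @export
band_limited_noise <- function(n, fs, f_lo, f_hi) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)                    # fold to physical frequency
  W[!(f >= f_lo & f < f_hi)] <- 0
  b <- Re(stats::fft(W, inverse = TRUE)) / n
  (b - mean(b)) / stats::sd(b)
}

#' Amplitude-modulated band-limited source
#'
#' A band-limited Gaussian carrier multiplied by a slowly varying positive
#' envelope (rectified 0.1–2 Hz noise), standardised. The modulation makes
#' the source bursty and leptokurtic, like real EEG rhythms — and unlike a
#' plain band-limited Gaussian process, such a source is identifiable by
#' ICA. Uses the current RNG state.
#'
#' @param n samples.
#' @param fs sampling rate, Hz.
#' @param f_lo,f_hi band edges, Hz.
#' @return Numeric vector of length `n`.
#' @export
bursty_band_source <- function(n, fs, f_lo, f_hi) {
  carrier <- band_limited_noise(n, fs, f_lo, f_hi)
  env_hi <- min(2, fs / 2 * 0.9)
  env <- abs(band_limited_noise(n, fs, 0.1, env_hi)) + 0.1
  s <- carrier * env
  (s - mean(s)) / stats::sd(s)
}

#' Specification of the two-class synthetic emotion dataset
#'
#' Describes the generative recipe for a calm-vs-pressure EEG dataset: one
#' bursty band-limited latent component per rhythm band
#' ([bursty_band_source()]), mixed into channels through a per-dataset
#' random spatial pattern, on top of per-channel pink background noise. Both classes share the recipe except the stated
#' per-band gains, encoding the phenomenon the dataset is built to carry:
#' under pressure, rhythm-band energy — particularly beta — increases.
#'
#' Trial ratings are drawn from class-specific truncated normals on the
#' 1–9 valence/arousal scale, so the downstream box-labelling rule recovers
#' the true class for most (not all) trials and exercises its discard zone.
#'
#' @param n_trials_per_class trials per class (default 20, giving a
#'   40-trial session like one subject's worth of the benchmark layout).
#' @param n_channels electrodes (default 32).
#' @param fs sampling rate, Hz (default 128, the preprocessed benchmark
#'   rate).
#' @param trial_seconds trial length (default 63).
#' @param class_gains named list `class -> named gains by band`; bands not
#'   named have gain 1. Default: pressure doubles the beta sub-band
#'   components.
#' @param background pink-noise SD added per channel (default 1).
#' @param rhythm_jitter_sd log-normal SD of the per-trial, per-component
#'   power fluctuation (default 0: every trial has identical rhythm
#'   amplitudes). Spontaneous band power varies between trials in real EEG;
#'   setting this to 0.3–0.5 reproduces that overlap between classes.
#' @param artifact_level amplitude of a single broadband (pink) artifact
#'   source shared by all channels through its own random spatial pattern
#'   (default 0: none). Mimics ocular/muscle contamination, the spatially
#'   low-rank interference ICA exists to remove.
#' @param artifact_jitter_sd log-normal SD of the artifact's per-trial
#'   power fluctuation.
#' @param artifact_band `NULL` for a broadband (pink) artifact, or
#'   `c(f_lo, f_hi)` in Hz for a band-limited bursty artifact — e.g. a
#'   muscle-noise source overlapping the beta band.
#' @param rating_model named list `class -> c(valence_mean, arousal_mean,
#'   sd)`.
#' @param scheme the [band_scheme()] whose bands define the latent
#'   components.
#' @param seed integer seed.
#' @return An `emotion_sim_spec` list.
#' @export
emotion_sim_spec <- function(n_trials_per_class = 20, n_channels = 32,
                             fs = 128, trial_seconds = 63,
                             class_gains = list(
                               calm = c(),
                               pressure = c(beta1 = 2, beta2 = 2, beta3 = 2)
                             ),
                             background = 1, rhythm_jitter_sd = 0,
                             artifact_level = 0, artifact_jitter_sd = 0,
                             artifact_band = NULL,
                             rating_model = list(
                               calm = c(valence = 5, arousal = 2.5, sd = 0.8),
                               pressure = c(valence = 2, arousal = 7, sd = 0.8)
                             ),
                             scheme = default_bands(), seed = 1) {
  stopifnot(n_trials_per_class >= 1, n_channels >= 1, fs > 0,
            trial_seconds > 0)
  if (!setequal(names(class_gains), names(rating_model))) {
    stop("class_gains and rating_model must name the same classes")
  }
  # tolerate JSON-decoded lists in place of numeric vectors
  class_gains <- lapply(class_gains, function(g) {
    g <- unlist(g)
    if (is.null(g)) g <- numeric(0)
    storage.mode(g) <- "double"
    g
  })
  rating_model <- lapply(rating_model, function(m) {
    m <- unlist(m)
    storage.mode(m) <- "double"
    m
  })
  structure(
    list(n_trials_per_class = n_trials_per_class, n_channels = n_channels,
         fs = fs, trial_seconds = trial_seconds, class_gains = class_gains,
         background = background, rhythm_jitter_sd = rhythm_jitter_sd,
         artifact_level = artifact_level,
         artifact_jitter_sd = artifact_jitter_sd,
         artifact_band = artifact_band,
         rating_model = rating_model,
         scheme = scheme, seed = seed),
    class = "emotion_sim_spec"
  )
}

rtrunc_norm <- function(n, mean, sd, lo = 1, hi = 9) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Generate a two-class synthetic emotion EEG dataset
#'
#' For each trial, one band-limited Gaussian component is generated per band
#' of the scheme, scaled by the trial's class gain for that band, and mixed
#' into channels through a spatial pattern drawn once per dataset (shared by
#' all trials, so a single spatial unmixing is meaningful); per-channel pink
#' noise is added on top. Trial order interleaves the classes and the whole
#' dataset is deterministic given the spec's seed.
#'
#' @param spec an [emotion_sim_spec()].
#' @return A list: `trials` (list of `recording`), `ratings` (tibble
#'   `trial`, `valence`, `arousal`), `labels` (true class per trial),
#'   `mixing` (channels x bands spatial pattern), `sources` (per-trial true
#'   latent component matrices, for evaluation oracles), `spec`.
#' @examples
#' ds <- make_emotion_dataset(emotion_sim_spec(
#'   n_trials_per_class = 2, n_channels = 4, trial_seconds = 10, seed = 3))
#' table(ds$labels)
#' @export
make_emotion_dataset <- function(spec = emotion_sim_spec()) {
  stopifnot(inherits(spec, "emotion_sim_spec"))
  set.seed(spec$seed)
  classes <- names(spec$class_gains)
  n_tot <- spec$n_trials_per_class * length(classes)
  labels <- rep(classes, spec$n_trials_per_class)   # interleaved
  n <- round(spec$trial_seconds * spec$fs)
  bands <- spec$scheme
  k <- nrow(bands)
  M <- matrix(stats::rnorm(spec$n_channels * k), spec$n_channels, k)
  # volume conduction spreads an artifact over every electrode: random
  # signs, magnitudes bounded away from zero
  m_art <- sample(c(-1, 1), spec$n_channels, replace = TRUE) *
    stats::runif(spec$n_channels, 0.5, 1.5)

  sources <- vector("list", n_tot)
  trials <- lapply(seq_len(n_tot), function(ti) {
    gains <- rep(1, k)
    cg <- spec$class_gains[[labels[ti]]]
    if (length(cg)) {
      idx <- match(names(cg), bands$band)
      if (anyNA(idx)) stop("class gain names must match scheme bands")
      gains[idx] <- cg
    }
    jit <- if (spec$rhythm_jitter_sd > 0) {
      exp(stats::rnorm(k, sd = spec$rhythm_jitter_sd))
    } else rep(1, k)
    S <- t(vapply(seq_len(k), function(b) {
      bursty_band_source(n, spec$fs, bands$f_lo[b], bands$f_hi[b]) *
        gains[b] * jit[b]
    }, numeric(n)))
    sources[[ti]] <<- S
    X <- M %*% S
    if (spec$artifact_level > 0) {
      art_gain <- spec$artifact_level *
        exp(stats::rnorm(1, sd = spec$artifact_jitter_sd))
      art <- if (is.null(spec$artifact_band)) {
        a <- pink_noise(n) * (abs(band_limited_noise(n, spec$fs, 0.1,
                                  min(2, spec$fs / 2 * 0.9))) + 0.1)
        a / stats::sd(a)
      } else {
        bursty_band_source(n, spec$fs, spec$artifact_band[1],
                           spec$artifact_band[2])
      }
      X <- X + (m_art * art_gain) %*% t(art)
    }
    X <- X + spec$background *
      t(vapply(seq_len(spec$n_channels), function(ch) pink_noise(n),
               numeric(n)))
    recording(X, fs = spec$fs)
  })

  ratings <- purrr::map_dfr(seq_len(n_tot), function(ti) {
    rm_ <- spec$rating_model[[labels[ti]]]
    tibble::tibble(
      trial = ti,
      valence = rtrunc_norm(1, rm_[["valence"]], rm_[["sd"]]),
      arousal = rtrunc_norm(1, rm_[["arousal"]], rm_[["sd"]])
    )
  })

  list(trials = trials, ratings = ratings, labels = labels, mixing = M,
       sources = sources, spec = spec)
}

#' DEAP-shaped study manifest
#'
#' Enumerates the trial units of a study with the benchmark dataset's
#' shape: `n_subjects` subjects each rating `n_trials` stimuli, one trial
#' unit per (subject, trial) pair.
#'
#' @param n_subjects subjects (default 32).
#' @param n_trials trials per subject (default 40).
#' @return A tibble with columns `subject`, `trial` and one row per unit.
#' @examples
#' nrow(study_manifest()) # 1280
#' @export
study_manifest <- function(n_subjects = 32, n_trials = 40) {
  tidyr::expand_grid(subject = seq_len(n_subjects),
                     trial = seq_len(n_trials))
}
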