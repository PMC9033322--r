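#' Standard validation benchmarks
#'
#' Frozen benchmark configurations used to validate the pipeline end to end.
#'
#' `selection_benchmark_spec()` is the channel-selection comparison
#' benchmark: eight channels carrying seven bursty rhythm components (the
#' pressure class doubles the beta2 component), a strong bursty beta-band
#' (14–32 Hz) artifact source with large trial-to-trial power jitter mixed
#' across all channels — muscle-noise-like, spatially low rank — and weak
#' pink sensor noise. On these data every raw channel's beta energy is
#' contaminated by the artifact's within-band power and its cross-spectral
#' noise, while spatial unmixing isolates the class-informative rhythm into
#' a single clean component.
#'
#' @param seed integer seed.
#' @param n_trials_per_class trials per class (default 30).
#' @return An [emotion_sim_spec()].
#' @export
selection_benchmark_spec <- function(seed, n_trials_per_class = 30) {
  emotion_sim_spec(
    n_trials_per_class = n_trials_per_class, n_channels = 8,
    fs = 128, trial_seconds = 15,
    class_gains = list(calm = c(), pressure = c(beta2 = 2)),
    background = 0.3, rhythm_jitter_sd = 0.3,
    artifact_level = 8, artifact_jitter_sd = 1, artifact_band = c(14, 32),
    seed = seed
  )
}

#' Run the channel-selection comparison benchmark
#'
#' Generates the [selection_benchmark_spec()] dataset, computes band-energy
#' features per raw channel and (after one shared spatial unmixing fitted on
#' the concatenated trials) per ICA component, evaluates every unit alone
#' with seed-matched stratified folds, and selects each condition's best
#' unit — the channel-selection result. Returns the best-unit reports, the
#' per-unit accuracy tables and their fold-paired comparison.
#'
#' @param seed integer seed (dataset, ICA initialisation, folds).
#' @param n_trials_per_class trials per class.
#' @param k_folds cross-validation folds.
#' @return A list: `raw`, `ica` (best-unit `eval_report`s), `per_unit_raw`,
#'   `per_unit_ica` (per-unit accuracy tibbles), `comparison`
#'   (fold-paired, ICA minus raw).
#' @export
run_selection_benchmark <- function(seed, n_trials_per_class = 30,
                                    k_folds = 5) {
  ds <- make_emotion_dataset(
    selection_benchmark_spec(seed, n_trials_per_class))
  labels <- label_trials(ds$ratings)$label
  ft_raw <- extract_features(ds$trials, entropy = NULL, labels = labels)
  um <- unmix_trials(ds$trials, seed = seed)
  ft_ica <- extract_features(um$trials, entropy = NULL, labels = labels)

  pc_raw <- evaluate_per_channel(ft_raw, k_folds = k_folds, seed = seed,
                                 condition = "raw")
  pc_ica <- evaluate_per_channel(ft_ica, k_folds = k_folds, seed = seed,
                                 condition = "ica")
  best <- function(pc) attr(pc, "reports")[[which.max(pc$accuracy)]]
  rep_raw <- best(pc_raw)
  rep_ica <- best(pc_ica)
  list(
    raw = rep_raw, ica = rep_ica,
    per_unit_raw = tibble::as_tibble(pc_raw),
    per_unit_ica = tibble::as_tibble(pc_ica),
    comparison = compare_conditions(rep_ica, rep_raw)
  )
}
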