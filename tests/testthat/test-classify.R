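test_that("the labelling rule assigns by box membership with closed edges", {
  ratings <- tibble::tibble(
    trial = 1:6,
    valence = c(5.0, 5.0, 2.0, 4.0, 6.0, 3.0),
    arousal = c(2.0, 5.0, 7.0, 4.0, 1.0, 5.0)
  )
  lab <- label_trials(ratings)
  expect_equal(lab$label,
               c("calm", "discarded", "pressure", "calm", "calm", "pressure"))
  # partition: every trial gets exactly one label
  expect_equal(sum(table(lab$label)), 6)
})

test_that("overlapping boxes and out-of-range ratings are rejected", {
  expect_error(label_rule(c(1, 5, 1, 5), c(4, 8, 4, 8)), "disjoint")
  expect_error(label_rule(c(0, 5, 1, 4)), "\\[1, 9\\]")
  expect_error(
    label_trials(tibble::tibble(trial = 1, valence = 10, arousal = 5)),
    "\\[1, 9\\]"
  )
})

test_that("the discard fraction matches the rating model's outside mass", {
  # calm ratings: valence ~ N(5, .8), arousal ~ N(2.5, .8), truncated to [1,9]
  # numeric integral of the mass outside the calm box (pressure box is far)
  p_v <- diff(pnorm(c(4, 6), 5, 0.8)) / diff(pnorm(c(1, 9), 5, 0.8))
  p_a <- diff(pnorm(c(1, 4), 2.5, 0.8)) / diff(pnorm(c(1, 9), 2.5, 0.8))
  p_keep <- p_v * p_a
  ds <- make_emotion_dataset(emotion_sim_spec(
    n_trials_per_class = 200, n_channels = 1, trial_seconds = 1,
    class_gains = list(calm = c(), pressure = c()), seed = 51))
  lab <- label_trials(ds$ratings)
  calm_kept <- mean(lab$label[ds$labels == "calm"] == "calm")
  ci <- qbinom(c(0.005, 0.995), 200, p_keep) / 200
  expect_gte(calm_kept, ci[1])
  expect_lte(calm_kept, ci[2])
})

make_sep_features <- function(seed, gain, n_per_class = 20, n_ch = 4) {
  ds <- make_emotion_dataset(emotion_sim_spec(
    n_trials_per_class = n_per_class, n_channels = n_ch, trial_seconds = 10,
    class_gains = list(calm = c(),
                       pressure = c(beta1 = gain, beta2 = gain,
                                    beta3 = gain)),
    seed = seed))
  ft <- extract_features(ds$trials, entropy = NULL, labels = ds$labels)
  features_wide(ft)
}

test_that("a separable benchmark reaches accuracy 1 and is deterministic", {
  wide <- make_sep_features(seed = 52, gain = 3)
  rep1 <- evaluate(wide, k_folds = 5, seed = 52)
  expect_equal(rep1$accuracy, 1.0)
  rep2 <- evaluate(wide, k_folds = 5, seed = 52)
  expect_identical(glance(rep1), glance(rep2))
  expect_identical(rep1$fold_accuracy, rep2$fold_accuracy)
  # confusion counts sum to n_used
  expect_equal(sum(rep1$confusion), rep1$n_used)
})

test_that("the null benchmark stays within the binomial band of chance", {
  accs <- vapply(1:20, function(s) {
    wide <- make_sep_features(seed = 6000 + s, gain = 1, n_per_class = 10,
                              n_ch = 2)
    evaluate(wide, k_folds = 5, seed = s)$accuracy
  }, numeric(1))
  n_total <- 20 * 20
  half_width <- 1.96 * sqrt(0.25 / n_total)
  expect_gt(mean(accs), 0.5 - half_width - 0.05)
  expect_lt(mean(accs), 0.5 + half_width + 0.05)
})

test_that("permuting the labels collapses accuracy to chance", {
  wide <- make_sep_features(seed = 53, gain = 3, n_per_class = 15)
  expect_equal(evaluate(wide, k_folds = 5, seed = 53)$accuracy, 1.0)
  set.seed(53)
  perm <- wide
  perm$label <- sample(perm$label)
  acc_perm <- evaluate(perm, k_folds = 5, seed = 53)$accuracy
  ci_hi <- qbinom(0.995, nrow(perm), 0.5) / nrow(perm)
  expect_lte(acc_perm, ci_hi)
})

test_that("degenerate label inputs are rejected", {
  wide <- make_sep_features(seed = 54, gain = 2, n_per_class = 6, n_ch = 2)
  one_class <- wide
  one_class$label <- "calm"
  expect_error(evaluate(one_class, k_folds = 2, seed = 1), "2 classes")
  expect_error(evaluate(wide, k_folds = 10, seed = 1), "2 \\* k_folds")
  expect_error(evaluate(wide, k_folds = 2), "seed")
})

test_that("per-channel evaluation scores each channel block alone", {
  ds <- make_emotion_dataset(emotion_sim_spec(
    n_trials_per_class = 15, n_channels = 3, trial_seconds = 10,
    class_gains = list(calm = c(), pressure = c(beta2 = 3)), seed = 55))
  ft <- extract_features(ds$trials, entropy = NULL, labels = ds$labels)
  pc <- evaluate_per_channel(ft, k_folds = 5, seed = 55)
  expect_equal(nrow(pc), 3)
  expect_true(all(pc$accuracy >= 0 & pc$accuracy <= 1))
  reports <- attr(pc, "reports")
  expect_length(reports, 3)
  expect_s3_class(autoplot(pc), "ggplot")
})

test_that("condition comparison pairs folds and is antisymmetric", {
  wide <- make_sep_features(seed = 56, gain = 2, n_per_class = 15)
  rep_a <- evaluate(wide, k_folds = 5, seed = 56, condition = "ica")
  rep_b <- evaluate(wide, k_folds = 5, seed = 56, condition = "raw")
  cmp <- compare_conditions(rep_a, rep_b)
  expect_equal(attr(cmp, "mean_diff"), 0) # identical inputs -> zero diff
  expect_equal(cmp$diff, rep(0, 5))

  # antisymmetry on genuinely different reports
  wide2 <- wide
  wide2$label <- rev(wide2$label)
  rep_c <- evaluate(wide2, k_folds = 5, seed = 56, condition = "x")
  c1 <- compare_conditions(rep_a, rep_c)
  c2 <- compare_conditions(rep_c, rep_a)
  expect_equal(c1$diff, -c2$diff)

  rep_d <- evaluate(wide, k_folds = 4, seed = 56)
  expect_error(compare_conditions(rep_a, rep_d), "mismatched fold")
})

test_that("evaluation reports serialise to JSON with their bookkeeping", {
  wide <- make_sep_features(seed = 57, gain = 3, n_per_class = 8, n_ch = 2)
  rep <- evaluate(wide, k_folds = 3, seed = 57, condition = "ica")
  p <- tempfile(fileext = ".json")
  write_eval_report(rep, p)
  j <- jsonlite::fromJSON(p)
  expect_equal(j$accuracy, rep$accuracy)
  expect_equal(j$condition, "ica")
  expect_equal(sum(j$confusion$Freq), rep$n_used)
  td <- tidy(rep)
  expect_equal(nrow(td), 3)
  expect_equal(glance(rep)$accuracy, rep$accuracy)
})
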