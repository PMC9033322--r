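#' Valence/arousal labelling rule
#'
#' Maps continuous 1–9 valence/arousal ratings to the two classes by box
#' membership: a trial inside the calm box is `calm`, inside the pressure
#' box `pressure`, and outside both it is `discarded` (a worthless sample).
#' Box intervals are closed at both ends; the boxes must be disjoint.
#'
#' The default geometry places calm at mid valence / low arousal and
#' pressure at low valence / high arousal. The true thresholds behind any
#' particular study are rarely published, so the boxes are configuration,
#' always logged with a run.
#'
#' @param calm_box,pressure_box numeric length-4
#'   `(valence_lo, valence_hi, arousal_lo, arousal_hi)`.
#' @return A `label_rule` object.
#' @export
label_rule <- function(calm_box = c(4, 6, 1, 4),
                       pressure_box = c(1, 3, 5, 9)) {
  stopifnot(length(calm_box) == 4, length(pressure_box) == 4)
  chk <- function(b, nm) {
    if (b[1] > b[2] || b[3] > b[4]) stop(nm, " box has lo > hi")
    if (any(b < 1) || any(b > 9)) stop(nm, " box must lie in [1, 9]")
  }
  chk(calm_box, "calm"); chk(pressure_box, "pressure")
  overlap <- function(a, b) a[1] <= b[2] && b[1] <= a[2]
  if (overlap(calm_box[1:2], pressure_box[1:2]) &&
      overlap(calm_box[3:4], pressure_box[3:4])) {
    stop("calm and pressure boxes must be disjoint")
  }
  structure(list(calm_box = calm_box, pressure_box = pressure_box),
            class = "label_rule")
}

#' @export
print.label_rule <- function(x, ...) {
  fmt <- function(b) sprintf("valence [%g, %g], arousal [%g, %g]",
                             b[1], b[2], b[3], b[4])
  cat("<label_rule>\n  calm:    ", fmt(x$calm_box),
      "\n  pressure:", fmt(x$pressure_box), "\n")
  invisible(x)
}

#' Label trials from their ratings
#'
#' @param ratings a data frame with columns `trial`, `valence`, `arousal`
#'   (values in `[1, 9]`).
#' @param rule a [label_rule()].
#' @return The ratings tibble with a `label` column
#'   (`calm` / `pressure` / `discarded`). The three labels partition the
#'   trials exactly.
#' @examples
#' label_trials(tibble::tibble(trial = 1:2, valence = c(5, 5),
#'                             arousal = c(2, 5)))
#' @export
label_trials <- function(ratings, rule = label_rule()) {
  stopifnot(all(c("trial", "valence", "arousal") %in% names(ratings)),
            inherits(rule, "label_rule"))
  if (any(ratings$valence < 1 | ratings$valence > 9 |
          ratings$arousal < 1 | ratings$arousal > 9)) {
    stop("ratings must lie in [1, 9]")
  }
  inside <- function(v, a, b) v >= b[1] & v <= b[2] & a >= b[3] & a <= b[4]
  out <- tibble::as_tibble(ratings)
  out$label <- dplyr::case_when(
    inside(out$valence, out$arousal, rule$calm_box) ~ "calm",
    inside(out$valence, out$arousal, rule$pressure_box) ~ "pressure",
    TRUE ~ "discarded"
  )
  out
}

stratified_folds <- function(labels, k, seed) {
  # round-robin within class after a seeded shuffle; every class appears in
  # every fold whenever its count >= k
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Cross-validated SVM evaluation of a feature table
#'
#' Runs stratified k-fold cross-validation of a support-vector machine
#' (linear kernel, cost 1 by default) on a one-row-per-trial feature table.
#' Features are standardised per fold using training-fold statistics only.
#' The whole procedure is deterministic given `seed`.
#'
#' @param features a wide feature tibble (see [features_wide()]) with a
#'   `label` column, or pass `labels` separately. Trials labelled
#'   `discarded` are dropped and counted.
#' @param labels optional label vector overriding the `label` column.
#' @param k_folds folds (default 5).
#' @param seed integer seed for fold assignment.
#' @param condition free-form tag recorded in the report, conventionally
#'   `"ica"` or `"raw"`.
#' @param cost SVM cost parameter.
#' @param kernel SVM kernel (default `"linear"`).
#' @return An `eval_report`: overall `accuracy`, per-fold accuracies,
#'   confusion counts, `n_used`, `n_discarded`, and the settings.
#' @examples
#' ds <- make_emotion_dataset(emotion_sim_spec(
#'   n_trials_per_class = 10, n_channels = 3, trial_seconds = 10,
#'   class_gains = list(calm = c(), pressure = c(beta2 = 3)), seed = 5))
#' ft <- extract_features(ds$trials, entropy = NULL, labels = ds$labels)
#' evaluate(features_wide(ft), k_folds = 5, seed = 1)
#' @export
evaluate <- function(features, labels = NULL, k_folds = 5, seed,
                     condition = "raw", cost = 1, kernel = "linear") {
  if (missing(seed)) stop("`seed` is required: evaluation must be reproducible")
  df <- tibble::as_tibble(features)
  if (!is.null(labels)) df$label <- labels
  if (!"label" %in% names(df)) stop("no labels: supply `labels` or a label column")
  n_disc <- sum(df$label == "discarded")
  df <- df[df$label != "discarded", ]
  classes <- sort(unique(df$label))
  if (length(classes) < 2) stop("need at least 2 classes, got: ",
                                paste(classes, collapse = ", "))
  if (nrow(df) < 2 * k_folds) {
    stop("need n_used >= 2 * k_folds (", nrow(df), " < ", 2 * k_folds, ")")
  }
  y <- factor(df$label, levels = classes)
  X <- as.matrix(df[setdiff(names(df), c("trial", "label"))])
  storage.mode(X) <- "double"

  fold <- stratified_folds(as.character(y), k_folds, seed)
  attempt <- 0L
  while (any(vapply(seq_len(k_folds), function(f) {
    length(unique(y[fold != f])) < 2
  }, logical(1))) && attempt < 5L) {
    attempt <- attempt + 1L
    warning("a training fold was single-class; re-stratifying", call. = FALSE)
    fold <- stratified_folds(as.character(y), k_folds, seed + attempt)
  }

  per_fold <- purrr::map_dfr(seq_len(k_folds), function(f) {
    tr <- fold != f; te <- !tr
    mu <- colMeans(X[tr, , drop = FALSE])
    sdv <- apply(X[tr, , drop = FALSE], 2, stats::sd)
    sdv[sdv == 0 | !is.finite(sdv)] <- 1
    Xtr <- scale(X[tr, , drop = FALSE], center = mu, scale = sdv)
    Xte <- scale(X[te, , drop = FALSE], center = mu, scale = sdv)
    fit <- e1071::svm(Xtr, y[tr], kernel = kernel, cost = cost,
                      scale = FALSE)
    pred <- stats::predict(fit, Xte)
    tibble::tibble(fold = f, n_test = sum(te),
                   n_correct = sum(pred == y[te]),
                   accuracy = mean(pred == y[te]),
                   truth = list(y[te]), pred = list(pred))
  })

  truth <- factor(unlist(lapply(per_fold$truth, as.character)), levels = classes)
  pred <- factor(unlist(lapply(per_fold$pred, as.character)), levels = classes)
  confusion <- table(truth = truth, predicted = pred)

  structure(
    list(
      accuracy = sum(per_fold$n_correct) / sum(per_fold$n_test),
      fold_accuracy = per_fold$accuracy,
      per_fold = per_fold[c("fold", "n_test", "n_correct", "accuracy")],
      confusion = confusion,
      n_used = nrow(df), n_discarded = n_disc,
      classes = classes, k_folds = k_folds, seed = seed,
      condition = condition, cost = cost, kernel = kernel
    ),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> condition '%s': accuracy %.3f over %d folds (n = %d used, %d discarded)\n",
    x$condition, x$accuracy, x$k_folds, x$n_used, x$n_discarded
  ))
  print(x$confusion)
  invisible(x)
}

#' @rdname evaluate
#' @param x an `eval_report`.
#' @param ... unused.
#' @method tidy eval_report
#' @export
tidy.eval_report <- function(x, ...) {
  dplyr::mutate(x$per_fold, condition = x$condition)
}

#' @rdname evaluate
#' @method glance eval_report
#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(
    condition = x$condition, accuracy = x$accuracy,
    n_used = x$n_used, n_discarded = x$n_discarded,
    k_folds = x$k_folds, seed = x$seed, cost = x$cost, kernel = x$kernel
  )
}

#' Per-channel evaluation
#'
#' Repeats [evaluate()] with each channel's feature block alone, ranking
#' channels by how much class information their features carry.
#'
#' @param features the long per-(trial, channel) table from
#'   [extract_features()] including a `label` column.
#' @inheritParams evaluate
#' @return A tibble `channel`, `accuracy`, `n_used`, plus the per-channel
#'   `eval_report`s in attribute `reports`; class `per_channel_eval`.
#' @export
evaluate_per_channel <- function(features, k_folds = 5, seed,
                                 condition = "raw", cost = 1,
                                 kernel = "linear") {
  chans <- unique(features$channel)
  reports <- lapply(chans, function(ch) {
    evaluate(features_wide(features, channels = ch), k_folds = k_folds,
             seed = seed, condition = condition, cost = cost, kernel = kernel)
  })
  out <- tibble::tibble(
    channel = chans,
    accuracy = vapply(reports, `[[`, numeric(1), "accuracy"),
    n_used = vapply(reports, `[[`, numeric(1), "n_used")
  )
  attr(out, "reports") <- reports
  class(out) <- c("per_channel_eval", class(out))
  out
}

#' @method autoplot per_channel_eval
#' @export
autoplot.per_channel_eval <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$channel <- factor(df$channel, levels = df$channel[order(df$accuracy)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$channel, y = .data$accuracy)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "cross-validated accuracy")
}

#' Compare two evaluation conditions fold by fold
#'
#' Pairs the per-fold accuracies of two reports run on the same trials with
#' the same fold structure (seed-matched) and summarises the paired
#' differences: mean difference and a sign summary. No significance test is
#' attached.
#'
#' @param report_a,report_b two `eval_report`s, e.g. the ICA-feature and
#'   raw-channel conditions.
#' @return A `condition_comparison` tibble `fold`, `acc_a`, `acc_b`, `diff`
#'   (`a - b`), with attributes `mean_diff`, `n_pos`, `n_neg`, `n_zero`,
#'   `conditions`.
#' @export
compare_conditions <- function(report_a, report_b) {
  stopifnot(inherits(report_a, "eval_report"), inherits(report_b, "eval_report"))
  if (report_a$k_folds != report_b$k_folds ||
      report_a$n_used != report_b$n_used ||
      report_a$seed != report_b$seed ||
      !identical(report_a$per_fold$n_test, report_b$per_fold$n_test)) {
    stop("reports have mismatched fold structure; rerun seed-matched on the same trials")
  }
  d <- report_a$fold_accuracy - report_b$fold_accuracy
  out <- tibble::tibble(
    fold = seq_along(d),
    acc_a = report_a$fold_accuracy,
    acc_b = report_b$fold_accuracy,
    diff = d
  )
  attr(out, "mean_diff") <- mean(d)
  attr(out, "n_pos") <- sum(d > 0)
  attr(out, "n_neg") <- sum(d < 0)
  attr(out, "n_zero") <- sum(d == 0)
  attr(out, "conditions") <- c(report_a$condition, report_b$condition)
  class(out) <- c("condition_comparison", class(out))
  out
}

#' @export
print.condition_comparison <- function(x, ...) {
  cond <- attr(x, "conditions")
  cat(sprintf(
    "<condition_comparison> '%s' - '%s': mean per-fold difference %+.3f (%d+/%d-/%d=)\n",
    cond[1], cond[2], attr(x, "mean_diff"),
    attr(x, "n_pos"), attr(x, "n_neg"), attr(x, "n_zero")
  ))
  print(tibble::as_tibble(unclass(x)[c("fold", "acc_a", "acc_b", "diff")]))
  invisible(x)
}

#' @method autoplot condition_comparison
#' @export
autoplot.condition_comparison <- function(object, ...) {
  cond <- attr(object, "conditions")
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("fold", "acc_a", "acc_b")],
    cols = c("acc_a", "acc_b"), names_to = "condition", values_to = "accuracy"
  )
  df$condition <- ifelse(df$condition == "acc_a", cond[1], cond[2])
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$fold), y = .data$accuracy,
                                   fill = .data$condition)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "fold", y = "accuracy", fill = NULL)
}

#' Write an evaluation report as JSON
#'
#' @param report an `eval_report`.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  jsonlite::write_json(
    list(
      condition = report$condition, accuracy = report$accuracy,
      fold_accuracy = report$fold_accuracy,
      confusion = as.data.frame(report$confusion),
      n_used = report$n_used, n_discarded = report$n_discarded,
      classes = report$classes, k_folds = report$k_folds,
      seed = report$seed, cost = report$cost, kernel = report$kernel
    ),
    path, digits = NA, auto_unbox = TRUE
  )
  invisible(path)
}
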