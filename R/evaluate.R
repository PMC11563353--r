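#' Image-level score of a posterior map
#'
#' The arithmetic mean of the per-pixel posterior probabilities over valid
#' pixels — the single-number summary compared against the decision
#' threshold.
#'
#' @param pmap A [predict_posterior_map()] `posterior_map`.
#' @return Scalar in `[0, 1]`.
#' @export
image_score <- function(pmap) {
  stopifnot(inherits(pmap, "posterior_map"))
  v <- pmap$prob[pmap$mask$valid]
  if (length(v) == 0) stop("image score undefined: no valid pixels")
  mean(v)
}

#' Constrained-ROC decision threshold
#'
#' Chooses the image-score threshold on the training ROC curve with maximum
#' sensitivity subject to a false-positive-rate ceiling (1-specificity of at
#' most `max_fpr`, default 30%). The decision rule is `score >= threshold ->
#' positive`; candidate thresholds are the unique observed scores plus
#' `Inf` (reject-all, always feasible). Ties are broken by lower FPR, then
#' by larger threshold.
#'
#' @param scores Numeric image-level scores.
#' @param labels Binary labels (1 = positive), same length.
#' @param max_fpr Maximum admissible false-positive rate (default 0.30).
#' @return List with `threshold`, `sensitivity`, `fpr`.
#' @export
optimize_threshold <- function(scores, labels, max_fpr = 0.30) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0)
    stop("both classes required to optimize the threshold")
  cand <- c(sort(unique(scores)), Inf)
  sens <- vapply(cand, function(th) sum(scores >= th & labels == 1) / n_pos,
                 numeric(1))
  fpr <- vapply(cand, function(th) sum(scores >= th & labels == 0) / n_neg,
                numeric(1))
  ok <- fpr <= max_fpr + 1e-12
  cand <- cand[ok]; sens <- sens[ok]; fpr <- fpr[ok]
  best <- order(-sens, fpr, -cand)[1]
  list(threshold = cand[best], sensitivity = sens[best], fpr = fpr[best])
}

#' Confusion-matrix counts from binary truth and prediction
#'
#' @param truth,predicted Binary vectors (1 = positive).
#' @return Object of class `confusion_matrix`: named counts `TP`, `FN`,
#'   `TN`, `FP`.
#' @export
confusion_matrix <- function(truth, predicted) {
  truth <- as.integer(truth); predicted <- as.integer(predicted)
  stopifnot(length(truth) == length(predicted),
            all(truth %in% 0:1), all(predicted %in% 0:1))
  structure(c(TP = sum(truth == 1 & predicted == 1),
              FN = sum(truth == 1 & predicted == 0),
              TN = sum(truth == 0 & predicted == 0),
              FP = sum(truth == 0 & predicted == 1)),
            class = "confusion_matrix")
}

#' Sensitivity, specificity and accuracy of a confusion matrix
#'
#' Sensitivity = TP / (TP + FN), specificity = TN / (TN + FP), accuracy =
#' (TP + TN) / N. Returned as fractions; use [as_percent()] for the
#' nearest-integer percent convention used in reporting.
#'
#' @param cm A [confusion_matrix()] or named vector with `TP`, `FN`, `TN`,
#'   `FP`.
#' @return Named numeric vector `c(sensitivity, specificity, accuracy)`.
#' @export
confusion_metrics <- function(cm) {
  cm <- unclass(cm)
  stopifnot(all(c("TP", "FN", "TN", "FP") %in% names(cm)), all(cm >= 0))
  if (cm[["TP"]] + cm[["FN"]] == 0)
    stop("sensitivity undefined: no positive lesions")
  if (cm[["TN"]] + cm[["FP"]] == 0)
    stop("specificity undefined: no benign lesions")
  c(sensitivity = cm[["TP"]] / (cm[["TP"]] + cm[["FN"]]),
    specificity = cm[["TN"]] / (cm[["TN"]] + cm[["FP"]]),
    accuracy = (cm[["TP"]] + cm[["TN"]]) / sum(cm))
}

#' Nearest-integer percent
#'
#' @param x Fraction(s) in `[0, 1]`.
#' @return `round(100 * x)`.
#' @export
as_percent <- function(x) round(100 * x)

# One LOPOCV fold: hold out patient i, train on the rest, classify the
# held-out lesion image.
run_fold <- function(cohort, i, pool, k, C, pixel_cap, max_fpr, seed) {
  train <- cohort[-i]
  train_labels <- vapply(train, function(e)
    as.integer(is_positive_grade(e$histopathology)), integer(1))
  if (length(unique(train_labels)) < 2)
    stop("training fold for patient ", cohort[[i]]$patient_id,
         " collapses to one class")
  stacks <- lapply(train, `[[`, "lesion")

  table <- make_pixel_table(stacks, train_labels, pool = pool,
                            pixel_cap = pixel_cap,
                            seed = derive_seed(seed, 5L, i))
  warm <- NULL
  if (length(table$pool) > k) {
    full <- fit_l1_svm(table$x, table$y, C = C)
    ranking <- rank_features(full$weights)
    warm <- full$weights
  } else {
    ranking <- structure(list(
      normalized_weights = stats::setNames(rep(1 / length(table$pool),
                                               length(table$pool)),
                                           table$pool),
      order = table$pool), class = "feature_ranking")
  }
  model <- retrain_top_k(table, ranking, k = min(k, length(table$pool)),
                         C = C, warm = warm)

  train_scores <- vapply(stacks, function(s)
    image_score(predict_posterior_map(model, s)), numeric(1))
  thr <- optimize_threshold(train_scores, train_labels, max_fpr = max_fpr)

  pmap <- predict_posterior_map(model, cohort[[i]]$lesion)
  score <- image_score(pmap)
  structure(list(held_out_patient = cohort[[i]]$patient_id,
                 histopathology = cohort[[i]]$histopathology,
                 model = model,
                 threshold = thr$threshold,
                 train_sensitivity = thr$sensitivity,
                 train_fpr = thr$fpr,
                 image_score = score,
                 predicted_label = as.integer(score >= thr$threshold),
                 true_label = as.integer(
                   is_positive_grade(cohort[[i]]$histopathology)),
                 posterior = pmap),
            class = "fold_result")
}

summarize_folds <- function(folds, pool_names, pool, k, C) {
  truth <- vapply(folds, `[[`, integer(1), "true_label")
  pred <- vapply(folds, `[[`, integer(1), "predicted_label")
  grade <- vapply(folds, `[[`, character(1), "histopathology")
  cm <- confusion_matrix(truth, pred)
  per_grade <- lapply(HISTO_LEVELS, function(g) {
    sel <- grade == g
    c(n = sum(sel),
      predicted_benign = sum(sel & pred == 0),
      predicted_positive = sum(sel & pred == 1))
  })
  names(per_grade) <- HISTO_LEVELS
  sel_freq <- vapply(pool_names, function(f)
    mean(vapply(folds, function(fr) f %in% fr$model$selected_features,
                logical(1))), numeric(1))
  structure(list(folds = folds,
                 pool = pool, k = k, C = C,
                 confusion = cm,
                 per_grade = per_grade,
                 metrics = confusion_metrics(cm),
                 selection_frequency = sel_freq),
            class = "cv_report")
}

#' Leave-one-patient-out cross-validation
#'
#' For each patient: hold out that patient's lesion image; fit the full-pool
#' L1-SVM on the remaining patients' pixels; rank features by normalized
#' absolute weight; retrain on the top-k features and calibrate; score every
#' training image (mean posterior) and optimize the constrained-ROC
#' threshold on the training scores; then score and classify the held-out
#' image (`score >= threshold`). The held-out image never influences
#' training, ranking, calibration or thresholding.
#'
#' @param cohort List of cohort entries, each with `patient_id`,
#'   `histopathology`, and `lesion` (an 18-feature [feature_stack()]); see
#'   [cohort_feature_stacks()].
#' @param pool Feature pool: `"absolute"`, `"relative"`, `"both"`, or
#'   explicit feature names.
#' @param k Number of top-ranked features to retrain on (the evaluated sizes
#'   are 3, 4 and 5; the single-feature baseline uses 1).
#' @param C L1-SVM regularization parameter (default 1).
#' @param pixel_cap Per-image training-pixel cap (default 2000; `Inf`
#'   reproduces the all-pixels design).
#' @param max_fpr False-positive-rate ceiling of the threshold search.
#' @param seed Integer seed for the pixel subsampling.
#' @return Object of class `cv_report`: `folds`, `confusion`, `per_grade`,
#'   `metrics`, `selection_frequency`.
#' @export
lopocv <- function(cohort, pool = "absolute", k = 4, C = 1,
                   pixel_cap = 2000, max_fpr = 0.30, seed = 1L) {
  stopifnot(length(cohort) >= 4)
  labels <- vapply(cohort, function(e)
    as.integer(is_positive_grade(e$histopathology)), integer(1))
  if (sum(labels == 1) < 2 || sum(labels == 0) < 2)
    stop("need at least 2 patients per class")
  pool_names <- resolve_pool(pool, cohort[[1]]$lesion$feature_names)
  folds <- lapply(seq_along(cohort), function(i)
    run_fold(cohort, i, pool = pool_names, k = k, C = C,
             pixel_cap = pixel_cap, max_fpr = max_fpr, seed = seed))
  summarize_folds(folds, pool_names,
                  pool = if (length(pool) == 1) pool else "custom",
                  k = k, C = C)
}

#' Single-feature baseline simulating a blue-excitation adjunct
#'
#' Runs the identical LOPOCV protocol with the single feature
#' `I452,n + I500,n` (the combined normalized NADH + FAD band emission that
#' a VELscope-like device visualizes): no ranking step, `k = 1`.
#'
#' @inheritParams lopocv
#' @return A `cv_report` whose selection frequency is 1 for the baseline
#'   feature.
#' @export
velscope_baseline <- function(cohort, C = 1, pixel_cap = 2000,
                              max_fpr = 0.30, seed = 1L) {
  vs_cohort <- lapply(cohort, function(e) {
    e$lesion <- velscope_stack(e$lesion)
    e
  })
  rep <- lopocv(vs_cohort, pool = VELSCOPE_FEATURE, k = 1, C = C,
                pixel_cap = pixel_cap, max_fpr = max_fpr, seed = seed)
  rep$pool <- "velscope"
  rep
}

#' @export
print.cv_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("cv_report: pool=%s, k=%d, C=%g, %d folds\n",
              x$pool, x$k, x$C, length(x$folds)))
  cat(sprintf("  sensitivity %d%%  specificity %d%%  accuracy %d%%\n",
              as_percent(m[["sensitivity"]]), as_percent(m[["specificity"]]),
              as_percent(m[["accuracy"]])))
  cat(sprintf("  confusion: TP=%d FN=%d TN=%d FP=%d\n",
              x$confusion[["TP"]], x$confusion[["FN"]],
              x$confusion[["TN"]], x$confusion[["FP"]]))
  invisible(x)
}
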