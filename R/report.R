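finite_or_na <- function(x) ifelse(is.finite(x), x, NA_real_)

metrics_table <- function(reports) {
  do.call(rbind, lapply(reports, function(r) {
    m <- r$metrics
    data.frame(pool = r$pool, k = r$k, C = r$C,
               n_folds = length(r$folds),
               TP = r$confusion[["TP"]], FN = r$confusion[["FN"]],
               TN = r$confusion[["TN"]], FP = r$confusion[["FP"]],
               sensitivity = m[["sensitivity"]],
               specificity = m[["specificity"]],
               accuracy = m[["accuracy"]],
               sensitivity_pct = as_percent(m[["sensitivity"]]),
               specificity_pct = as_percent(m[["specificity"]]),
               accuracy_pct = as_percent(m[["accuracy"]]),
               stringsAsFactors = FALSE)
  }))
}

selection_frequency_table <- function(reports) {
  do.call(rbind, lapply(reports, function(r) {
    data.frame(pool = r$pool, k = r$k,
               feature = names(r$selection_frequency),
               frequency = unname(r$selection_frequency),
               stringsAsFactors = FALSE)
  }))
}

folds_list <- function(reports) {
  lapply(reports, function(r) {
    list(pool = r$pool, k = r$k,
         folds = lapply(r$folds, function(f)
           list(held_out_patient = f$held_out_patient,
                histopathology = f$histopathology,
                selected_features = f$model$selected_features,
                image_score = f$image_score,
                threshold = finite_or_na(f$threshold),
                predicted_label = f$predicted_label,
                true_label = f$true_label)))
  })
}

# Red posterior scale composited over the gray total-intensity image.
overlay_rgb <- function(prob, total, mask) {
  rng <- range(total[mask$valid], finite = TRUE)
  gray <- (total - rng[1]) / max(rng[2] - rng[1], .Machine$double.eps)
  gray[!mask$valid] <- 0
  gray <- pmin(pmax(gray, 0), 1)
  a <- prob
  a[!mask$valid | is.na(a)] <- 0
  rgb <- array(0, dim = c(nrow(gray), ncol(gray), 3))
  rgb[, , 1] <- (1 - a) * gray + a          # red ramps with probability
  rgb[, , 2] <- (1 - a) * gray
  rgb[, , 3] <- (1 - a) * gray
  rgb
}

#' Write cross-validation report files
#'
#' Writes `metrics.csv` (one row per pool x k run: confusion counts,
#' sensitivity/specificity/accuracy as fractions and nearest-integer
#' percent), `confusion.json` (overall and per-grade counts),
#' `selection_frequency.csv` (fraction of folds each feature was selected
#' in), `folds.json` (per-fold scores, thresholds and predictions), and —
#' when cohort entries are supplied — one PNG posterior overlay per lesion
#' (red probability scale over the gray total-intensity image).
#'
#' @param reports A `cv_report` or list of them.
#' @param out_dir Output directory (created if absent).
#' @param cohort Optional cohort (from [cohort_feature_stacks()]) used for
#'   the total-intensity underlays of the overlay images.
#' @return Invisibly, the vector of files written.
#' @export
write_report <- function(reports, out_dir, cohort = NULL) {
  if (inherits(reports, "cv_report")) reports <- list(reports)
  stopifnot(all(vapply(reports, inherits, logical(1), "cv_report")))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)

  f <- file.path(out_dir, "metrics.csv")
  utils::write.csv(metrics_table(reports), f, row.names = FALSE)
  files <- c(files, f)

  f <- file.path(out_dir, "selection_frequency.csv")
  utils::write.csv(selection_frequency_table(reports), f, row.names = FALSE)
  files <- c(files, f)

  f <- file.path(out_dir, "confusion.json")
  jsonlite::write_json(lapply(reports, function(r)
    list(pool = r$pool, k = r$k,
         overall = as.list(unclass(r$confusion)),
         per_grade = r$per_grade)),
    f, auto_unbox = TRUE, pretty = TRUE)
  files <- c(files, f)

  f <- file.path(out_dir, "folds.json")
  jsonlite::write_json(folds_list(reports), f, auto_unbox = TRUE,
                       pretty = TRUE, na = "null")
  files <- c(files, f)

  if (!is.null(cohort)) {
    ov_dir <- file.path(out_dir, "overlays")
    dir.create(ov_dir, showWarnings = FALSE)
    by_id <- stats::setNames(cohort, vapply(cohort, `[[`, character(1),
                                            "patient_id"))
    r1 <- reports[[1]]
    for (fold in r1$folds) {
      entry <- by_id[[fold$held_out_patient]]
      if (is.null(entry)) next
      rgb <- overlay_rgb(fold$posterior$prob,
                         entry$lesion$meta$total_intensity,
                         fold$posterior$mask)
      fn <- file.path(ov_dir, sprintf("%s_%s_%s.png",
                                      fold$held_out_patient,
                                      fold$histopathology,
                                      if (fold$predicted_label == 1)
                                        "positive" else "benign"))
      png::writePNG(rgb, fn)
      files <- c(files, fn)
    }
  }
  invisible(files)
}
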