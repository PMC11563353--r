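resolve_pool <- function(pool, available) {
  if (length(pool) == 1 && pool %in% c("absolute", "relative", "both"))
    pool <- spectral_feature_names(pool)
  missing <- setdiff(pool, available)
  if (length(missing) > 0)
    stop("features not present in stacks: ", paste(missing, collapse = ", "))
  if (length(pool) == 0) stop("empty feature pool")
  pool
}

#' Assemble the pixel-level training table
#'
#' Stacks the valid pixels of a set of lesion feature stacks into a design
#' matrix (columns = pool features in canonical order). Every pixel inherits
#' its image's binary label — the histopathology of the central biopsy —
#' which is the label-noise source inherent to image-level ground truth.
#' Optionally caps the number of pixels per image with a seeded uniform
#' subsample to keep cross-validation tractable.
#'
#' @param stacks List of lesion [feature_stack()] objects.
#' @param labels Binary vector (1 = cancer/pre-cancer), one per stack.
#' @param pool `"absolute"`, `"relative"`, `"both"`, or an explicit character
#'   vector of feature names.
#' @param pixel_cap Maximum pixels per image (`Inf` keeps all valid pixels).
#' @param seed Integer seed for the subsample.
#' @return List with `x` (matrix), `y` (0/1 vector), `image` (row-wise image
#'   index), `pool` (resolved feature names).
#' @export
make_pixel_table <- function(stacks, labels, pool = "absolute",
                             pixel_cap = Inf, seed = 1L) {
  stopifnot(length(stacks) == length(labels), length(stacks) >= 1)
  pool <- resolve_pool(pool, stacks[[1]]$feature_names)
  labels <- as.integer(labels)
  stopifnot(all(labels %in% c(0L, 1L)))

  rows <- vector("list", length(stacks))
  for (i in seq_along(stacks)) {
    s <- stacks[[i]]
    idx <- which(s$mask$valid)
    if (length(idx) == 0) stop("stack ", i, " has no valid pixels")
    if (is.finite(pixel_cap) && length(idx) > pixel_cap)
      idx <- with_seed(derive_seed(seed, 4L, i),
                       sort(sample(idx, pixel_cap)))
    m <- vapply(pool, function(f) s$features[[f]][idx], numeric(length(idx)))
    if (length(idx) == 1) m <- matrix(m, nrow = 1, dimnames = list(NULL, pool))
    rows[[i]] <- m
  }
  x <- do.call(rbind, rows)
  n_per <- vapply(rows, nrow, integer(1))
  list(x = x,
       y = rep(labels, n_per),
       image = rep(seq_along(stacks), n_per),
       pool = pool)
}

#' Fit the L1-regularized linear SVM on standardized pixel features
#'
#' Columns are z-scored on the training pixels (weight magnitudes are only
#' comparable across features on commensurate scales), then the
#' L1-penalized squared-hinge linear SVM is fitted via [l1svm_fit()].
#'
#' @param x Pixel-by-feature matrix (named columns).
#' @param y Binary pixel labels (1 = positive).
#' @param C Regularization parameter (default 1).
#' @return List with named `weights` (on the standardized scale), `bias`,
#'   `center`, `scale`, `C`, `solver`.
#' @export
fit_l1_svm <- function(x, y, C = 1, warm = NULL) {
  stopifnot(is.matrix(x), !is.null(colnames(x)))
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale, "/")
  fit <- l1svm_fit(xs, y, C = C, warm = warm)
  weights <- fit$weights
  names(weights) <- colnames(x)
  list(weights = weights, bias = fit$bias,
       center = center, scale = scale, C = C,
       solver = fit$solver, objective = fit$objective,
       iterations = fit$iterations, converged = fit$converged)
}

#' Rank features by normalized absolute SVM weight
#'
#' Takes the absolute value of each weight, normalizes to sum 1, and sorts
#' descending; ties (and all-zero weight vectors) fall back to the canonical
#' feature order.
#'
#' @param weights Named weight vector from [fit_l1_svm()].
#' @return Object of class `feature_ranking`: list with `normalized_weights`
#'   (in input order) and `order` (feature names, descending weight).
#' @export
rank_features <- function(weights) {
  stopifnot(!is.null(names(weights)))
  aw <- abs(weights)
  total <- sum(aw)
  if (total == 0) {
    warning("all SVM weights are zero; ranking falls back to canonical order")
    nw <- aw
  } else {
    nw <- aw / total
  }
  canon <- seq_along(weights)  # input order is the canonical pool order
  ord <- order(-nw, canon)
  structure(list(normalized_weights = nw, order = names(weights)[ord]),
            class = "feature_ranking")
}

#' Retrain on the top-k ranked features and calibrate
#'
#' Refits the L1-SVM using only the `k` highest-ranked features, then fits a
#' Platt-style logistic calibration on the training decision values so the
#' model emits posterior probabilities. If fewer than `k` features carried
#' nonzero weight in the full fit, the remainder of the top-k is filled from
#' zero-weight features in canonical order (with a warning).
#'
#' @param table Pixel table from [make_pixel_table()].
#' @param ranking A [rank_features()] result for the table's pool.
#' @param k Number of features to keep.
#' @param C Regularization parameter.
#' @param warm Optional warm start for the refit, a named weight vector on
#'   the standardized scale (e.g. the full-pool fit's weights).
#' @return Object of class `trained_model`: `selected_features`, `weights`,
#'   `bias`, `center`, `scale`, `calibration`, `C`, `solver`.
#' @export
retrain_top_k <- function(table, ranking, k, C = 1, warm = NULL) {
  stopifnot(inherits(ranking, "feature_ranking"), k >= 1,
            k <= length(ranking$order))
  nnz <- sum(ranking$normalized_weights > 0)
  if (nnz < k && nnz > 0)
    warning("only ", nnz, " features have nonzero weight; top-", k,
            " filled from zero-weight features in canonical order")
  selected <- ranking$order[seq_len(k)]
  xs <- table$x[, selected, drop = FALSE]
  warm_fit <- if (!is.null(warm))
    list(weights = unname(warm[selected]), bias = 0)
  fit <- fit_l1_svm(xs, table$y, C = C, warm = warm_fit)
  d <- decision_values(fit, xs)
  calibration <- platt_calibrate(d, table$y)
  structure(list(selected_features = selected,
                 weights = fit$weights, bias = fit$bias,
                 center = fit$center, scale = fit$scale,
                 calibration = calibration, C = C,
                 solver = fit$solver),
            class = "trained_model")
}

decision_values <- function(model, x) {
  xs <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  drop(xs %*% model$weights) + model$bias
}

#' Per-pixel posterior probability map
#'
#' Applies a trained model at the pixel level: standardizes the selected
#' features with the training statistics, computes the linear decision
#' value, and maps it through the logistic calibration. Every value of a
#' posterior map is the estimated likelihood that the pixel belongs to a
#' cancerous/pre-cancerous lesion; masked pixels are `NA`.
#'
#' @param model A [retrain_top_k()] `trained_model`.
#' @param stack A lesion [feature_stack()] containing the model's features.
#' @return Object of class `posterior_map`: list with `prob` (matrix in
#'   `[0, 1]`, `NA` at masked pixels) and `mask`.
#' @export
predict_posterior_map <- function(model, stack) {
  stopifnot(inherits(model, "trained_model"),
            inherits(stack, "feature_stack"))
  missing <- setdiff(model$selected_features, stack$feature_names)
  if (length(missing) > 0)
    stop("stack is missing model features: ", paste(missing, collapse = ", "))
  idx <- which(stack$mask$valid)
  x <- vapply(model$selected_features, function(f) stack$features[[f]][idx],
              numeric(length(idx)))
  if (length(idx) == 1)
    x <- matrix(x, nrow = 1, dimnames = list(NULL, model$selected_features))
  p <- calibrated_probability(decision_values(model, x), model$calibration)
  prob <- matrix(NA_real_, nrow(stack$mask$valid), ncol(stack$mask$valid))
  prob[idx] <- pmin(pmax(p, 0), 1)
  structure(list(prob = prob, mask = stack$mask), class = "posterior_map")
}
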