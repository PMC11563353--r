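# Two-class pixel data with one informative column among noise columns.
planted_data <- function(n = 300, p = 5, delta = 3, seed = 1) {
  set.seed(seed)
  y <- rep(c(0, 1), length.out = n)
  x <- matrix(rnorm(n * p), n, p)
  x[, 1] <- x[, 1] + delta * y
  colnames(x) <- paste0("f", seq_len(p))
  list(x = x, y = y)
}

# Subgradient optimality of ||w||_1 + C * sum(max(0, 1 - y f)^2):
# at a minimum, |grad_j| <= 1 where w_j = 0, grad_j = -sign(w_j) otherwise,
# and the intercept gradient vanishes.
kkt_residual <- function(x, y, fit, C) {
  ys <- 2 * y - 1
  z <- drop(x %*% fit$weights) + fit$bias
  h <- pmax(0, 1 - ys * z)
  g <- drop(crossprod(x, -2 * C * ys * h))
  r_zero <- if (any(fit$weights == 0))
    max(0, max(abs(g[fit$weights == 0]) - 1))
  else 0
  r_nz <- if (any(fit$weights != 0))
    max(abs(g[fit$weights != 0] + sign(fit$weights[fit$weights != 0])))
  else 0
  max(r_zero, r_nz, abs(sum(-2 * C * ys * h)))
}

test_that("the L1-SVM solver satisfies subgradient optimality", {
  for (seed in 1:5) {
    d <- planted_data(n = 120, p = 6, delta = 2, seed = seed)
    fit <- l1svm_fit(d$x, d$y, C = 1)
    scale_ref <- max(1, sqrt(sum(d$x^2)))
    expect_lt(kkt_residual(d$x, d$y, fit, 1) / scale_ref, 1e-4)
    # no perturbation of the solution improves the objective
    obj <- oralaf:::l1svm_objective(d$x, 2 * d$y - 1, fit$weights, fit$bias, 1)
    set.seed(seed + 100)
    for (i in 1:20) {
      dw <- rnorm(length(fit$weights), 0, 0.05)
      expect_gte(oralaf:::l1svm_objective(d$x, 2 * d$y - 1,
                                          fit$weights + dw,
                                          fit$bias + rnorm(1, 0, 0.05), 1),
                 obj - 1e-8)
    }
  }
})

test_that("a single separating feature dominates the normalized weights", {
  d <- planted_data(n = 400, p = 6, delta = 6, seed = 2)
  fit <- fit_l1_svm(d$x, d$y, C = 1)
  ranking <- rank_features(fit$weights)
  nw <- ranking$normalized_weights
  expect_identical(ranking$order[1], "f1")
  expect_true(all(nw[names(nw) != "f1"] < 0.1))
})

test_that("pure-noise feature weights shrink toward zero under L1", {
  med_noise_weight <- median(sapply(1:10, function(seed) {
    d <- planted_data(n = 500, p = 8, delta = 4, seed = seed)
    fit <- fit_l1_svm(d$x, d$y, C = 1)
    max(rank_features(fit$weights)$normalized_weights[-1])
  }))
  expect_lt(med_noise_weight, 0.05)
})

test_that("row duplication with C halved leaves the solution unchanged", {
  d <- planted_data(n = 80, p = 4, delta = 2, seed = 7)
  f1 <- l1svm_fit(d$x, d$y, C = 1)
  f2 <- l1svm_fit(rbind(d$x, d$x), c(d$y, d$y), C = 0.5)
  expect_equal(f2$weights, f1$weights, tolerance = 1e-4)
  expect_equal(f2$bias, f1$bias, tolerance = 1e-4)
})

test_that("sparsity is non-increasing as C decreases", {
  d <- planted_data(n = 200, p = 10, delta = 1.5, seed = 3)
  nnz <- sapply(c(3, 1, 0.3, 0.1, 0.03, 0.01),
                function(C) sum(l1svm_fit(d$x, d$y, C = C)$weights != 0))
  expect_true(all(diff(nnz) <= 0))
  expect_lt(nnz[length(nnz)], nnz[1])
})

test_that("feature ranking normalizes, sorts and tie-breaks canonically", {
  w <- c(a = -2, b = 1, c = 1)
  r <- rank_features(w)
  expect_equal(unname(r$normalized_weights), c(0.5, 0.25, 0.25))
  expect_identical(r$order, c("a", "b", "c"))  # b before c by input order
  expect_equal(sum(r$normalized_weights), 1)

  r2 <- rank_features(c(x = 1, y = -1, z = 1))
  expect_identical(r2$order, c("x", "y", "z"))

  expect_warning(r3 <- rank_features(c(u = 0, v = 0)), "zero")
  expect_identical(r3$order, c("u", "v"))
})

test_that("pixel tables honor pool, cap and seed", {
  cohort <- small_cohort(seed = 23, n_patients = 4)
  stacks <- lapply(cohort, `[[`, "lesion")
  labels <- as.integer(vapply(cohort, function(e)
    is_positive_grade(e$histopathology), logical(1)))

  t9 <- make_pixel_table(stacks, labels, pool = "absolute")
  t18 <- make_pixel_table(stacks, labels, pool = "both")
  expect_equal(ncol(t9$x), 9)
  expect_equal(ncol(t18$x), 18)
  total_valid <- sum(vapply(stacks, function(s) valid_count(s$mask),
                            integer(1)))
  expect_equal(nrow(t18$x), total_valid)  # cap = Inf keeps every valid pixel
  expect_false(anyNA(t18$x))

  tc1 <- make_pixel_table(stacks, labels, pool = "absolute",
                          pixel_cap = 50, seed = 5)
  tc2 <- make_pixel_table(stacks, labels, pool = "absolute",
                          pixel_cap = 50, seed = 5)
  tc3 <- make_pixel_table(stacks, labels, pool = "absolute",
                          pixel_cap = 50, seed = 6)
  expect_identical(tc1$x, tc2$x)
  expect_false(identical(tc1$x, tc3$x))
  expect_equal(nrow(tc1$x), 50 * length(stacks))
  expect_equal(tc1$y, rep(labels, each = 50))

  expect_error(make_pixel_table(stacks, labels, pool = "nonsense"),
               "not present")
})

test_that("standardization round-trips and is stored on the model", {
  d <- planted_data(n = 150, p = 4, delta = 2, seed = 11)
  fit <- fit_l1_svm(d$x, d$y)
  xs <- sweep(sweep(d$x, 2, fit$center), 2, fit$scale, "/")
  back <- sweep(sweep(xs, 2, fit$scale, "*"), 2, fit$center, "+")
  expect_lt(max(abs(back - d$x)), 1e-9)
  expect_true(all(fit$scale > 0))
})

test_that("top-k retraining selects k features and calibrates posteriors", {
  d <- planted_data(n = 400, p = 9, delta = 4, seed = 13)
  table <- list(x = d$x, y = d$y, pool = colnames(d$x))
  full <- fit_l1_svm(d$x, d$y)
  ranking <- rank_features(full$weights)

  m4 <- retrain_top_k(table, ranking, k = 4)
  expect_s3_class(m4, "trained_model")
  expect_length(m4$selected_features, 4)
  expect_identical(m4$selected_features, ranking$order[1:4])

  m9 <- retrain_top_k(table, ranking, k = 9)
  expect_setequal(m9$selected_features, colnames(d$x))

  # calibration midpoint at decision value zero
  p0 <- calibrated_probability(0, m4$calibration)
  expect_equal(unname(p0), 1 / (1 + exp(m4$calibration[["B"]])))
  # monotone in the decision value
  dseq <- seq(-3, 3, length.out = 25)
  expect_true(all(diff(calibrated_probability(dseq, m4$calibration)) > 0) ||
                all(diff(calibrated_probability(dseq, m4$calibration)) < 0))

  # the planted informative feature survives selection across seeds
  hits <- sapply(1:20, function(seed) {
    d <- planted_data(n = 250, p = 9, delta = 5, seed = seed)
    full <- fit_l1_svm(d$x, d$y)
    "f1" %in% rank_features(full$weights)$order[1:3]
  })
  expect_true(all(hits))
})

test_that("posterior maps lie in [0,1] and separate planted classes", {
  cohort <- small_cohort(seed = 29, n_patients = 8)
  stacks <- lapply(cohort, `[[`, "lesion")
  labels <- as.integer(vapply(cohort, function(e)
    is_positive_grade(e$histopathology), logical(1)))
  table <- make_pixel_table(stacks, labels, pool = "absolute",
                            pixel_cap = 300, seed = 2)
  full <- fit_l1_svm(table$x, table$y)
  model <- retrain_top_k(table, rank_features(full$weights), k = 4)

  meds <- sapply(seq_along(stacks), function(i) {
    pm <- predict_posterior_map(model, stacks[[i]])
    expect_true(all(pm$prob[pm$mask$valid] >= 0 &
                      pm$prob[pm$mask$valid] <= 1))
    expect_true(all(is.na(pm$prob[!pm$mask$valid])))
    median(pm$prob[pm$mask$valid])
  })
  expect_true(all(meds[labels == 1] > 0.5))
  expect_true(all(meds[labels == 0] < 0.5))

  expect_error(predict_posterior_map(model, velscope_stack(stacks[[1]])),
               "missing")
})
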