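# L1-regularized linear SVM with squared-hinge loss
#
#   min_{w, b}  ||w||_1 + C * sum_i max(0, 1 - y_i (x_i' w + b))^2
#
# solved by proximal Newton iterations: at each step the smooth loss is
# replaced by its second-order model over the margin-violating (active)
# pixel set, the resulting L1-penalized quadratic subproblem is solved by
# coordinate descent in the (small) feature dimension, and the Newton
# direction is safeguarded by an Armijo line search on the true objective.
# The intercept is an unpenalized extra coordinate. This glmnet-style
# scheme handles the strongly correlated, nearly separable pixel tables
# this pipeline produces, where plain (proximal) gradient or
# one-coordinate-at-a-time descent zig-zags for thousands of iterations.

`%||%` <- function(a, b) if (is.null(a)) b else a

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

l1svm_objective <- function(x, y, w, b, C) {
  h <- pmax(0, 1 - y * (drop(x %*% w) + b))
  sum(abs(w)) + C * sum(h^2)
}

# Maximal violation of the subgradient optimality conditions:
# |grad_j| <= 1 where w_j = 0, grad_j = -sign(w_j) otherwise, grad_b = 0.
l1svm_kkt_violation <- function(x, y, w, b, C) {
  h <- pmax(0, 1 - y * (drop(x %*% w) + b))
  g <- drop(crossprod(x, -2 * C * y * h))
  max(abs(sum(-2 * C * y * h)),
      max(ifelse(w == 0, pmax(abs(g) - 1, 0), abs(g + sign(w))), 0))
}

# Coordinate descent on the L1-penalized quadratic model
#   q(u) = g'(u - u0) + 0.5 (u - u0)' H (u - u0) + sum_j |u_j|,
# the last (intercept) coordinate unpenalized. Returns the subproblem
# minimizer u.
solve_l1_quadratic <- function(g, H, u0, penalized, max_sweeps = 200L) {
  u <- u0
  Hd <- rep(0, length(u0))          # running H %*% (u - u0)
  for (sweep in seq_len(max_sweeps)) {
    dmax <- 0
    for (j in seq_along(u)) {
      a <- H[j, j]
      cc <- g[j] + Hd[j] - a * (u[j] - u0[j])
      uj <- if (penalized[j]) soft_threshold(u0[j] - cc / a, 1 / a)
            else u0[j] - cc / a
      d <- uj - u[j]
      if (d != 0) {
        Hd <- Hd + H[, j] * d
        u[j] <- uj
        dmax <- max(dmax, abs(d))
      }
    }
    if (dmax < 1e-12) break
  }
  u
}

#' L1-penalized squared-hinge linear SVM solver
#'
#' Minimizes `||w||_1 + C * sum(max(0, 1 - y * (X w + b))^2)` with an
#' unpenalized intercept by proximal Newton iterations (active-set Hessian,
#' inner coordinate-descent lasso subproblem, Armijo backtracking). The L1
#' penalty drives uninformative or redundant coordinates exactly to zero.
#'
#' Callers are expected to standardize columns first (see [fit_l1_svm()]);
#' weight magnitudes are only comparable across features on commensurate
#' scales.
#'
#' @param x Numeric matrix, rows = training pixels, columns = features.
#' @param y Labels in `{-1, +1}` (numeric) or `{0, 1}`/logical.
#' @param C Regularization trade-off (default 1, the sum-form convention of
#'   the standard linear-SVM solvers): larger C weights the data term more
#'   heavily, smaller C increases sparsity.
#' @param max_outer Cap on proximal-Newton iterations.
#' @param tol Convergence tolerance: stop when the maximal violation of the
#'   subgradient optimality conditions falls below `tol` times its initial
#'   (zero-weight) value.
#' @param warm Optional warm start, a list with `weights` and `bias`.
#' @return List with `weights`, `bias`, `objective`, `iterations`,
#'   `converged`, `kkt_violation`, `solver`.
#' @export
l1svm_fit <- function(x, y, C = 1, max_outer = 100L, tol = 1e-6,
                      warm = NULL) {
  stopifnot(is.matrix(x), nrow(x) >= 2)
  y <- as.numeric(y)
  if (all(y %in% c(0, 1))) y <- 2 * y - 1
  if (!all(y %in% c(-1, 1))) stop("labels must be binary")
  if (length(unique(y)) < 2)
    stop("both classes must be present in the training data")
  if (C <= 0) stop("C must be positive")

  n <- nrow(x); p <- ncol(x)
  w <- rep(0, p); b <- 0
  if (!is.null(warm)) {
    stopifnot(length(warm$weights) == p)
    w <- as.numeric(warm$weights)
    b <- as.numeric(warm$bias %||% 0)
  }
  z <- drop(x %*% w) + b
  h <- pmax(0, 1 - y * z)
  kkt <- function(h) {
    g <- drop(crossprod(x, -2 * C * y * h))
    max(abs(sum(-2 * C * y * h)),
        max(ifelse(w == 0, pmax(abs(g) - 1, 0), abs(g + sign(w))), 0))
  }
  # reference scale: violation at the zero solution, independent of warm start
  v0 <- max(abs(drop(crossprod(x, -2 * C * y))), abs(sum(-2 * C * y)), 1)
  converged <- FALSE
  it <- 0L
  sigma <- 0.01                      # Armijo sufficient-decrease constant

  while (it < max_outer) {
    it <- it + 1L
    act <- h > 0
    xa <- x[act, , drop = FALSE]
    ya <- y[act]; ha <- h[act]
    g <- c(drop(crossprod(xa, -2 * C * ya * ha)), -2 * C * sum(ya * ha))
    xa1 <- cbind(xa, 1)
    H <- 2 * C * crossprod(xa1)
    diag(H) <- diag(H) + 1e-8 * max(diag(H), 1) + 1e-10   # damping

    u <- solve_l1_quadratic(g, H, c(w, b),
                            penalized = c(rep(TRUE, p), FALSE))
    dirw <- u[seq_len(p)] - w
    dirb <- u[p + 1L] - b
    if (max(abs(c(dirw, dirb))) < 1e-13) break

    delta <- sum(g * c(dirw, dirb)) + sum(abs(w + dirw)) - sum(abs(w))
    f0 <- sum(abs(w)) + C * sum(h^2)
    dz <- drop(x %*% dirw) + dirb
    lam <- 1
    accepted <- FALSE
    for (ls in seq_len(30L)) {
      zt <- z + lam * dz
      ht <- pmax(0, 1 - y * zt)
      ft <- sum(abs(w + lam * dirw)) + C * sum(ht^2)
      if (ft <= f0 + sigma * lam * delta + 1e-12) {
        w <- w + lam * dirw; b <- b + lam * dirb
        z <- zt; h <- ht
        accepted <- TRUE
        break
      }
      lam <- lam / 2
    }
    if (!accepted) break
    v <- kkt(h)
    if (v <= tol * v0) { converged <- TRUE; break }
  }
  list(weights = w, bias = b,
       objective = sum(abs(w)) + C * sum(h^2),
       iterations = it, converged = converged,
       kkt_violation = kkt(h),
       solver = "prox_newton_l1_squared_hinge")
}

#' Platt-style logistic calibration of decision values
#'
#' Fits the sigmoid `p = 1 / (1 + exp(A * d + B))` mapping classifier
#' decision values `d` to positive-class probabilities, by minimizing the
#' cross-entropy against Platt's regularized targets
#' `(n_pos + 1) / (n_pos + 2)` and `1 / (n_neg + 2)` (which keeps the fit
#' finite on separable data).
#'
#' @param d Numeric vector of decision values.
#' @param y Binary labels (1 = positive).
#' @return Named numeric vector `c(A, B)`.
#' @export
platt_calibrate <- function(d, y) {
  y <- as.numeric(y)
  stopifnot(length(d) == length(y), all(y %in% c(0, 1)))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes required for calibration")
  t <- ifelse(y == 1, (n1 + 1) / (n1 + 2), 1 / (n0 + 2))

  nll <- function(par) {
    z <- par[1] * d + par[2]
    # stable log(1 + exp(z)); cross-entropy of p = sigmoid(-z) against t
    lse <- ifelse(z > 0, z + log1p(exp(-z)), log1p(exp(z)))
    sum(t * lse + (1 - t) * (lse - z))
  }
  grad <- function(par) {
    z <- par[1] * d + par[2]
    r <- 1 / (1 + exp(-z)) - (1 - t)
    c(sum(r * d), sum(r))
  }
  init <- c(0, log((n0 + 1) / (n1 + 1)))
  fit <- stats::optim(init, nll, grad, method = "BFGS",
                      control = list(maxit = 200, reltol = 1e-12))
  c(A = fit$par[1], B = fit$par[2])
}

#' Posterior probability from decision values
#'
#' @param d Decision values.
#' @param calibration Named vector `c(A, B)` from [platt_calibrate()].
#' @return Probabilities in `[0, 1]`.
#' @export
calibrated_probability <- function(d, calibration) {
  1 / (1 + exp(calibration[["A"]] * d + calibration[["B"]]))
}
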