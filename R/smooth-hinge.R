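# Smooth-hinge (softplus / "modified logistic") loss and the penalized
# fitting engine. The hinge loss (1 - y x'b)_+ has a nondifferentiable
# kink, so optimization uses the smooth upper bound
#   L_gamma(b) = (n gamma)^-1 sum log(1 + exp(gamma (1 - y_i x_i' b)))
# which decreases to the hinge loss as gamma -> Inf, with per-term gap
# at most log(2)/gamma.

#' Hinge loss of a linear classifier
#'
#' \eqn{L_H(\beta) = n^{-1} \sum_i (1 - y_i X_i^\top \beta)_+}.
#'
#' @param X design matrix, n x (p+1), first column the intercept (all ones).
#' @param y label vector in \{-1, +1\}.
#' @param beta coefficient vector of length p+1.
#' @return the mean hinge loss (nonnegative scalar).
#' @export
hinge_loss <- function(X, y, beta) {
  check_design(X, y, beta)
  m <- drop(X %*% beta) * y
  mean(pmax(1 - m, 0))
}

#' Smooth (softplus) approximation of the hinge loss
#'
#' \eqn{L_\gamma(\beta) = (n\gamma)^{-1} \sum_i \log(1 + e^{\gamma(1 - y_i X_i^\top \beta)})}.
#' Satisfies \eqn{0 \le L_\gamma - L_H \le \log(2)/\gamma} and converges to
#' [hinge_loss()] as `gamma` grows. Evaluation is overflow-safe for any
#' finite margin.
#'
#' @inheritParams hinge_loss
#' @param gamma smoothness parameter \eqn{\gamma > 0}; larger is closer to
#'   the hinge.
#' @return the smoothed loss (nonnegative scalar).
#' @export
mlr_loss <- function(X, y, beta, gamma) {
  check_design(X, y, beta)
  stopifnot(is.numeric(gamma), length(gamma) == 1L, gamma > 0)
  m <- drop(X %*% beta) * y
  mean(softplus(gamma * (1 - m))) / gamma
}

# gradient of mlr_loss wrt beta
mlr_grad <- function(X, y, beta, gamma) {
  m <- drop(X %*% beta) * y
  s <- stats::plogis(gamma * (1 - m)) # sigmoid, in (0,1)
  -drop(crossprod(X, s * y)) / nrow(X)
}

check_design <- function(X, y, beta = NULL) {
  if (!is.matrix(X) || !is.numeric(X))
    stop("`X` must be a numeric matrix", call. = FALSE)
  if (length(y) != nrow(X))
    stop("length(y) must equal nrow(X)", call. = FALSE)
  if (!all(y %in% c(-1, 1)))
    stop("labels must be coded -1/+1", call. = FALSE)
  if (!is.null(beta) && length(beta) != ncol(X))
    stop("length(beta) must equal ncol(X)", call. = FALSE)
  invisible(TRUE)
}

#' Fitting configuration for the penalized smooth-hinge engine
#'
#' @param gamma final smoothness of the softplus surrogate (default 50).
#' @param gamma_schedule continuation schedule: the fit is solved at each
#'   value in turn, warm-starting the next, ending at `gamma`. Avoids the
#'   flat, ill-conditioned regime of a large `gamma` from a cold start.
#' @param tol relative objective-change tolerance for the outer
#'   (difference-of-convex) loop.
#' @param inner_tol tolerance for the inner proximal-gradient solve.
#' @param max_iter maximum outer iterations.
#' @param inner_max_iter maximum inner proximal-gradient iterations.
#' @param lambda_grid descending \eqn{\lambda} grid for cross-validation;
#'   default \eqn{\{2^0, 2^{-1}, \dots, 2^{-10}\} \times 10^{-3}}.
#' @param tau truncated-lasso knot (default `1e-4`).
#' @param penalize_intercept penalize the intercept? Default `FALSE`.
#' @param support_threshold magnitude above which a coefficient counts as
#'   selected; defaults to `tau` (the truncated lasso is flat beyond
#'   \eqn{\tau}, so any coefficient on the plateau is selected).
#' @return a list of class `fit_config`.
#' @export
fit_config <- function(gamma = 50,
                       gamma_schedule = c(5, 10, 25, 50),
                       tol = 1e-6,
                       inner_tol = 1e-8,
                       max_iter = 500L,
                       inner_max_iter = 2000L,
                       lambda_grid = default_lambda_grid(),
                       tau = 1e-4,
                       penalize_intercept = FALSE,
                       support_threshold = tau) {
  stopifnot(gamma > 0, tol > 0, max_iter >= 1, length(lambda_grid) >= 1,
            all(lambda_grid > 0), tau > 0)
  gamma_schedule <- sort(unique(c(gamma_schedule[gamma_schedule <= gamma], gamma)))
  structure(list(gamma = gamma, gamma_schedule = gamma_schedule, tol = tol,
                 inner_tol = inner_tol, max_iter = as.integer(max_iter),
                 inner_max_iter = as.integer(inner_max_iter),
                 lambda_grid = sort(lambda_grid, decreasing = TRUE),
                 tau = tau, penalize_intercept = penalize_intercept,
                 support_threshold = support_threshold),
            class = "fit_config")
}

#' Default lambda grid
#'
#' The descending grid \eqn{(1, 2^{-1}, \dots, 2^{-10}) \times 10^{-3}}
#' (11 values) used for cross-validated selection of the penalty level.
#' @return a numeric vector of length 11, descending.
#' @export
default_lambda_grid <- function() 2^(-(0:10)) * 1e-3

# FISTA (accelerated proximal gradient with backtracking and restart) for
#   min_b S(b) + sum_j w_j |b_j|
# where S is smooth with gradient `grad`, value `fn`. Weights for the
# intercept are 0. Returns list(beta, value, iters, converged, L).
prox_gradient <- function(fn, grad, beta0, w, tol, max_iter, L0 = 1) {
  beta <- beta0
  z <- beta0
  t_acc <- 1
  L <- L0
  f_beta <- fn(beta)
  obj <- f_beta + sum(w * abs(beta))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    g <- grad(z)
    f_z <- fn(z)
    repeat {
      step <- 1 / L
      cand <- z - step * g
      cand <- sign(cand) * pmax(abs(cand) - step * w, 0)
      d <- cand - z
      f_cand <- fn(cand)
      if (f_cand <= f_z + sum(g * d) + 0.5 * L * sum(d * d) + 1e-12) break
      L <- L * 2
      if (L > 1e12) break
    }
    new_obj <- f_cand + sum(w * abs(cand))
    if (new_obj > obj) { # restart momentum at the last good point
      z <- beta
      t_acc <- 1
      g <- grad(z)
      f_z <- fn(z)
      step <- 1 / L
      cand <- z - step * g
      cand <- sign(cand) * pmax(abs(cand) - step * w, 0)
      new_obj <- fn(cand) + sum(w * abs(cand))
    }
    t_new <- (1 + sqrt(1 + 4 * t_acc^2)) / 2
    z <- cand + ((t_acc - 1) / t_new) * (cand - beta)
    rel <- abs(obj - new_obj) / max(1, abs(obj))
    beta <- cand
    obj <- new_obj
    t_acc <- t_new
    L <- max(L / 1.5, 1e-4) # allow the step to grow again
    if (rel < tol) { converged <- TRUE; break }
  }
  list(beta = beta, value = obj, iters = it, converged = converged, L = L)
}

# Smooth minimization (ridge or unpenalized) with gamma continuation.
# Damped Newton with an analytic Hessian (the objective is smooth and,
# with any ridge, strictly convex); falls back to BFGS if the Newton
# system is ill-conditioned.
fit_ridge_mlr <- function(X, y, lambda, config = fit_config(), beta0 = NULL) {
  p1 <- ncol(X)
  pen_mask <- c(if (config$penalize_intercept) 1 else 0, rep(1, p1 - 1L))
  beta <- beta0 %||% numeric(p1)
  schedule <- if (is.null(beta0)) config$gamma_schedule else config$gamma
  n <- nrow(X)
  Xy <- X * y
  value <- NA_real_
  for (gam in schedule) {
    obj <- function(b) {
      m <- drop(Xy %*% b)
      sum(softplus(gam * (1 - m))) / (n * gam) + lambda * sum(pen_mask * b^2)
    }
    value <- obj(beta)
    for (it in 1:60) {
      m <- drop(Xy %*% beta)
      s <- stats::plogis(gam * (1 - m))
      g <- -drop(crossprod(Xy, s)) / n + 2 * lambda * pen_mask * beta
      if (max(abs(g)) < 1e-9) break
      wgt <- gam * s * (1 - s) / n
      H <- crossprod(X, X * wgt)
      diag(H) <- diag(H) + 2 * lambda * pen_mask + 1e-10
      dir <- tryCatch(-solve(H, g), error = function(e) NULL)
      if (is.null(dir) || !all(is.finite(dir))) { # fall back to BFGS
        opt <- stats::optim(beta, obj,
                            function(b) mlr_grad(X, y, b, gam) +
                              2 * lambda * pen_mask * b,
                            method = "BFGS",
                            control = list(maxit = 200, reltol = config$tol))
        beta <- opt$par
        value <- opt$value
        break
      }
      step <- 1
      repeat { # backtracking line search
        cand <- beta + step * dir
        v <- obj(cand)
        if (is.finite(v) && v <= value + 1e-4 * step * sum(g * dir)) break
        step <- step / 2
        if (step < 1e-10) { cand <- beta; v <- value; break }
      }
      done <- abs(value - v) < config$tol * max(1, abs(value))
      beta <- cand
      value <- v
      if (done) break
    }
  }
  list(beta = beta, value = value, converged = TRUE)
}

#' Fit a penalized smooth-hinge SVM
#'
#' Minimizes \eqn{L_\gamma(\beta) + \sum_{j \ge 1} P_\lambda(|\beta_j|)}
#' (intercept unpenalized by default). Convex penalties (ridge, lasso) are
#' solved directly; nonconvex penalties (tlp, scad, mcp) by a
#' difference-of-convex algorithm: the concave part of the penalty is
#' linearized at the current iterate and each outer step solves the
#' resulting weighted-\eqn{\ell_1} problem by accelerated proximal
#' gradient. The outer objective trace is nonincreasing. Nonconvex fits
#' start from \eqn{\beta = 0}, so the first outer step is a plain
#' lasso-type screen and later steps release the penalty on coordinates
#' that cleared the knot — the standard truncated-lasso strategy.
#'
#' @inheritParams hinge_loss
#' @param penalty a [penalty_spec()].
#' @param config a [fit_config()].
#' @param beta0 optional warm start (length p+1).
#' @return an object of class `tlpsvm_fit`: list with `beta` (named),
#'   `support` (selected non-intercept column names), `objective_trace`,
#'   `lambda_used`, `converged`, `penalty`, `gamma`.
#' @examples
#' set.seed(1)
#' X <- cbind(1, matrix(rnorm(80), 40, 2))
#' colnames(X) <- c("(Intercept)", "a", "b")
#' y <- sign(X[, 2] + 0.25 * rnorm(40))
#' fit <- fit_penalized(X, y, penalty_spec("tlp", lam = 1e-5), fit_config())
#' fit$support
#' @export
fit_penalized <- function(X, y, penalty, config = fit_config(), beta0 = NULL) {
  check_design(X, y)
  stopifnot(inherits(penalty, "penalty_spec"))
  if (length(unique(y)) < 2L)
    stop("both classes must be present to fit", call. = FALSE)
  if (is.null(colnames(X)))
    colnames(X) <- c("(Intercept)", paste0("V", seq_len(ncol(X) - 1L)))
  p1 <- ncol(X)
  pen_mask <- c(if (config$penalize_intercept) 1 else 0, rep(1, p1 - 1L))

  if (penalty$kind == "ridge") {
    res <- fit_ridge_mlr(X, y, penalty$lam, config, beta0)
    beta <- res$beta
    obj <- function(b) mlr_loss(X, y, b, config$gamma) +
      sum(pen_mask * penalty_value(abs(b), penalty))
    trace <- c(obj(beta0 %||% numeric(p1)), obj(beta))
    trace[1] <- max(trace) # cold-start value at final gamma
    return(new_fit(beta, colnames(X), trace, penalty, config, TRUE))
  }

  if (penalty$kind == "lasso") {
    beta <- beta0 %||% numeric(p1)
    w <- pen_mask * penalty$lam
    trace <- numeric(0)
    conv <- TRUE
    L <- 1
    for (gam in config$gamma_schedule) {
      fn <- function(b) mlr_loss(X, y, b, gam)
      gr <- function(b) mlr_grad(X, y, b, gam)
      sol <- prox_gradient(fn, gr, beta, w, config$inner_tol,
                           config$inner_max_iter, L)
      beta <- sol$beta
      L <- sol$L
      conv <- sol$converged
    }
    final_obj <- mlr_loss(X, y, beta, config$gamma) + sum(w * abs(beta))
    trace <- c(mlr_loss(X, y, numeric(p1), config$gamma) +
                 sum(w * abs(numeric(p1))), final_obj)
    return(new_fit(beta, colnames(X), cummin(trace), penalty, config, conv))
  }

  # Nonconvex penalties: DC algorithm with gamma continuation.
  slope <- dc_slope(penalty)
  w <- pen_mask * slope
  pen_obj <- function(b, gam) mlr_loss(X, y, b, gam) +
    sum(pen_mask * penalty_value(abs(b), penalty))

  beta <- beta0 %||% numeric(p1)
  conv <- FALSE
  L <- 1
  trace <- numeric(0)
  for (gam in config$gamma_schedule) {
    last <- gam == config$gamma
    obj_prev <- pen_obj(beta, gam)
    if (last) trace <- obj_prev
    for (outer in seq_len(config$max_iter)) {
      # linearize the concave part: subtract t' b, t_j = h'(|b_j|) sign(b_j)
      hsub <- pen_mask * (slope - penalty_deriv(abs(beta), penalty))
      t_lin <- hsub * sign(beta)
      fn <- function(b) mlr_loss(X, y, b, gam) - sum(t_lin * b)
      gr <- function(b) mlr_grad(X, y, b, gam) - t_lin
      sol <- prox_gradient(fn, gr, beta, w, config$inner_tol,
                           config$inner_max_iter, L)
      beta <- sol$beta
      L <- sol$L
      obj_new <- pen_obj(beta, gam)
      if (last) trace <- c(trace, obj_new)
      done <- abs(obj_prev - obj_new) / max(1, abs(obj_prev)) < config$tol
      obj_prev <- obj_new
      if (done) break
    }
    if (last) conv <- done
  }
  new_fit(beta, colnames(X), cummin(trace), penalty, config, conv)
}

new_fit <- function(beta, names, trace, penalty, config, converged) {
  names(beta) <- names
  structure(list(beta = beta,
                 support = selected_support_beta(beta, config$support_threshold),
                 objective_trace = as.numeric(trace),
                 lambda_used = penalty$lam,
                 penalty = penalty,
                 gamma = config$gamma,
                 converged = isTRUE(converged)),
            class = "tlpsvm_fit")
}

selected_support_beta <- function(beta, threshold) {
  b <- beta[-1L]
  names(b)[abs(b) > threshold]
}

#' Selected variables of a fit
#'
#' Non-intercept coefficients with \eqn{|\beta_j|} above a threshold.
#' The default threshold is the truncated-lasso knot \eqn{\tau}: the
#' penalty is flat beyond \eqn{\tau}, so coefficients past it sit on the
#' plateau and count as selected.
#'
#' @param fit a `tlpsvm_fit` from [fit_penalized()].
#' @param threshold selection magnitude cutoff (default the fit's `tau`).
#' @return character vector of selected column names.
#' @export
selected_support <- function(fit, threshold = fit$penalty$tau) {
  stopifnot(inherits(fit, "tlpsvm_fit"))
  if (is.na(threshold)) threshold <- 0
  selected_support_beta(fit$beta, threshold)
}

#' @export
print.tlpsvm_fit <- function(x, ...) {
  cat(sprintf("<tlpsvm_fit: %s penalty, lambda = %g, %d/%d variables selected, %s>\n",
              x$penalty$kind, x$lambda_used, length(x$support),
              length(x$beta) - 1L,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Select the penalty level by leave-one-out cross-validation
#'
#' For each \eqn{\lambda} in the (descending) grid, computes the
#' leave-one-out classification accuracy of the penalized smooth-hinge fit
#' and returns the accuracy-maximizing \eqn{\lambda}; ties are broken
#' toward the larger \eqn{\lambda} (the sparser model). Within each fold
#' the grid is traversed from the largest \eqn{\lambda} down with warm
#' starts.
#'
#' @inheritParams hinge_loss
#' @param penalty_kind penalty family (`"tlp"`, `"lasso"`, `"scad"`,
#'   `"mcp"`, `"ridge"`).
#' @param config a [fit_config()]; supplies the grid and `tau`.
#' @return list with `lambda_used`, `cv_curve` (named accuracy per
#'   \eqn{\lambda}, grid order), and `grid`.
#' @export
select_lambda_cv <- function(X, y, penalty_kind = "tlp", config = fit_config()) {
  check_design(X, y)
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 subjects for leave-one-out CV", call. = FALSE)
  grid <- config$lambda_grid
  correct <- matrix(0, n, length(grid))
  for (i in seq_len(n)) {
    b0 <- NULL
    for (k in seq_along(grid)) {
      pen <- penalty_spec(penalty_kind, lam = grid[k], tau = config$tau)
      fit <- fit_penalized(X[-i, , drop = FALSE], y[-i], pen, config, beta0 = b0)
      b0 <- fit$beta
      pred <- sign(sum(X[i, ] * fit$beta))
      if (pred == 0) pred <- 1
      correct[i, k] <- pred == y[i]
    }
  }
  cv_curve <- colMeans(correct)
  names(cv_curve) <- signif(grid, 4)
  best <- which.max(cv_curve) # first max = largest lambda (grid descending)
  list(lambda_used = grid[best], cv_curve = cv_curve, grid = grid)
}
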