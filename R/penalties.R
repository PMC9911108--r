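#' Penalty specification
#'
#' Describes one of the sparsity (or ridge) penalties used by the penalized
#' smooth-hinge fitting engine. Supported kinds:
#'
#' * `lasso`: \eqn{P_\lambda(|\beta|) = \lambda |\beta|}
#' * `ridge`: \eqn{P_\lambda(|\beta|) = \lambda \beta^2}
#' * `scad`: the smoothly clipped absolute deviation penalty with concavity
#'   parameter `a` (> 2); linear up to \eqn{\lambda}, quadratic blend up to
#'   \eqn{a\lambda}, then the constant \eqn{(a+1)\lambda^2/2}.
#' * `mcp`: the minimax concave penalty with `a` (> 1);
#'   \eqn{\lambda|\beta| - \beta^2/(2a)} up to \eqn{a\lambda}, then the
#'   constant \eqn{a\lambda^2/2}.
#' * `tlp`: the truncated lasso penalty
#'   \eqn{P_\lambda(|\beta|) = \lambda \min(|\beta|/\tau, 1)}; bounded by
#'   \eqn{\lambda}, so every coefficient past the knot \eqn{\tau} pays the
#'   same price — a continuous surrogate for the \eqn{\ell_0} penalty.
#'
#' The SCAD constant branch is the continuity-forced \eqn{(a+1)\lambda^2/2}
#' (the quadratic middle branch evaluates to exactly that at
#' \eqn{|\beta| = a\lambda}).
#'
#' @param kind one of `"lasso"`, `"ridge"`, `"scad"`, `"mcp"`, `"tlp"`.
#' @param lam penalty level \eqn{\lambda \ge 0}.
#' @param tau knot \eqn{\tau > 0} of the truncated lasso penalty
#'   (default `1e-4`, the setting used throughout this package).
#' @param a concavity parameter for SCAD (`a > 2`, default 3.7) and MCP
#'   (`a > 1`, default 3).
#' @return an object of class `penalty_spec`.
#' @examples
#' penalty_value(0.5, penalty_spec("tlp", lam = 1, tau = 1e-4))
#' @export
penalty_spec <- function(kind = c("lasso", "ridge", "scad", "mcp", "tlp"),
                         lam, tau = 1e-4, a = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(lam) || length(lam) != 1L || is.na(lam) || lam < 0)
    stop("`lam` must be a single nonnegative number", call. = FALSE)
  if (kind == "tlp") {
    if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau <= 0)
      stop("`tau` must be a single positive number for the tlp penalty",
           call. = FALSE)
  }
  if (is.null(a)) a <- switch(kind, scad = 3.7, mcp = 3, NA_real_)
  if (kind == "scad" && (!is.numeric(a) || a <= 2))
    stop("SCAD requires `a` > 2", call. = FALSE)
  if (kind == "mcp" && (!is.numeric(a) || a <= 1))
    stop("MCP requires `a` > 1", call. = FALSE)
  structure(list(kind = kind, lam = lam, tau = tau, a = a),
            class = "penalty_spec")
}

#' @export
print.penalty_spec <- function(x, ...) {
  extra <- switch(x$kind,
    tlp = sprintf(", tau = %g", x$tau),
    scad = , mcp = sprintf(", a = %g", x$a),
    "")
  cat(sprintf("<penalty_spec: %s, lambda = %g%s>\n", x$kind, x$lam, extra))
  invisible(x)
}

#' Evaluate a penalty at a coefficient magnitude
#'
#' @param beta_abs nonnegative coefficient magnitude(s) \eqn{|\beta|};
#'   vectorized.
#' @param spec a [penalty_spec()].
#' @return the penalty value(s) \eqn{P_\lambda(|\beta|)}.
#' @export
penalty_value <- function(beta_abs, spec) {
  stopifnot(inherits(spec, "penalty_spec"))
  if (any(!is.finite(beta_abs)) || any(beta_abs < 0))
    stop("`beta_abs` must be finite and nonnegative", call. = FALSE)
  lam <- spec$lam
  switch(spec$kind,
    lasso = lam * beta_abs,
    ridge = lam * beta_abs^2,
    tlp = lam * pmin(beta_abs / spec$tau, 1),
    scad = {
      a <- spec$a
      ifelse(beta_abs <= lam, lam * beta_abs,
        ifelse(beta_abs <= a * lam,
          (2 * a * lam * beta_abs - beta_abs^2 - lam^2) / (2 * (a - 1)),
          (a + 1) * lam^2 / 2))
    },
    mcp = {
      a <- spec$a
      ifelse(beta_abs <= a * lam,
        lam * beta_abs - beta_abs^2 / (2 * a),
        a * lam^2 / 2)
    })
}

# Right derivative dP/d|beta| of a penalty; used to build DC linearizations.
penalty_deriv <- function(beta_abs, spec) {
  lam <- spec$lam
  switch(spec$kind,
    lasso = rep(lam, length(beta_abs)),
    ridge = 2 * lam * beta_abs,
    tlp = ifelse(beta_abs < spec$tau, lam / spec$tau, 0),
    scad = {
      a <- spec$a
      ifelse(beta_abs <= lam, lam,
        ifelse(beta_abs <= a * lam, (a * lam - beta_abs) / (a - 1), 0))
    },
    mcp = {
      a <- spec$a
      ifelse(beta_abs <= a * lam, lam - beta_abs / a, 0)
    })
}

# Slope of the convex majorant g in the DC split P = g - h:
# g(|beta|) = dc_slope * |beta|.
dc_slope <- function(spec) {
  switch(spec$kind,
    tlp = spec$lam / spec$tau,
    scad = , mcp = spec$lam,
    stop("difference-of-convex decomposition applies only to tlp, scad and mcp penalties",
         call. = FALSE))
}

#' Difference-of-convex decomposition of a nonconvex penalty
#'
#' Splits a nonconvex penalty into \eqn{P = g - h} with both parts convex in
#' \eqn{|\beta|}: `g` is the steepest linear majorant
#' \eqn{g(|\beta|) = c\,|\beta|} (with \eqn{c = \lambda/\tau} for the
#' truncated lasso and \eqn{c = \lambda} for SCAD/MCP), and
#' \eqn{h = g - P} collects the concave shortfall. The optimizer linearizes
#' `h` at the current iterate, leaving a weighted-\eqn{\ell_1} problem.
#'
#' @param spec a [penalty_spec()] of kind `tlp`, `scad` or `mcp`.
#' @return a list with functions `g(beta_abs)`, `h(beta_abs)` and their
#'   derivatives in \eqn{|\beta|}, `g_sub(beta_abs)`, `h_sub(beta_abs)`
#'   (subgradients at the kinks take the lower value, so `h_sub(0) = 0`).
#' @export
penalty_dc_parts <- function(spec) {
  stopifnot(inherits(spec, "penalty_spec"))
  slope <- dc_slope(spec)
  list(
    g = function(beta_abs) slope * beta_abs,
    h = function(beta_abs) slope * beta_abs - penalty_value(beta_abs, spec),
    g_sub = function(beta_abs) rep(slope, length(beta_abs)),
    h_sub = function(beta_abs) slope - penalty_deriv(beta_abs, spec)
  )
}
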