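# Model-free variable screening. The marginal and pairwise-joint stages
# mirror a model-free nonparametric association screen: a statistic
# sensitive to smooth nonlinear effects, gated at permutation p < 0.05.
# The statistic is pluggable; the default is the R^2 of a
# no-interior-knot B-spline regression of the class indicator on the
# variable (order 4 marginally; order-3 tensor product for pairs, net of
# the better single-variable fit).

# R^2 of regressing y01 on a basis matrix (intercept added), via QR.
basis_r2 <- function(basis, y01) {
  fit <- stats::lm.fit(cbind(1, basis), y01)
  ssr <- sum(fit$residuals^2)
  sst <- sum((y01 - mean(y01))^2)
  if (sst <= 0) return(0)
  max(0, 1 - ssr / sst)
}

marginal_stat_spline <- function(x, y01, order = 4L) {
  lo <- min(x); hi <- max(x)
  if (hi <= lo) return(0) # constant variable carries no information
  basis_r2(bspline_basis(x, lo, hi, order), y01)
}

joint_stat_spline <- function(x1, x2, y01, order = 3L) {
  lo1 <- min(x1); hi1 <- max(x1); lo2 <- min(x2); hi2 <- max(x2)
  if (hi1 <= lo1 || hi2 <= lo2) return(0)
  b1 <- bspline_basis(x1, lo1, hi1, order)
  b2 <- bspline_basis(x2, lo2, hi2, order)
  tens <- matrix(0, length(y01), ncol(b1) * ncol(b2))
  k <- 0L
  for (i in seq_len(ncol(b1))) for (j in seq_len(ncol(b2))) {
    k <- k + 1L
    tens[, k] <- b1[, i] * b2[, j]
  }
  r2_joint <- basis_r2(tens, y01)
  max(0, r2_joint - max(basis_r2(b1, y01), basis_r2(b2, y01)))
}

perm_pvalue <- function(stat_fun, y01, n_perm, seed) {
  obs <- stat_fun(y01)
  perms <- with_preserved_seed(seed, {
    vapply(seq_len(n_perm), function(b) stat_fun(sample(y01)), numeric(1))
  })
  list(statistic = obs,
       p_value = (sum(perms >= obs) + 1) / (n_perm + 1))
}

#' Marginal nonparametric screening
#'
#' For each variable, computes a nonlinear-sensitive association statistic
#' between the variable and the class indicator (default: R² of an
#' order-4, no-interior-knot B-spline regression) on pairwise-complete
#' observations, with a label-permutation p-value
#' \eqn{p = (\#\{stat_b \ge stat\} + 1)/(n_{perm} + 1)}. Variables with
#' `p < alpha` are flagged selected (raw gate by default; set
#' `adjust = "BH"` for a Benjamini-Hochberg gate on adjusted p-values).
#'
#' @param table a [cohort_table()].
#' @param n_perm number of label permutations (default 199).
#' @param seed RNG seed for the permutations.
#' @param alpha selection gate on the p-value (default 0.05).
#' @param adjust `"none"` (raw p gate, default) or `"BH"`.
#' @param min_complete minimum pairwise-complete observations per
#'   variable (default 20); variables below it are skipped with a warning.
#' @param stat_fun optional replacement statistic,
#'   `function(x, y01) -> scalar` (larger = stronger association), making
#'   the screen pluggable.
#' @return a `screening_result`: data frame with `variable`, `statistic`,
#'   `p_value`, `effect_kind = "marginal"`, `selected`, sorted by
#'   p-value.
#' @export
marginal_screen <- function(table, n_perm = 199L, seed = 1L, alpha = 0.05,
                            adjust = c("none", "BH"), min_complete = 20L,
                            stat_fun = NULL) {
  stopifnot(inherits(table, "cohort_table"), n_perm >= 1)
  adjust <- match.arg(adjust)
  y01 <- as.integer(table$y == 1L)
  vars <- colnames(table$x)
  seeds <- child_seeds(seed, length(vars))
  rows <- vector("list", length(vars))
  for (k in seq_along(vars)) {
    v <- vars[k]
    ok <- !is.na(table$x[, v])
    if (sum(ok) < min_complete) {
      warning("variable '", v, "' skipped: only ", sum(ok),
              " complete pairs", call. = FALSE)
      next
    }
    x <- table$x[ok, v]
    yv <- y01[ok]
    f <- if (is.null(stat_fun)) function(yy) marginal_stat_spline(x, yy)
         else function(yy) stat_fun(x, yy)
    if (max(x) <= min(x)) {
      res <- list(statistic = 0, p_value = 1)
    } else {
      res <- perm_pvalue(f, yv, n_perm, seeds[k])
    }
    rows[[k]] <- data.frame(variable = v, statistic = res$statistic,
                            p_value = res$p_value,
                            effect_kind = "marginal",
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(variable = character(0), statistic = numeric(0),
                      p_value = numeric(0), effect_kind = character(0))
  out <- out[order(out$p_value, out$variable), , drop = FALSE]
  gate_p <- if (adjust == "BH") stats::p.adjust(out$p_value, "BH") else out$p_value
  out$selected <- gate_p < alpha
  rownames(out) <- NULL
  class(out) <- c("screening_result", class(out))
  out
}

#' Pairwise joint-effect screening
#'
#' For each variable pair, the statistic is the R² of an order-3
#' tensor-product spline surface minus the larger single-variable R²
#' (the joint signal beyond the best marginal fit), with a permutation
#' p-value as in [marginal_screen()]. Pairs are classified by the
#' marginal results: `joint_T1` if neither member was marginally
#' selected, `joint_T2` if exactly one was; pairs whose members were both
#' marginally selected are excluded. Joint pairs are reported for
#' inspection but are deliberately not fed into downstream model
#' building.
#'
#' @inheritParams marginal_screen
#' @param marginal a `screening_result` from [marginal_screen()].
#' @param pairs optional 2-column character matrix of pairs to test
#'   (default: all eligible pairs).
#' @return a `screening_result` with `variable` (`"a:b"`), `statistic`,
#'   `p_value`, `effect_kind` in `joint_T1`/`joint_T2`, `selected`.
#' @export
joint_screen <- function(table, marginal, n_perm = 199L, seed = 1L,
                         alpha = 0.05, min_complete = 20L, pairs = NULL) {
  stopifnot(inherits(table, "cohort_table"), inherits(marginal, "screening_result"))
  y01 <- as.integer(table$y == 1L)
  sel <- marginal$variable[marginal$selected]
  vars <- intersect(colnames(table$x), marginal$variable)
  if (is.null(pairs)) {
    pairs <- t(utils::combn(vars, 2L))
  }
  keep <- !(pairs[, 1] %in% sel & pairs[, 2] %in% sel)
  pairs <- pairs[keep, , drop = FALSE]
  seeds <- child_seeds(seed, nrow(pairs))
  rows <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    v1 <- pairs[k, 1]; v2 <- pairs[k, 2]
    ok <- !is.na(table$x[, v1]) & !is.na(table$x[, v2])
    if (sum(ok) < min_complete) {
      warning("pair '", v1, ":", v2, "' skipped: only ", sum(ok),
              " complete pairs", call. = FALSE)
      next
    }
    x1 <- table$x[ok, v1]; x2 <- table$x[ok, v2]
    yv <- y01[ok]
    res <- perm_pvalue(function(yy) joint_stat_spline(x1, x2, yy),
                       yv, n_perm, seeds[k])
    kind <- if (!(v1 %in% sel) && !(v2 %in% sel)) "joint_T1" else "joint_T2"
    rows[[k]] <- data.frame(variable = paste0(v1, ":", v2),
                            statistic = res$statistic, p_value = res$p_value,
                            effect_kind = kind, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(variable = character(0), statistic = numeric(0),
                      p_value = numeric(0), effect_kind = character(0))
  out <- out[order(out$p_value, out$variable), , drop = FALSE]
  out$selected <- out$p_value < alpha
  rownames(out) <- NULL
  class(out) <- c("screening_result", class(out))
  out
}

#' Write a screening report as TSV
#'
#' @param result a `screening_result`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_screening_report <- function(result, path) {
  utils::write.table(result, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
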