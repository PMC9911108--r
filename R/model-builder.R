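# Mixed linear / B-spline feature designs and the final ridge
# smooth-hinge SVM, grown by stepwise forward selection under LOO-CV.
#
# Spline encoding: an order-s B-spline basis with NO interior knots on
# the training range of the (standardized) variable — exactly s basis
# columns per variable, a partition of unity on the domain. Out-of-domain
# values are clamped to the boundary rather than extrapolated (B-splines
# vanish outside their knot span).

#' Order-s B-spline basis with no interior knots
#'
#' @param x evaluation points (clamped into `[lo, hi]`).
#' @param lo,hi domain endpoints (`lo < hi`).
#' @param order spline order `s` (polynomial degree `s - 1`); the basis
#'   has exactly `s` columns.
#' @return an `length(x) x order` matrix; rows sum to 1.
#' @export
bspline_basis <- function(x, lo, hi, order) {
  stopifnot(order >= 1, is.finite(lo), is.finite(hi))
  if (hi <= lo)
    stop("degenerate spline domain: lo >= hi", call. = FALSE)
  knots <- c(rep(lo, order), rep(hi, order))
  splines::splineDesign(knots, clamp(x, lo, hi), ord = order)
}

#' Feature map: per-variable encodings of the final model's design
#'
#' @param linear character vector of variables encoded as plain linear
#'   terms.
#' @param spline character vector of variables encoded as B-spline blocks.
#' @param orders integer vector of spline orders (recycled over `spline`),
#'   each in \{2, 3, 4\}.
#' @param domains optional named list of `c(lo, hi)` domains; filled from
#'   training data when the design is built.
#' @return an object of class `feature_map`.
#' @export
feature_map <- function(linear = character(0), spline = character(0),
                        orders = 4L, domains = NULL) {
  stopifnot(all(orders %in% 2:4))
  if (length(intersect(linear, spline)))
    stop("a variable cannot be both linear and spline encoded", call. = FALSE)
  if (!length(linear) && !length(spline))
    stop("feature map must contain at least one variable", call. = FALSE)
  orders <- rep_len(as.integer(orders), length(spline))
  names(orders) <- spline
  structure(list(linear = linear, spline = spline, orders = orders,
                 domains = domains),
            class = "feature_map")
}

fmap_variables <- function(fmap) c(fmap$linear, fmap$spline)

#' @export
print.feature_map <- function(x, ...) {
  cat(sprintf("<feature_map: %d linear (%s); %d spline (%s)>\n",
              length(x$linear), paste(x$linear, collapse = ", "),
              length(x$spline),
              paste(sprintf("%s[s=%d]", x$spline, x$orders), collapse = ", ")))
  invisible(x)
}

#' Build a design matrix from a cohort table and feature map
#'
#' Produces the intercept column, one column per linear variable, and
#' `s` columns per spline variable (order-`s` basis, no interior knots,
#' domain = training `[min, max]` unless supplied in the map). Subjects
#' must already be complete on the mapped variables (see
#' [complete_cases()]).
#'
#' @param table a [cohort_table()] (typically standardized).
#' @param fmap a [feature_map()].
#' @return a design matrix with attribute `"fmap"` carrying the map with
#'   domains filled in.
#' @export
build_design <- function(table, fmap) {
  stopifnot(inherits(table, "cohort_table"), inherits(fmap, "feature_map"))
  vars <- fmap_variables(fmap)
  missing_vars <- setdiff(vars, colnames(table$x))
  if (length(missing_vars))
    stop("variables not in table: ", paste(missing_vars, collapse = ", "),
         call. = FALSE)
  x <- table$x[, vars, drop = FALSE]
  if (anyNA(x))
    stop("design variables contain missing values; apply complete_cases() first",
         call. = FALSE)
  n <- nrow(x)
  cols <- list(`(Intercept)` = rep(1, n))
  for (v in fmap$linear) cols[[v]] <- x[, v]
  domains <- fmap$domains %||% list()
  for (v in fmap$spline) {
    dom <- domains[[v]]
    if (is.null(dom)) dom <- range(x[, v])
    if (dom[2] <= dom[1]) dom <- dom + c(-0.5, 0.5) # constant-column guard
    domains[[v]] <- dom
    s <- fmap$orders[[v]]
    b <- bspline_basis(x[, v], dom[1], dom[2], s)
    colnames(b) <- paste0(v, ".", seq_len(s))
    for (j in seq_len(s)) cols[[colnames(b)[j]]] <- b[, j]
  }
  design <- do.call(cbind, cols)
  fmap$domains <- domains
  attr(design, "fmap") <- fmap
  design
}

#' Fit the final ridge smooth-hinge SVM on a built design
#'
#' Minimizes the smooth-hinge loss plus a ridge penalty
#' \eqn{\lambda |\beta|^2} on the non-intercept coefficients — the
#' classical SVM objective with the margin loss smoothed for
#' optimization.
#'
#' @param design design matrix from [build_design()].
#' @param y labels in \{-1, +1\}.
#' @param ridge_lambda ridge level (default `1e-3`).
#' @param gamma smoothness of the surrogate loss (default 50).
#' @param std optional standardization parameters to store in the model.
#' @param classes length-2 character: names of the -1/+1 classes.
#' @return an object of class `svm_model` with the feature map, domains,
#'   intercept, per-variable linear coefficients and spline coefficient
#'   blocks, and standardization parameters.
#' @export
fit_final_svm <- function(design, y, ridge_lambda = 1e-3, gamma = 50,
                          std = NULL, classes = c("SSNS", "SRNS")) {
  fmap <- attr(design, "fmap")
  if (is.null(fmap))
    stop("`design` must come from build_design()", call. = FALSE)
  check_design(design, y)
  if (length(unique(y)) < 2L)
    stop("both classes must be present to fit", call. = FALSE)
  cfg <- fit_config(gamma = gamma)
  res <- fit_ridge_mlr(design, y, ridge_lambda, cfg)
  beta <- res$beta
  names(beta) <- colnames(design)
  linear_coefs <- beta[fmap$linear]
  spline_coefs <- lapply(fmap$spline, function(v)
    unname(beta[paste0(v, ".", seq_len(fmap$orders[[v]]))]))
  names(spline_coefs) <- fmap$spline
  structure(list(feature_map = fmap,
                 intercept = unname(beta[1]),
                 linear_coefs = as.list(linear_coefs),
                 spline_coefs = spline_coefs,
                 std = std,
                 classes = classes,
                 ridge_lambda = ridge_lambda,
                 gamma = gamma,
                 schema_version = 1L),
            class = "svm_model")
}

#' Train a mixed linear/spline SVM from a cohort table
#'
#' Convenience wrapper: restrict to complete cases on the mapped
#' variables, standardize (parameters stored in the model), build the
#' design and fit.
#'
#' @param table a raw (unstandardized) [cohort_table()].
#' @param fmap a [feature_map()].
#' @inheritParams fit_final_svm
#' @return an `svm_model`.
#' @export
train_svm <- function(table, fmap, ridge_lambda = 1e-3, gamma = 50) {
  cc <- complete_cases(table, fmap_variables(fmap))
  std <- standardize_cohort(cc)
  design <- build_design(std, fmap)
  fit_final_svm(design, std$y, ridge_lambda, gamma,
                std = std$std[fmap_variables(fmap)], classes = std$classes)
}

#' @export
print.svm_model <- function(x, ...) {
  cat(sprintf("<svm_model: intercept %.4f; %d linear + %d spline variables; +1 = %s>\n",
              x$intercept, length(x$linear_coefs), length(x$spline_coefs),
              x$classes[2]))
  invisible(x)
}

#' Predict from a trained SVM model
#'
#' Inputs are standardized with the model's stored parameters, spline
#' variables are evaluated on their stored (training) domains with
#' out-of-domain values clamped, and the decision score is
#' intercept + linear terms + spline-block dot products. The class is
#' `sign(score)` with 0 mapped to +1.
#'
#' @param object an `svm_model`.
#' @param newdata a data frame, named list or named vector of variable
#'   values (one row, or a data frame of several rows).
#' @param ... unused.
#' @return a data frame with `score` and `class` (the class *names*, +1
#'   mapped to `object$classes[2]`), plus numeric `label` in \{-1, +1\}.
#' @export
predict.svm_model <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- as.data.frame(as.list(newdata))
  vars <- fmap_variables(object$feature_map)
  missing_vars <- setdiff(vars, names(newdata))
  if (length(missing_vars))
    stop("missing required variable(s): ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  n <- nrow(newdata)
  score <- rep(object$intercept, n)
  std_of <- function(v, val) {
    p <- object$std[[v]]
    if (is.null(p) || p["sd"] <= 0) val else (val - p[["mean"]]) / p[["sd"]]
  }
  for (v in object$feature_map$linear)
    score <- score + object$linear_coefs[[v]] * std_of(v, newdata[[v]])
  for (v in object$feature_map$spline) {
    dom <- object$feature_map$domains[[v]]
    s <- object$feature_map$orders[[v]]
    b <- bspline_basis(std_of(v, newdata[[v]]), dom[1], dom[2], s)
    score <- score + drop(b %*% object$spline_coefs[[v]])
  }
  label <- ifelse(score >= 0, 1L, -1L)
  data.frame(score = score, label = label,
             class = object$classes[(label + 3L) / 2L],
             stringsAsFactors = FALSE)
}

#' Serialize / deserialize a trained model as JSON
#'
#' Structured JSON text with a schema version, the feature map with
#' domains, standardization parameters and all coefficients; the
#' round-trip is lossless for prediction.
#'
#' @param model an `svm_model`.
#' @param path file path.
#' @return `path` invisibly for write; an `svm_model` for read.
#' @export
write_svm_model <- function(model, path) {
  stopifnot(inherits(model, "svm_model"))
  payload <- list(
    schema_version = model$schema_version,
    classes = model$classes,
    intercept = model$intercept,
    feature_map = list(linear = model$feature_map$linear,
                       spline = model$feature_map$spline,
                       orders = as.list(model$feature_map$orders),
                       domains = model$feature_map$domains),
    linear_coefs = model$linear_coefs,
    spline_coefs = model$spline_coefs,
    std = lapply(model$std, as.list),
    ridge_lambda = model$ridge_lambda,
    gamma = model$gamma)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_svm_model
#' @export
read_svm_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(p$schema_version) || p$schema_version != 1L)
    stop("unsupported model schema version: ", p$schema_version, call. = FALSE)
  fmap <- feature_map(linear = as.character(p$feature_map$linear %||% character(0)),
                      spline = as.character(p$feature_map$spline %||% character(0)),
                      orders = if (length(p$feature_map$orders))
                        unlist(p$feature_map$orders) else 4L,
                      domains = lapply(p$feature_map$domains, as.numeric))
  std <- lapply(p$std, function(s) c(mean = s$mean, sd = s$sd))
  structure(list(feature_map = fmap, intercept = p$intercept,
                 linear_coefs = as.list(p$linear_coefs),
                 spline_coefs = lapply(p$spline_coefs, as.numeric),
                 std = std, classes = as.character(p$classes),
                 ridge_lambda = p$ridge_lambda, gamma = p$gamma,
                 schema_version = 1L),
            class = "svm_model")
}

#' Stepwise forward model building under LOO-CV
#'
#' Greedy growth of the final SVM: at each step, the candidate whose
#' addition maximizes leave-one-out accuracy joins the model; ties are
#' broken by candidate order; the search stops when no addition improves
#' accuracy or `max_vars` is reached. Correlated near-duplicates of
#' variables already in the model improve LOO accuracy little, so the
#' greedy path prunes them naturally.
#'
#' @param table a raw [cohort_table()].
#' @param candidates ordered character vector of candidate variables.
#' @param encodings named character vector (`"linear"` or `"spline"`) per
#'   candidate; unnamed candidates default to linear.
#' @param max_vars maximum model size.
#' @param orders named integer vector of spline orders (default 4).
#' @param ridge_lambda,gamma passed to the fitting engine.
#' @return list with `model` (an `svm_model` trained on the final
#'   selection), `selected`, and `trace` (data frame of step, variable
#'   added, LOO accuracy).
#' @export
stepwise_forward <- function(table, candidates, encodings = NULL,
                             max_vars = 8L, orders = NULL,
                             ridge_lambda = 1e-3, gamma = 50) {
  stopifnot(inherits(table, "cohort_table"), length(candidates) >= 1)
  if (is.null(encodings)) encodings <- stats::setNames(
    rep("linear", length(candidates)), candidates)
  enc_of <- function(v) {
    e <- encodings[[v]] %||% "linear"
    if (is.na(e)) "linear" else e
  }
  ord_of <- function(v) {
    o <- if (!is.null(orders)) orders[[v]] else NULL
    as.integer(o %||% 4L)
  }
  make_fmap <- function(vars) {
    lin <- vars[vapply(vars, enc_of, "") == "linear"]
    spl <- setdiff(vars, lin)
    feature_map(linear = lin, spline = spl,
                orders = if (length(spl)) vapply(spl, ord_of, 1L) else 4L)
  }
  selected <- character(0)
  best_acc <- -Inf
  trace <- list()
  repeat {
    remaining <- setdiff(candidates, selected)
    if (!length(remaining) || length(selected) >= max_vars) break
    accs <- vapply(remaining, function(v) {
      loo_cv(table, make_fmap(c(selected, v)),
             ridge_lambda = ridge_lambda, gamma = gamma)$accuracy
    }, numeric(1))
    step_best <- which.max(accs) # first max: candidate order breaks ties
    if (accs[step_best] <= best_acc) break
    selected <- c(selected, remaining[step_best])
    best_acc <- accs[step_best]
    trace[[length(trace) + 1L]] <- data.frame(
      step = length(selected), variable = remaining[step_best],
      loo_accuracy = best_acc, stringsAsFactors = FALSE)
  }
  model <- train_svm(table, make_fmap(selected), ridge_lambda, gamma)
  list(model = model, selected = selected, trace = do.call(rbind, trace))
}

#' Select a spline order under overfitting control
#'
#' Among candidate orders, fits the single-variable spline SVM, computes
#' its LOO accuracy and its overfitting-test p-value, and returns the
#' accuracy-maximizing order among those passing the overfit gate
#' (`p <= overfit_alpha`); ties resolve to the smaller order. If no order
#' passes the gate the variable is considered unstable and
#' `NA_integer_` is returned.
#'
#' @param table a raw [cohort_table()].
#' @param variable variable name.
#' @param orders candidate orders (default `2:4`).
#' @param overfit_alpha gate on the overfit-test p-value (default 0.05).
#' @param B permutations for the overfit test (default 99).
#' @param seed RNG seed for the permutation test.
#' @inheritParams stepwise_forward
#' @return the chosen order (integer) or `NA_integer_`; the per-order
#'   trace is in attribute `"trace"`.
#' @export
select_spline_order <- function(table, variable, orders = 2:4,
                                overfit_alpha = 0.05, B = 99L, seed = 1L,
                                ridge_lambda = 1e-3, gamma = 50) {
  stopifnot(all(orders %in% 2:4))
  rows <- lapply(orders, function(s) {
    fmap <- feature_map(spline = variable, orders = s)
    ot <- overfit_test(table, fmap, B = B, seed = seed,
                       ridge_lambda = ridge_lambda, gamma = gamma)
    data.frame(order = s, loo_accuracy = ot$t0, overfit_p = ot$p_value)
  })
  trace <- do.call(rbind, rows)
  ok <- trace$overfit_p <= overfit_alpha
  out <- if (!any(ok)) NA_integer_ else {
    cand <- trace[ok, ]
    as.integer(cand$order[which.max(cand$loo_accuracy)]) # orders ascending: ties -> smaller
  }
  attr(out, "trace") <- trace
  out
}

#' Pearson correlation matrix of selected variables
#'
#' Pairwise-complete Pearson correlations; constant columns get
#' correlation 0 by convention (with a warning). Optionally renders a
#' heatmap to file (requires the pheatmap package).
#'
#' @param table a [cohort_table()].
#' @param variables at least two variable names.
#' @param file optional PNG path for a heatmap rendering.
#' @return symmetric correlation matrix.
#' @export
correlation_matrix <- function(table, variables, file = NULL) {
  stopifnot(inherits(table, "cohort_table"), length(variables) >= 2)
  x <- table$x[, variables, drop = FALSE]
  cm <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
  if (anyNA(cm)) {
    warning("constant column(s); correlations set to 0 by convention",
            call. = FALSE)
    cm[is.na(cm)] <- 0
    diag(cm) <- 1
  }
  if (!is.null(file)) {
    if (requireNamespace("pheatmap", quietly = TRUE)) {
      grDevices::png(file, width = 900, height = 800)
      pheatmap::pheatmap(cm, cluster_rows = TRUE, cluster_cols = TRUE)
      grDevices::dev.off()
    } else {
      warning("pheatmap not installed; heatmap not written", call. = FALSE)
    }
  }
  cm
}
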