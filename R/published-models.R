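# The coefficient vectors of the published SRNS prediction models are
# shipped as read-only JSON fixtures for formula-evaluation tests. They
# are NOT usable as clinical predictors from this package: the
# standardization constants and spline domains behind them were never
# published, so only the linear part (or explicitly supplied spline
# basis contributions) can be evaluated.

#' Published model coefficient fixtures
#'
#' Loads the published 5-variable linear model (`"linear"`) or the
#' reduced 8-variable linear + spline model (`"reduced"`) shipped with
#' the package.
#'
#' @param which `"linear"` or `"reduced"`.
#' @return a list with `intercept`, `linear_coefs`, and (reduced only)
#'   `spline_coefs` (length-4 blocks) and `spline_order`.
#' @export
published_model <- function(which = c("linear", "reduced")) {
  which <- match.arg(which)
  path <- system.file("extdata",
                      paste0("published_", which, "_model.json"),
                      package = "tlpsvm", mustWork = TRUE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Evaluate a published model fixture
#'
#' Computes `intercept + sum(linear_coefs * values)` plus, optionally,
#' explicitly supplied spline-block contributions
#' `sum(basis %*% spline_coefs)`. Inputs are on the authors'
#' standardized scale (mean 0, variance 1); unsupplied linear variables
#' default to 0 (the standardized mean). Because the published spline
#' domains are unavailable, spline blocks are zeroed unless their basis
#' rows are given in `spline_basis`.
#'
#' @param model a fixture from [published_model()].
#' @param values named numeric vector of standardized linear-variable
#'   values (defaults to all zero).
#' @param spline_basis optional named list: per spline variable, a
#'   length-4 basis row to dot with the published coefficient block.
#' @return list with `score` and `class` (`"SRNS"` if score >= 0 else
#'   `"SSNS"`).
#' @examples
#' published_model_score(published_model("linear"))$score # 0.2527
#' @export
published_model_score <- function(model, values = numeric(0),
                                  spline_basis = NULL) {
  unknown <- setdiff(names(values), names(model$linear_coefs))
  if (length(unknown))
    stop("not a linear variable of this model: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  score <- model$intercept
  for (v in names(model$linear_coefs)) {
    xv <- if (v %in% names(values)) values[[v]] else 0
    score <- score + model$linear_coefs[[v]] * xv
  }
  for (v in names(spline_basis)) {
    if (is.null(model$spline_coefs[[v]]))
      stop("no published spline block for '", v, "'", call. = FALSE)
    score <- score + sum(spline_basis[[v]] * model$spline_coefs[[v]])
  }
  list(score = score, class = if (score >= 0) "SRNS" else "SSNS")
}
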