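# End-to-end pipeline: preprocessing -> penalized-SVM linear selection ->
# nonparametric screening -> encoding assignment -> stepwise forward
# model building -> LOO-CV validation, ROC and the overfitting test.

#' Pipeline configuration
#'
#' Defaults are the settings used throughout the package:
#' \eqn{\tau = 10^{-4}}, \eqn{\lambda} grid
#' \eqn{(1, 2^{-1}, \dots, 2^{-10}) \times 10^{-3}}, screening gate
#' \eqn{\alpha = 0.05}, overfit-test permutations `B = 200`.
#'
#' @param label_column,positive_class CSV ingestion settings.
#' @param max_missing_rate variables with a larger missing fraction are
#'   dropped (default 0.5).
#' @param tau truncated-lasso knot.
#' @param lambda_grid descending grid for cross-validated \eqn{\lambda}.
#' @param lambda fixed \eqn{\lambda}; `NULL` (default) selects it by
#'   leave-one-out cross-validation over `lambda_grid`.
#' @param penalty_kind penalty for the selection stage (default `"tlp"`).
#' @param screen_n_perm screening permutations (default 199).
#' @param alpha screening selection gate (default 0.05).
#' @param screen_joint also run the pairwise joint screen? Reported only;
#'   joint pairs never enter the final model (default `FALSE`).
#' @param orders candidate spline orders (default `2:4`).
#' @param order_B permutations for the per-variable overfit gate in
#'   spline-order selection (default 49).
#' @param max_vars stepwise model size cap (default 8).
#' @param ridge_lambda ridge level of the final SVM (default `1e-3`).
#' @param gamma smoothness of the surrogate loss (default 50).
#' @param B overfit-test permutations for the final model (default 200).
#' @param seed master seed; all stage seeds derive from it.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(label_column = "class", positive_class = "SRNS",
                            max_missing_rate = 0.5,
                            tau = 1e-4, lambda_grid = default_lambda_grid(),
                            lambda = NULL, penalty_kind = "tlp",
                            screen_n_perm = 199L, alpha = 0.05,
                            screen_joint = FALSE,
                            orders = 2:4, order_B = 49L,
                            max_vars = 8L, ridge_lambda = 1e-3, gamma = 50,
                            B = 200L, seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full variable-selection and model-building pipeline
#'
#' Stages: load (if `input` is a path) -> drop high-missingness
#' variables -> standardize -> penalized smooth-hinge (linear-effect)
#' selection -> nonparametric marginal screening (nonlinear effects;
#' joint pairs reported only) -> encoding assignment (linear for
#' SVM-selected variables — this wins when a variable is chosen by both
#' stages — spline with a selected order for screening-only variables)
#' -> stepwise forward building under LOO-CV -> final validation
#' (metrics, ROC/AUC) and the permutation overfitting test. Deterministic
#' given `config$seed`.
#'
#' @param input a CSV path (see [load_cohort()]) or a [cohort_table()].
#' @param config a [pipeline_config()].
#' @param out_dir optional directory for reports (model JSON, screening
#'   and validation TSVs, correlation heatmap).
#' @return a list bundle: `table`, `svm_selection` (fit, lambda, support,
#'   cv_curve), `screening` (+ `screening_joint` if requested),
#'   `encodings`, `candidates`, `stepwise` (model, selected, trace),
#'   `cv`, `metrics`, `roc`, `overfit`, `config`.
#' @export
run_pipeline <- function(input, config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  table <- if (inherits(input, "cohort_table")) input
           else load_cohort(input, config$label_column, config$positive_class)
  seeds <- child_seeds(config$seed, 4L)

  table <- drop_high_missing(table, config$max_missing_rate)
  std <- standardize_cohort(table)

  # -- linear-effect selection: penalized smooth-hinge SVM ---------------
  cc <- complete_cases(std, colnames(std$x))
  X <- cbind(`(Intercept)` = 1, cc$x)
  fc <- fit_config(gamma = config$gamma, lambda_grid = config$lambda_grid,
                   tau = config$tau)
  cv_curve <- NULL
  lam <- config$lambda
  if (is.null(lam)) {
    sel <- select_lambda_cv(X, cc$y, config$penalty_kind, fc)
    lam <- sel$lambda_used
    cv_curve <- sel$cv_curve
  }
  fit <- fit_penalized(X, cc$y,
                       penalty_spec(config$penalty_kind, lam = lam,
                                    tau = config$tau), fc)
  svm_vars <- fit$support
  message("penalized SVM stage selected ", length(svm_vars), " variable(s)")

  # -- nonlinear-effect screening ---------------------------------------
  screen <- marginal_screen(std, n_perm = config$screen_n_perm,
                            seed = seeds[1], alpha = config$alpha)
  screen_vars <- screen$variable[screen$selected]
  screen_joint <- NULL
  if (isTRUE(config$screen_joint))
    screen_joint <- joint_screen(std, screen, n_perm = config$screen_n_perm,
                                 seed = seeds[2], alpha = config$alpha)
  message("screening stage selected ", length(screen_vars), " variable(s)")

  # -- encodings: linear wins for SVM-selected; spline otherwise --------
  spline_only <- setdiff(screen_vars, svm_vars)
  encodings <- c(stats::setNames(rep("linear", length(svm_vars)), svm_vars),
                 stats::setNames(rep("spline", length(spline_only)), spline_only))
  orders <- integer(0)
  kept_spline <- character(0)
  for (v in spline_only) {
    s <- select_spline_order(table, v, orders = config$orders,
                             B = config$order_B, seed = seeds[3],
                             ridge_lambda = config$ridge_lambda,
                             gamma = config$gamma)
    if (is.na(s)) {
      message("variable '", v, "': no spline order passed the overfit gate; dropped")
    } else {
      orders[v] <- s
      kept_spline <- c(kept_spline, v)
    }
  }
  encodings <- encodings[c(svm_vars, kept_spline)]

  # candidate order: SVM picks by |coefficient|, then screened by p-value
  svm_order <- svm_vars[order(-abs(fit$beta[svm_vars]))]
  screen_order <- screen$variable[screen$selected]
  screen_order <- screen_order[screen_order %in% kept_spline]
  candidates <- c(svm_order, screen_order)
  if (!length(candidates))
    stop("pipeline stage 'selection': no variable survived either stage",
         call. = FALSE)

  # -- stepwise forward build + validation ------------------------------
  sw <- stepwise_forward(table, candidates, encodings,
                         max_vars = config$max_vars, orders = orders,
                         ridge_lambda = config$ridge_lambda,
                         gamma = config$gamma)
  final_fmap <- sw$model$feature_map
  cv <- loo_cv(table, final_fmap, config$ridge_lambda, config$gamma)
  mets <- metrics(cv$cm)
  roc <- roc_auc(cv$scores, cv$y)
  overfit <- overfit_test(table, final_fmap, B = config$B, seed = seeds[4],
                          ridge_lambda = config$ridge_lambda,
                          gamma = config$gamma)

  bundle <- list(table = table, svm_selection = list(fit = fit, lambda = lam,
                                                     support = svm_vars,
                                                     cv_curve = cv_curve),
                 screening = screen, screening_joint = screen_joint,
                 encodings = encodings, candidates = candidates,
                 stepwise = sw, cv = cv, metrics = mets, roc = roc,
                 overfit = overfit, config = config)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_svm_model(sw$model, file.path(out_dir, "model.json"))
    write_screening_report(screen, file.path(out_dir, "screening.tsv"))
    if (!is.null(screen_joint))
      write_screening_report(screen_joint, file.path(out_dir, "screening_joint.tsv"))
    write_validation_report(cv, file.path(out_dir, "validation.tsv"), overfit)
    if (length(sw$selected) >= 2)
      correlation_matrix(table, sw$selected,
                         file = file.path(out_dir, "correlation_heatmap.png"))
  }
  bundle
}
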