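# Leave-one-out cross-validation, classification metrics, ROC/AUC and
# the permutation test for overfitting.
#
# LOO-CV refits everything inside each fold: standardization parameters
# and spline domains are re-estimated on the n-1 training subjects, so
# nothing leaks from the held-out subject. Because the design depends on
# the features only, the per-fold designs can be prebuilt once and reused
# across the label permutations of the overfitting test.

# Prebuild the n leave-one-out fold designs (plus the full-data design
# used for warm starts). Operates on complete cases of the mapped
# variables.
loo_designs <- function(table, fmap) {
  cc <- complete_cases(table, fmap_variables(fmap))
  n <- nrow(cc$x)
  if (n < 3L) stop("need at least 3 complete subjects for LOO-CV", call. = FALSE)
  full_std <- standardize_cohort(cc)
  full_design <- build_design(full_std, fmap)
  folds <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- subset_cohort(cc, setdiff(seq_len(n), i))
    std <- standardize_cohort(tr)
    design <- build_design(std, fmap)
    te <- standardize_cohort(subset_cohort(cc, i), params = std$std)
    fm_i <- attr(design, "fmap") # carries this fold's domains
    te_design <- build_design(te, fm_i)
    folds[[i]] <- list(X = design, x_new = te_design[1, ])
  }
  list(folds = folds, y = cc$y, n = n, full_design = full_design,
       table = cc)
}

# Evaluate LOO accuracy for a label vector on prebuilt fold designs.
loo_eval <- function(designs, y, ridge_lambda, gamma) {
  n <- designs$n
  cfg <- fit_config(gamma = gamma)
  warm <- tryCatch(
    fit_ridge_mlr(designs$full_design, y, ridge_lambda, cfg)$beta,
    error = function(e) NULL)
  scores <- numeric(n)
  pred <- integer(n)
  for (i in seq_len(n)) {
    ytr <- y[-i]
    if (length(unique(ytr)) < 2L) {
      warning("fold ", i, " has a single class; majority-class prediction used",
              call. = FALSE)
      maj <- if (sum(ytr == 1L) >= sum(ytr == -1L)) 1L else -1L
      pred[i] <- maj
      scores[i] <- maj * Inf
      next
    }
    fit <- fit_ridge_mlr(designs$folds[[i]]$X, ytr, ridge_lambda, cfg,
                         beta0 = warm)
    s <- sum(designs$folds[[i]]$x_new * fit$beta)
    scores[i] <- s
    pred[i] <- if (s >= 0) 1L else -1L
  }
  list(accuracy = mean(pred == y), scores = scores, pred = pred)
}

#' Leave-one-out cross-validation of a mixed linear/spline SVM
#'
#' For each subject: standardize and refit on the remaining subjects
#' (standardization and spline domains re-estimated inside the fold),
#' predict the held-out subject. Exactly n fits are performed. Folds
#' whose training labels collapse to one class fall back to
#' majority-class prediction with a warning.
#'
#' @param table a raw [cohort_table()].
#' @param fmap a [feature_map()] describing the model.
#' @param ridge_lambda ridge level of the final SVM (default `1e-3`).
#' @param gamma smoothness of the surrogate loss (default 50).
#' @return list with `accuracy`, `cm` (a `confusion_matrix`), `scores`
#'   (per-subject out-of-fold decision scores), `pred`, `y`, `n_fits`.
#' @export
loo_cv <- function(table, fmap, ridge_lambda = 1e-3, gamma = 50) {
  designs <- loo_designs(table, fmap)
  ev <- loo_eval(designs, designs$y, ridge_lambda, gamma)
  list(accuracy = ev$accuracy,
       cm = confusion_matrix(designs$y, ev$pred),
       scores = ev$scores, pred = ev$pred, y = designs$y,
       n_fits = designs$n)
}

#' Confusion matrix for \{-1, +1\} labels
#'
#' @param truth true labels in \{-1, +1\} (+1 = positive class).
#' @param pred predicted labels in \{-1, +1\}.
#' @param tp,fn,fp,tn alternatively, the four counts directly.
#' @return an object of class `confusion_matrix`: list with `tp`, `fn`,
#'   `fp`, `tn`.
#' @export
confusion_matrix <- function(truth = NULL, pred = NULL,
                             tp = NULL, fn = NULL, fp = NULL, tn = NULL) {
  if (is.null(tp)) {
    stopifnot(length(truth) == length(pred),
              all(truth %in% c(-1, 1)), all(pred %in% c(-1, 1)))
    tp <- sum(truth == 1 & pred == 1)
    fn <- sum(truth == 1 & pred == -1)
    fp <- sum(truth == -1 & pred == 1)
    tn <- sum(truth == -1 & pred == -1)
  }
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion matrix counts must be nonnegative integers", call. = FALSE)
  structure(as.list(counts), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix: TP=%d FN=%d FP=%d TN=%d>\n",
              x$tp, x$fn, x$fp, x$tn))
  invisible(x)
}

#' Classification performance metrics
#'
#' Sensitivity `SN = TP/(TP+FN)`, specificity `SP = TN/(TN+FP)`,
#' `Precision = TP/(TP+FP)`, accuracy `ACC = (TP+TN)/n`, and the Matthews
#' correlation coefficient
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, with
#' `MCC = 0` when any factor of the denominator is zero.
#'
#' @param cm a [confusion_matrix()].
#' @return named list with `SN`, `SP`, `Precision`, `ACC`, `MCC` (all
#'   proportions except MCC, which lies in \[-1, 1\]).
#' @export
metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  tp <- cm$tp; fn <- cm$fn; fp <- cm$fp; tn <- cm$tn
  n <- tp + fn + fp + tn
  if (n == 0) stop("empty confusion matrix", call. = FALSE)
  safe_div <- function(a, b) if (b == 0) NA_real_ else a / b
  den <- prod(sqrt(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  list(SN = safe_div(tp, tp + fn),
       SP = safe_div(tn, tn + fp),
       Precision = safe_div(tp, tp + fp),
       ACC = (tp + tn) / n,
       MCC = if (den == 0) 0 else (tp * tn - fp * fn) / den)
}

#' ROC curve and AUC
#'
#' AUC by the rank (Mann-Whitney) formulation — the probability that a
#' random positive scores above a random negative, ties counting one
#' half. ROC points are computed at every distinct score threshold.
#'
#' @param scores real-valued decision scores (larger = more positive).
#' @param labels labels in \{-1, +1\}.
#' @return list with `roc` (data frame of `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(-1, 1)))
  pos <- labels == 1
  if (!any(pos) || all(pos))
    stop("both classes must be present", call. = FALSE)
  r <- rank(scores) # average ranks: ties contribute 1/2
  auc <- (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) /
    (sum(pos) * sum(!pos))
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  roc <- data.frame(
    threshold = thr,
    tpr = vapply(thr, function(t) mean(scores[pos] >= t), numeric(1)),
    fpr = vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1)))
  list(roc = roc, auc = auc)
}

#' Permutation test for model overfitting
#'
#' Tests the null hypothesis that the model is overfitted — i.e. that its
#' accuracy in predicting the true labels is no better than its accuracy
#' in predicting an independent random relabeling. `T0` is the LOO-CV
#' accuracy on the true labels; for b = 1..B the labels are permuted
#' (without replacement, preserving class balance) and the LOO-CV
#' accuracy `Tb` is recomputed with the identical estimator. The p-value
#' is \eqn{p = (\sum_b 1\{T_b > T_0\} + 1)/(B + 1)} (strict inequality:
#' ties favor significance); `p < 0.05` rejects overfitting. Per-replicate
#' seeds are pre-drawn, so replicates are order-independent.
#'
#' @inheritParams loo_cv
#' @param B number of label permutations (default 200).
#' @param seed RNG seed.
#' @return an `overfit_test_result`: list with `t0`, `t_perm` (length B),
#'   `B`, `p_value`, `seed`.
#' @export
overfit_test <- function(table, fmap, B = 200L, seed = 1L,
                         ridge_lambda = 1e-3, gamma = 50) {
  stopifnot(B >= 19)
  designs <- loo_designs(table, fmap)
  t0 <- loo_eval(designs, designs$y, ridge_lambda, gamma)$accuracy
  seeds <- child_seeds(seed, B)
  t_perm <- vapply(seq_len(B), function(b) {
    yb <- with_preserved_seed(seeds[b], sample(designs$y))
    loo_eval(designs, yb, ridge_lambda, gamma)$accuracy
  }, numeric(1))
  structure(list(t0 = t0, t_perm = t_perm, B = as.integer(B),
                 p_value = (sum(t_perm > t0) + 1) / (B + 1),
                 seed = seed),
            class = "overfit_test_result")
}

#' @export
print.overfit_test_result <- function(x, ...) {
  cat(sprintf("<overfit test: T0 = %.3f; B = %d permutations, Tb in [%.3f, %.3f]; p = %.4g>\n",
              x$t0, x$B, min(x$t_perm), max(x$t_perm), x$p_value))
  invisible(x)
}

#' Write a validation report
#'
#' TSV of the metrics plus a short human-readable summary alongside.
#'
#' @param cv a [loo_cv()] result.
#' @param path base output path (TSV written at `path`).
#' @param overfit optional [overfit_test()] result to include.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(cv, path, overfit = NULL) {
  m <- metrics(cv$cm)
  auc <- roc_auc(cv$scores, cv$y)$auc
  df <- data.frame(
    measure = c("LOO_accuracy", "TP", "FN", "FP", "TN", "SN", "SP",
                "Precision", "ACC", "MCC", "AUC",
                if (!is.null(overfit)) c("overfit_p", "overfit_B")),
    value = c(cv$accuracy, cv$cm$tp, cv$cm$fn, cv$cm$fp, cv$cm$tn,
              m$SN, m$SP, m$Precision, m$ACC, m$MCC, auc,
              if (!is.null(overfit)) c(overfit$p_value, overfit$B)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
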