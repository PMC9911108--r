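test_that("metric formulas match hand-computed confusion matrices", {
  # 20 positives / 30 negatives with SN 0.90, SP 29/30
  cm <- confusion_matrix(tp = 18, fn = 2, fp = 1, tn = 29)
  m <- metrics(cm)
  expect_equal(m$ACC, 47 / 50)
  expect_equal(m$SN, 0.9)
  expect_equal(m$SP, 29 / 30)
  expect_equal(m$Precision, 18 / 19)
  perfect <- metrics(confusion_matrix(tp = 10, fn = 0, fp = 0, tn = 10))
  expect_equal(perfect$MCC, 1)
  expect_equal(perfect$ACC, 1)
  balanced <- metrics(confusion_matrix(tp = 5, fn = 5, fp = 5, tn = 5))
  expect_equal(balanced$MCC, 0)
  # degenerate denominator factor -> MCC 0 by convention
  expect_equal(metrics(confusion_matrix(tp = 5, fn = 0, fp = 5, tn = 0))$MCC, 0)
  expect_error(metrics(confusion_matrix(tp = 0, fn = 0, fp = 0, tn = 0)),
               "empty")
  expect_error(confusion_matrix(tp = -1, fn = 0, fp = 0, tn = 0), "nonnegative")
})

test_that("confusion matrices built from labels count correctly", {
  truth <- c(1, 1, 1, -1, -1)
  pred <- c(1, -1, 1, -1, 1)
  cm <- confusion_matrix(truth, pred)
  expect_equal(unlist(cm), c(tp = 2, fn = 1, fp = 1, tn = 1))
  m <- metrics(cm)
  expect_true(all(unlist(m[c("SN", "SP", "Precision", "ACC")]) >= 0))
  expect_true(m$MCC >= -1 && m$MCC <= 1)
})

test_that("AUC follows the rank formulation and matches brute-force pair counting", {
  expect_equal(roc_auc(1:10, c(rep(-1, 5), rep(1, 5)))$auc, 1)
  expect_equal(roc_auc(10:1, c(rep(-1, 5), rep(1, 5)))$auc, 0)
  expect_equal(roc_auc(rep(0.3, 10), rep(c(-1, 1), 5))$auc, 0.5)
  set.seed(13)
  for (r in 1:5) {
    scores <- round(rnorm(30), 1) # coarse scores force ties
    labels <- sample(c(-1, 1), 30, replace = TRUE, prob = c(0.6, 0.4))
    if (length(unique(labels)) < 2) next
    expect_equal(roc_auc(scores, labels)$auc,
                 auc_bruteforce(scores, labels), tolerance = 1e-12)
  }
  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(29)
  scores <- rnorm(50)
  labels <- sign(scores + rnorm(50))
  ours <- roc_auc(scores, labels)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<", levels = c(-1, 1))))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("LOO-CV performs n fits, is order-invariant and aces a separable toy", {
  tab <- toy_separable(n = 20)
  fmap <- feature_map(linear = c("a", "b"))
  cv <- loo_cv(tab, fmap)
  expect_equal(cv$accuracy, 1)
  expect_equal(cv$n_fits, 20L)
  expect_length(cv$scores, 20L)
  set.seed(77)
  perm <- sample(20)
  tabp <- tab
  tabp$x <- tab$x[perm, , drop = FALSE]
  tabp$y <- tab$y[perm]
  tabp$subjects <- tab$subjects[perm]
  cvp <- loo_cv(tabp, fmap)
  expect_equal(cvp$accuracy, cv$accuracy)
  expect_equal(cvp$scores, cv$scores[perm], tolerance = 1e-6)
})

test_that("LOO-CV accuracy sits near chance when labels are independent of features", {
  # balanced no-signal cohort: accuracy has nothing to learn from, so it
  # hovers around 0.5 (slightly below if anything -- leave-one-out tilts
  # each training fold against the held-out subject's class)
  spec <- synthetic_spec(120, 8, block_size = 4, rho = 0, class_balance = 0.5)
  accs <- vapply(1:5, function(s) {
    co <- generate_cohort(spec, seed = s)
    loo_cv(co$table, feature_map(linear = c("x01", "x07")))$accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.12)
  # with an imbalanced no-signal cohort the classifier converges to the
  # majority class, so accuracy tracks the majority rate instead
  acc_imb <- mean(vapply(1:3, function(s) {
    co <- generate_cohort("null", seed = s, n = 40)
    loo_cv(co$table, feature_map(linear = c("x01", "x07")))$accuracy
  }, numeric(1)))
  expect_lt(abs(acc_imb - (1 - 34 / 91)), 0.15)
})

test_that("a single-class training fold falls back to majority prediction with a warning", {
  # one positive subject: its fold trains on negatives only
  x <- cbind(a = c(5, rnorm(9)))
  tab <- cohort_table(x, c("SRNS", rep("SSNS", 9)))
  expect_warning(cv <- loo_cv(tab, feature_map(linear = "a")), "single class")
  expect_equal(cv$n_fits, 10L)
})

test_that("the overfitting test obeys its p-value formula, bounds and determinism", {
  tab <- toy_separable(n = 16, seed = 2)
  fmap <- feature_map(linear = c("a", "b"))
  ot <- overfit_test(tab, fmap, B = 39, seed = 4)
  expect_equal(ot$t0, 1) # separable toy
  expect_length(ot$t_perm, 39)
  expect_equal(ot$p_value, (sum(ot$t_perm > ot$t0) + 1) / 40)
  expect_gte(ot$p_value, 1 / 40)
  expect_lte(ot$p_value, 1)
  # T0 beats every permutation here: minimum attainable p
  expect_equal(ot$p_value, 1 / 40)
  ot2 <- overfit_test(tab, fmap, B = 39, seed = 4)
  expect_equal(ot2$t_perm, ot$t_perm)
  expect_error(overfit_test(tab, fmap, B = 5), "B >= 19")
})

test_that("validation reports serialize the metric set", {
  tab <- toy_separable(n = 14, seed = 6)
  cv <- loo_cv(tab, feature_map(linear = "a"))
  path <- tempfile(fileext = ".tsv")
  write_validation_report(cv, path)
  rep <- read.delim(path)
  expect_true(all(c("LOO_accuracy", "SN", "SP", "ACC", "MCC", "AUC") %in%
                    rep$measure))
  expect_equal(rep$value[rep$measure == "LOO_accuracy"], cv$accuracy)
})
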