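test_that("design matrices have the right shape and spline blocks form a partition of unity", {
  set.seed(2)
  x <- cbind(a = rnorm(10), b = rnorm(10), c = rnorm(10))
  tab <- cohort_table(x, rep(c("SRNS", "SSNS"), 5))
  fmap <- feature_map(linear = c("a", "b"), spline = "c", orders = 4)
  D <- build_design(tab, fmap)
  expect_equal(dim(D), c(10L, 1L + 2L + 4L))
  expect_equal(D[, 1], rep(1, 10), ignore_attr = TRUE)
  spl <- D[, paste0("c.", 1:4)]
  expect_equal(rowSums(spl), rep(1, 10), ignore_attr = TRUE) # partition of unity
  expect_true(all(spl >= 0))
  # domains recorded on the returned map
  expect_equal(attr(D, "fmap")$domains$c, range(x[, "c"]))
  expect_error(build_design(tab, feature_map(linear = "zz")), "not in table")
})

test_that("the spline basis agrees with a de Boor recursion oracle and is symmetric", {
  lo <- -2; hi <- 2
  for (ord in 2:4) {
    for (x in c(-2, -1.3, 0, 0.7, 2)) {
      expect_equal(drop(bspline_basis(x, lo, hi, ord)),
                   deboor_row(x, lo, hi, ord), tolerance = 1e-12)
    }
    # mirrored point on a symmetric domain: basis reverses
    b1 <- drop(bspline_basis(0.6, lo, hi, ord))
    b2 <- drop(bspline_basis(-0.6, lo, hi, ord))
    expect_equal(b1, rev(b2), tolerance = 1e-12)
  }
  # out-of-domain values clamp to the boundary basis
  expect_equal(drop(bspline_basis(5, lo, hi, 4)),
               drop(bspline_basis(hi, lo, hi, 4)))
})

test_that("the final ridge SVM separates a separable toy and collapses under huge ridge", {
  tab <- toy_separable()
  fmap <- feature_map(linear = c("a", "b"))
  model <- train_svm(tab, fmap)
  pred <- predict(model, as.data.frame(tab$x))
  expect_equal(mean(pred$label == tab$y), 1)
  # imbalanced labels so the (unpenalized) intercept dominates the
  # vanishing slopes and the prediction becomes constant
  set.seed(3)
  ximb <- cbind(a = rnorm(20), b = rnorm(20))
  timb <- cohort_table(ximb, c(rep("SRNS", 15), rep("SSNS", 5)))
  strong <- train_svm(timb, fmap, ridge_lambda = 1e6)
  expect_lt(max(abs(unlist(strong$linear_coefs))), 1e-3)
  expect_gt(strong$intercept, 0.1)
  pr <- predict(strong, data.frame(a = c(-3, 3), b = c(0, 0)))
  expect_equal(pr$label, c(1L, 1L)) # sign(intercept)
})

test_that("the decision boundary agrees with an independent linear-SVM solver", {
  skip_if_not_installed("e1071")
  tab <- toy_separable(n = 20, seed = 9)
  std <- standardize_cohort(tab)
  D <- build_design(std, feature_map(linear = c("a", "b")))
  model <- fit_final_svm(D, std$y, ridge_lambda = 1e-3)
  sv <- e1071::svm(std$x, factor(std$y), kernel = "linear", cost = 10,
                   scale = FALSE)
  w_ref <- drop(t(sv$coefs) %*% sv$SV)
  # libsvm orients its decision function toward the first training label
  if (sv$levels[sv$labels[1]] == "-1") w_ref <- -w_ref
  w <- unlist(model$linear_coefs)
  angle <- acos(sum(w * w_ref) / sqrt(sum(w^2) * sum(w_ref^2))) * 180 / pi
  expect_lt(angle, 2)
})

test_that("prediction is invariant to variable order and errors name missing inputs", {
  tab <- toy_separable()
  model <- train_svm(tab, feature_map(linear = c("a", "b")))
  p1 <- predict(model, list(a = 1, b = -0.5))
  p2 <- predict(model, list(b = -0.5, a = 1))
  expect_equal(p1$score, p2$score)
  expect_equal(p1$class, "SRNS")
  expect_error(predict(model, list(a = 1)), "b")
})

test_that("JSON serialization round-trips predictions losslessly", {
  set.seed(31)
  x <- cbind(u = rnorm(40), v = rnorm(40), w = rnorm(40))
  tab <- cohort_table(x, ifelse(x[, 1] + sin(x[, 2]) + 0.3 * rnorm(40) > 0,
                                "SRNS", "SSNS"))
  model <- train_svm(tab, feature_map(linear = "u", spline = c("v", "w"),
                                      orders = c(3, 4)))
  path <- tempfile(fileext = ".json")
  write_svm_model(model, path)
  back <- read_svm_model(path)
  newdata <- data.frame(u = rnorm(100), v = rnorm(100, sd = 2),
                        w = rnorm(100, sd = 2))
  expect_equal(predict(back, newdata), predict(model, newdata))
  # schema version is enforced
  bad <- jsonlite::read_json(path)
  bad$schema_version <- 99
  path2 <- tempfile(fileext = ".json")
  jsonlite::write_json(bad, path2, auto_unbox = TRUE)
  expect_error(read_svm_model(path2), "schema version")
})

test_that("stepwise forward equals exhaustive search for small candidate sets", {
  set.seed(17)
  n <- 40
  x <- cbind(s1 = rnorm(n), s2 = rnorm(n), d1 = rnorm(n), d2 = rnorm(n))
  y <- sign(1.5 * x[, "s1"] - 1.2 * x[, "s2"] + 0.5 * rnorm(n))
  tab <- cohort_table(x, ifelse(y > 0, "SRNS", "SSNS"))
  cands <- colnames(x)
  sw <- stepwise_forward(tab, cands, max_vars = 2)
  ex <- exhaustive_best(tab, cands, max_vars = 2)
  expect_equal(sort(sw$selected), sort(ex$vars))
  expect_equal(sw$trace$loo_accuracy[nrow(sw$trace)], ex$accuracy)
  # single candidate: that model, trivially
  sw1 <- stepwise_forward(tab, "s1", max_vars = 3)
  expect_equal(sw1$selected, "s1")
})

test_that("stepwise forward finds the planted signal pair among decoys", {
  hits <- 0
  for (s in 1:8) {
    set.seed(s)
    n <- 60
    x <- matrix(rnorm(n * 7), n, 7,
                dimnames = list(NULL, c("A", "B", paste0("d", 1:5))))
    y <- sign(1.8 * x[, "A"] + 1.8 * x[, "B"] + 0.6 * rnorm(n))
    tab <- cohort_table(x, ifelse(y > 0, "SRNS", "SSNS"))
    sw <- stepwise_forward(tab, colnames(x), max_vars = 2)
    hits <- hits + (sw$selected[1] %in% c("A", "B") &&
                    setequal(sw$selected, c("A", "B")))
  }
  expect_gte(hits, 6) # >= 75% of small replicates at this n
})

test_that("spline-order selection resolves ties downward and gates on overfitting", {
  # linear truth: all orders fit equally well; ties resolve to order 2
  set.seed(5)
  n <- 80
  x <- cbind(v = rnorm(n))
  y <- sign(2 * x[, "v"] + 0.5 * rnorm(n))
  tab <- cohort_table(x, ifelse(y > 0, "SRNS", "SSNS"))
  s <- select_spline_order(tab, "v", B = 19, seed = 2)
  expect_equal(s, 2L, ignore_attr = TRUE)
  trace <- attr(s, "trace")
  expect_equal(trace$order, 2:4)
  # pure noise: no order passes the overfit gate -> sentinel NA
  set.seed(6)
  tabn <- cohort_table(cbind(v = rnorm(40)),
                       sample(c("SRNS", "SSNS"), 40, replace = TRUE))
  sn <- select_spline_order(tabn, "v", B = 39, seed = 3)
  expect_true(is.na(sn))
})

test_that("a cubic-shaped signal prefers a higher spline order", {
  wins <- 0
  for (s in 1:6) {
    set.seed(s)
    n <- 200
    v <- rnorm(n)
    y <- sign((v^3 - 3 * v) / sqrt(6) * 3 + rlogis(n) * 0.4)
    tab <- cohort_table(cbind(v = v), ifelse(y > 0, "SRNS", "SSNS"))
    acc <- function(ord) loo_cv(tab, feature_map(spline = "v", orders = ord))$accuracy
    wins <- wins + (acc(4) > acc(2))
  }
  expect_gte(wins, 5)
})

test_that("correlation matrices use pairwise-complete cells and the zero convention", {
  set.seed(44)
  x <- cbind(a = rnorm(30), c = rep(1, 30))
  x <- cbind(x, b = -x[, "a"])
  x[1:3, "a"] <- NA
  tab <- cohort_table(x, rep(c("SRNS", "SSNS"), 15))
  expect_warning(cm <- correlation_matrix(tab, c("a", "b", "c")), "constant")
  expect_equal(diag(cm), c(a = 1, b = 1, c = 1))
  expect_equal(cm["a", "b"], -1)
  expect_equal(cm["a", "c"], 0)
  expect_equal(cm, t(cm))
})
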