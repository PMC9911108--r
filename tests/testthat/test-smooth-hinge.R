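test_that("hinge loss matches hand evaluation", {
  X <- cbind(1, c(2, 0))
  y <- c(1, 1)
  expect_equal(hinge_loss(X, y, c(0, 0)), 1) # beta = 0: mean (1 - 0)_+
  expect_equal(hinge_loss(matrix(c(1, 2), 1), 1, c(0, 1)), 0) # margin 2
  # margins (0.5, -0.5): loss = (0.5 + 1.5)/2
  X2 <- cbind(c(0.5, -0.5))
  expect_equal(hinge_loss(X2, c(1, 1), 1), 1)
  expect_error(hinge_loss(X, c(1, 1, 1), c(0, 0)), "length")
})

test_that("smoothed loss obeys the softplus-hinge bound and its limit", {
  X <- cbind(1, c(2, -1, 0.5))
  y <- c(1, -1, 1)
  # margin exactly 1 for all i: loss = log(2)/gamma
  expect_equal(mlr_loss(cbind(c(1, 1)), c(1, 1), 1, gamma = 7), log(2) / 7)
  set.seed(3)
  for (r in 1:50) {
    beta <- rnorm(2)
    gam <- runif(1, 0.5, 100)
    gap <- mlr_loss(X, y, beta, gam) - hinge_loss(X, y, beta)
    expect_gte(gap, -1e-12) # zero up to floating-point rounding
    expect_lte(gap, log(2) / gam + 1e-12)
  }
  beta <- c(0.3, -0.7)
  expect_lt(abs(mlr_loss(X, y, beta, 1e6) - hinge_loss(X, y, beta)), 1e-6)
  # overflow safety: huge negative margin stays finite
  expect_true(is.finite(mlr_loss(cbind(1e4), 1, -1e4, gamma = 50)))
})

test_that("unpenalized fit separates a separable toy and traces decrease", {
  td <- toy_design()
  fit <- fit_penalized(td$X, td$y, penalty_spec("tlp", lam = 0),
                       fit_config())
  pred <- sign(td$X %*% fit$beta)
  expect_equal(mean(pred == td$y), 1)
  expect_true(all(diff(fit$objective_trace) <= 1e-8))
})

test_that("a dominating tlp penalty empties the support", {
  td <- toy_design()
  fit <- fit_penalized(td$X, td$y, penalty_spec("tlp", lam = 10, tau = 1e-4),
                       fit_config())
  expect_length(fit$support, 0)
  expect_true(all(abs(fit$beta[-1]) <= 1e-4))
})

test_that("ridge fit with vanishing penalty approaches the unpenalized minimizer", {
  td <- toy_design(n = 10, seed = 5)
  cfg <- fit_config()
  f_ridge <- fit_penalized(td$X, td$y, penalty_spec("ridge", lam = 1e-10), cfg)
  f_free <- fit_penalized(td$X, td$y, penalty_spec("tlp", lam = 0), cfg)
  o1 <- mlr_loss(td$X, td$y, f_ridge$beta, cfg$gamma)
  o2 <- mlr_loss(td$X, td$y, f_free$beta, cfg$gamma)
  expect_lt(abs(o1 - o2), 1e-6)
})

test_that("fits are invariant to joint row permutation", {
  set.seed(11)
  X <- cbind(`(Intercept)` = 1, a = rnorm(40), b = rnorm(40))
  y <- sign(X[, 2] - 0.5 * X[, 3] + 0.3 * rnorm(40))
  fit1 <- fit_penalized(X, y, penalty_spec("tlp", lam = 1e-5), fit_config())
  perm <- sample(40)
  fit2 <- fit_penalized(X[perm, ], y[perm], penalty_spec("tlp", lam = 1e-5),
                        fit_config())
  expect_equal(fit1$beta, fit2$beta, tolerance = 1e-6)
})

test_that("nonconvex penalized fits recover a strong planted support", {
  # effects strong enough that an oracle logistic fit on the true support
  # also recovers it (checked once below)
  hits <- 0
  for (s in 1:20) {
    co <- generate_cohort("linear5", seed = s, n = 200)
    std <- standardize_cohort(co$table)
    X <- cbind(`(Intercept)` = 1, std$x)
    fit <- fit_penalized(X, std$y,
                         penalty_spec("tlp", lam = 2^-6 * 1e-3, tau = 1e-4),
                         fit_config())
    hits <- hits + setequal(fit$support, names(co$truth$linear))
  }
  expect_gte(hits, 16) # >= 80% of replicates
  # oracle: plain logistic regression on the true support has all
  # coefficients significant with the designed signs
  co <- generate_cohort("linear5", seed = 1, n = 200)
  std <- standardize_cohort(co$table)
  df <- data.frame(y = factor(std$y), std$x[, names(co$truth$linear)])
  or <- glm(y ~ ., data = df, family = binomial)
  z <- summary(or)$coefficients[-1, 3]
  expect_true(all(sign(z) == sign(co$truth$linear)))
  expect_true(all(abs(z) > 2))
})

test_that("single-class labels are rejected", {
  td <- toy_design()
  expect_error(fit_penalized(td$X, rep(1, nrow(td$X)),
                             penalty_spec("tlp", lam = 0)), "both classes")
})

test_that("selected_support applies the magnitude threshold to non-intercept coefficients", {
  fit <- structure(list(beta = c(`(Intercept)` = 0.3, a = 0, b = 0.2),
                        penalty = penalty_spec("tlp", 1e-3, tau = 1e-4)),
                   class = "tlpsvm_fit")
  expect_equal(selected_support(fit, threshold = 0.1), "b")
  expect_equal(selected_support(fit, threshold = 10), character(0))
  expect_equal(selected_support(fit, threshold = 0), "b") # strictly > 0
})

test_that("cross-validated lambda selection prefers the sparser model on noise", {
  set.seed(21)
  X <- cbind(`(Intercept)` = 1, matrix(rnorm(30 * 5), 30, 5,
                                       dimnames = list(NULL, paste0("v", 1:5))))
  y <- sample(c(-1, 1), 30, replace = TRUE)
  cfg <- fit_config(gamma_schedule = 50) # keep the grid search light
  sel <- select_lambda_cv(X, y, "tlp", cfg)
  expect_length(sel$cv_curve, 11)
  # accuracy near chance everywhere; ties broken toward the largest lambda
  flat <- which(sel$cv_curve >= max(sel$cv_curve) - 1e-12)
  expect_equal(sel$lambda_used, sel$grid[flat[1]])
  expect_error(select_lambda_cv(X[1:2, ], y[1:2], "tlp", cfg), "at least 3")
})
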