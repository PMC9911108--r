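# Independent oracles and small fixture builders used across the suite.

# de Boor recursion for one B-spline basis function value: independent of
# splines::splineDesign, used to cross-check the package's basis.
deboor_basis <- function(x, knots, i, ord) {
  if (ord == 1) {
    # half-open intervals, closed at the right end of the span
    upper_ok <- if (i + 1 <= length(knots) && knots[i + 1] == knots[length(knots)])
      x <= knots[i + 1] else x < knots[i + 1]
    return(as.numeric(x >= knots[i] && upper_ok))
  }
  d1 <- knots[i + ord - 1] - knots[i]
  d2 <- knots[i + ord] - knots[i + 1]
  t1 <- if (d1 > 0) (x - knots[i]) / d1 * deboor_basis(x, knots, i, ord - 1) else 0
  t2 <- if (d2 > 0) (knots[i + ord] - x) / d2 * deboor_basis(x, knots, i + 1, ord - 1) else 0
  t1 + t2
}

deboor_row <- function(x, lo, hi, ord) {
  knots <- c(rep(lo, ord), rep(hi, ord))
  vapply(seq_len(ord), function(i) deboor_basis(x, knots, i, ord), numeric(1))
}

# O(n^2) pair-counting AUC oracle (ties count one half)
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == -1]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# linearly separable toy: class decided by x1
toy_separable <- function(n = 20, seed = 42) {
  set.seed(seed)
  x1 <- c(seq(-2, -0.5, length.out = n / 2), seq(0.5, 2, length.out = n / 2))
  x2 <- rnorm(n)
  x <- cbind(a = x1, b = x2)
  cohort_table(x, ifelse(x1 > 0, "SRNS", "SSNS"),
               subjects = paste0("s", seq_len(n)))
}

toy_design <- function(n = 20, seed = 42) {
  tab <- toy_separable(n, seed)
  X <- cbind(`(Intercept)` = 1, tab$x)
  list(X = X, y = tab$y)
}

# exhaustive stepwise oracle: best model over all nonempty subsets of
# size <= max_vars, scored by the same LOO accuracy; returns best subset
# (ties resolved toward smaller, earlier-ordered subsets, matching the
# greedy path's preference only when the greedy path is optimal)
exhaustive_best <- function(table, candidates, max_vars, ...) {
  best <- NULL
  best_acc <- -Inf
  for (k in seq_len(max_vars)) {
    for (idx in utils::combn(length(candidates), k, simplify = FALSE)) {
      vars <- candidates[idx]
      acc <- loo_cv(table, feature_map(linear = vars), ...)$accuracy
      if (acc > best_acc + 1e-12) {
        best_acc <- acc
        best <- vars
      }
    }
  }
  list(vars = best, accuracy = best_acc)
}

write_toy_csv <- function(path, with_na = TRUE) {
  lines <- c(
    "subject,class,v1,v2,v3",
    "s1,SRNS,1.0,2.0,0.5",
    paste0("s2,SSNS,2.0,", if (with_na) "NA" else "3.0", ",1.5"),
    "s3,SSNS,3.0,4.0,")
  writeLines(lines, path)
  path
}
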