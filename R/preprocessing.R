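# Cohort table ingestion, missingness filtering, standardization and label
# encoding. A cohort_table is the universal input: subjects x variables
# with a binary class label per subject; missing cells are NA.

#' Construct a cohort table
#'
#' @param x numeric matrix (subjects x variables), `NA` for missing cells;
#'   must have column names.
#' @param y labels: either a \{-1, +1\} vector or a character/factor with
#'   two levels, in which case `positive_class` is mapped to `+1`.
#' @param subjects subject identifiers (default rownames of `x`).
#' @param positive_class label mapped to `+1` (default `"SRNS"`).
#' @param negative_class label mapped to `-1`; inferred if missing.
#' @return an object of class `cohort_table` with fields `x`, `y`
#'   (\{-1,+1\}), `subjects`, `classes` (names of the -1/+1 classes) and
#'   `std` (per-variable standardization parameters once
#'   [standardize_cohort()] has run, else `NULL`).
#' @export
cohort_table <- function(x, y, subjects = rownames(x),
                         positive_class = "SRNS", negative_class = NULL) {
  if (!is.matrix(x)) x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x)))
    stop("`x` must have column names", call. = FALSE)
  if (is.null(subjects)) subjects <- paste0("s", seq_len(nrow(x)))
  if (anyDuplicated(subjects))
    stop("duplicate subject identifiers: ",
         paste(unique(subjects[duplicated(subjects)]), collapse = ", "),
         call. = FALSE)
  if (length(y) != nrow(x))
    stop("one label per subject required", call. = FALSE)
  if (is.numeric(y) && all(y %in% c(-1, 1))) {
    classes <- c(negative_class %||% "neg", positive_class)
    y <- as.integer(y)
  } else {
    y <- as.character(y)
    lev <- unique(y[!is.na(y)])
    if (any(is.na(y))) stop("label present for every subject required", call. = FALSE)
    if (length(lev) != 2L)
      stop("label column must have exactly 2 levels, found: ",
           paste(lev, collapse = ", "), call. = FALSE)
    if (!positive_class %in% lev)
      stop("positive class '", positive_class, "' not found in labels", call. = FALSE)
    negative_class <- negative_class %||% setdiff(lev, positive_class)
    classes <- c(negative_class, positive_class)
    y <- ifelse(y == positive_class, 1L, -1L)
  }
  rownames(x) <- subjects
  structure(list(x = x, y = y, subjects = subjects, classes = classes,
                 std = NULL),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table: %d subjects x %d variables; %d %s (+1) / %d %s (-1); %.1f%% cells missing%s>\n",
              nrow(x$x), ncol(x$x), sum(x$y == 1), x$classes[2],
              sum(x$y == -1), x$classes[1],
              100 * mean(is.na(x$x)),
              if (is.null(x$std)) "" else "; standardized"))
  invisible(x)
}

#' @export
dim.cohort_table <- function(x) dim(x$x)

#' Load a cohort table from CSV
#'
#' Expected dialect: UTF-8, comma-separated, header row, first column the
#' subject identifier, one label column with exactly two classes, remaining
#' columns numeric features; `"NA"` or empty cells are missing.
#'
#' @param path CSV file path.
#' @param label_column name of the label column (default `"class"`).
#' @param positive_class class mapped to `+1` (default `"SRNS"`).
#' @return a [cohort_table()].
#' @export
load_cohort <- function(path, label_column = "class", positive_class = "SRNS") {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  if (ncol(df) < 3L)
    stop("expected subject id, label and at least one feature column", call. = FALSE)
  if (!label_column %in% names(df))
    stop("label column '", label_column, "' not found in ", path, call. = FALSE)
  subjects <- as.character(df[[1L]])
  labels <- df[[label_column]]
  feats <- df[, setdiff(names(df), c(names(df)[1L], label_column)), drop = FALSE]
  for (j in names(feats)) {
    v <- feats[[j]]
    if (!is.numeric(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(conv))
      if (length(bad))
        stop(sprintf("non-numeric value '%s' in column '%s', row %d",
                     v[bad[1]], j, bad[1]), call. = FALSE)
      feats[[j]] <- conv
    }
  }
  cohort_table(as.matrix(feats), labels, subjects = subjects,
               positive_class = positive_class)
}

#' Write a cohort table to CSV
#'
#' Inverse of [load_cohort()] (same dialect).
#' @param table a [cohort_table()].
#' @param path output CSV path.
#' @param label_column label column name.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path, label_column = "class") {
  stopifnot(inherits(table, "cohort_table"))
  lab <- ifelse(table$y == 1L, table$classes[2], table$classes[1])
  df <- data.frame(subject = table$subjects, class = lab,
                   table$x, check.names = FALSE)
  names(df)[2] <- label_column
  utils::write.csv(df, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Drop variables with too many missing values
#'
#' Removes variables whose missing fraction is strictly greater than
#' `max_missing_rate` (default 0.5, i.e. missing rate > 50%).
#'
#' @param table a [cohort_table()].
#' @param max_missing_rate threshold in (0, 1].
#' @return the filtered `cohort_table`; dropped names in attribute
#'   `"dropped"`.
#' @export
drop_high_missing <- function(table, max_missing_rate = 0.5) {
  stopifnot(inherits(table, "cohort_table"),
            max_missing_rate > 0, max_missing_rate <= 1)
  rate <- colMeans(is.na(table$x))
  drop <- names(rate)[rate > max_missing_rate]
  if (length(drop))
    message(length(drop), " variable(s) dropped for missing rate > ",
            max_missing_rate, ": ", paste(drop, collapse = ", "))
  out <- table
  out$x <- table$x[, setdiff(colnames(table$x), drop), drop = FALSE]
  if (!is.null(out$std)) out$std <- out$std[setdiff(names(out$std), drop)]
  attr(out, "dropped") <- drop
  out
}

#' Standardize variables to mean 0, variance 1
#'
#' Each column is centered and scaled using its observed (non-missing)
#' entries; the population variance convention (divide by n) is used.
#' Zero-variance columns are left untouched with a warning. Stored
#' parameters can be re-applied to new subjects via `params`.
#'
#' @param table a [cohort_table()].
#' @param params optional previously stored parameters (named list of
#'   `c(mean, sd)` per variable) to apply instead of re-estimating.
#' @return the standardized `cohort_table` with `$std` populated.
#' @export
standardize_cohort <- function(table, params = NULL) {
  stopifnot(inherits(table, "cohort_table"))
  x <- table$x
  if (is.null(params)) {
    params <- lapply(colnames(x), function(j) {
      v <- x[, j]
      v <- v[!is.na(v)]
      if (!length(v)) return(c(mean = 0, sd = 1))
      m <- mean(v)
      s <- sqrt(mean((v - m)^2)) # population convention
      c(mean = m, sd = s)
    })
    names(params) <- colnames(x)
  }
  for (j in colnames(x)) {
    p <- params[[j]]
    if (is.null(p)) stop("no standardization parameters for '", j, "'", call. = FALSE)
    if (p["sd"] <= 0) {
      warning("variable '", j, "' has zero variance; left unstandardized",
              call. = FALSE)
      next
    }
    x[, j] <- (x[, j] - p["mean"]) / p["sd"]
  }
  out <- table
  out$x <- x
  out$std <- params
  out
}

#' Keep subjects fully observed on a set of variables
#'
#' Subjects with any missing value on the listed variables are removed
#' (no imputation anywhere in this package: imputing would inject bias of
#' unknown direction into such a small cohort).
#'
#' @param table a [cohort_table()].
#' @param variables variable names that must be observed; empty vector
#'   returns the table unchanged.
#' @return the filtered `cohort_table`; number removed in attribute
#'   `"n_removed"`.
#' @export
complete_cases <- function(table, variables) {
  stopifnot(inherits(table, "cohort_table"))
  if (!all(variables %in% colnames(table$x)))
    stop("unknown variable(s): ",
         paste(setdiff(variables, colnames(table$x)), collapse = ", "),
         call. = FALSE)
  if (!length(variables)) {
    attr(table, "n_removed") <- 0L
    return(table)
  }
  keep <- stats::complete.cases(table$x[, variables, drop = FALSE])
  if (!any(keep))
    stop("no subjects fully observed on the selected variables", call. = FALSE)
  out <- table
  out$x <- table$x[keep, , drop = FALSE]
  out$y <- table$y[keep]
  out$subjects <- table$subjects[keep]
  attr(out, "n_removed") <- sum(!keep)
  out
}

# internal: row subset preserving structure
subset_cohort <- function(table, idx) {
  out <- table
  out$x <- table$x[idx, , drop = FALSE]
  out$y <- table$y[idx]
  out$subjects <- table$subjects[idx]
  out
}
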