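#' Sample skewness
#'
#' Adjusted Fisher-Pearson (bias-corrected) sample skewness. Constant
#' samples are defined to have skewness 0.
#'
#' @param values Numeric vector with at least 3 finite values.
#' @return The skewness.
#' @export
skewness <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) < 3) stop("skewness needs at least 3 finite values")
  if (stats::sd(v) == 0) return(0)
  e1071::skewness(v, type = 2)
}

#' Logarithmic transformation of designated features
#'
#' Applies the natural log to a designated set of features. The default
#' (`policy = "fixed"`) set is the dictionary's log-marked features
#' (latency mean/SD and all per-position fixation SDs). With
#' `policy = "skewness"` the set is chosen data-driven: features whose
#' sample skewness falls outside (-1, 1) on the rows indicated by
#' `train_rows` (training only, to avoid test leakage). Zero values are
#' offset by 1e-6 times the feature's positive median before the log;
#' negative values raise an error naming the feature.
#'
#' @param table Feature table (data.frame).
#' @param features Candidate feature columns; default: the 31 dictionary
#'   features present in `table`.
#' @param policy `"fixed"` or `"skewness"`.
#' @param train_rows Row indices used to estimate skewness (and offsets);
#'   default all rows.
#' @return A list with `table` (transformed) and `features` (the columns
#'   actually transformed).
#' @export
log_transform <- function(table, features = NULL,
                          policy = c("fixed", "skewness"),
                          train_rows = seq_len(nrow(table))) {
  policy <- match.arg(policy)
  dict <- ocat_feature_dictionary()
  if (is.null(features)) features <- intersect(dict$name, names(table))
  chosen <- if (policy == "fixed") {
    intersect(features, dict$name[dict$log])
  } else {
    features[vapply(features, function(f) {
      v <- table[train_rows, f]
      abs(skewness(v)) > 1
    }, logical(1))]
  }
  for (f in chosen) {
    v <- table[[f]]
    if (any(v < 0, na.rm = TRUE)) {
      stop("feature '", f, "' has negative values; cannot log-transform")
    }
    if (any(v == 0, na.rm = TRUE)) {
      pos <- table[train_rows, f]
      pos <- pos[pos > 0 & !is.na(pos)]
      off <- if (length(pos)) 1e-6 * stats::median(pos) else 1e-6
      v <- v + off
    }
    table[[f]] <- log(v)
  }
  list(table = table, features = chosen)
}

#' Stratified train/test split
#'
#' Splits a labeled feature table so the class distribution is preserved:
#' each class contributes `round(n_class * test_fraction)` test rows,
#' reconciled to the global test size `round(n * test_fraction)` by
#' largest remainder. Per-class test counts can be overridden to
#' reproduce an externally given partition.
#'
#' @param table Feature table with a `label` column.
#' @param test_fraction Held-out fraction (default 0.2).
#' @param seed RNG seed; membership is deterministic given it.
#' @param label_col Name of the class column.
#' @param test_counts Optional named vector of per-class test counts
#'   overriding the rounding rule.
#' @return A list of class `split_dataset` with `train`, `test` and
#'   `counts` (per-class table for each part).
#' @export
stratified_split <- function(table, test_fraction = 0.2, seed = 1,
                             label_col = "label", test_counts = NULL) {
  if (!is.null(test_fraction) &&
      (test_fraction <= 0 || test_fraction >= 1) && is.null(test_counts)) {
    stop("`test_fraction` must be in (0, 1)")
  }
  y <- as.character(table[[label_col]])
  classes <- sort(unique(y))
  if (length(classes) < 2) stop("both classes must be present")
  n_c <- table(y)
  if (any(n_c < 2)) stop("every class needs at least 2 members")
  if (is.null(test_counts)) {
    target <- round(nrow(table) * test_fraction)
    raw <- as.numeric(n_c[classes]) * test_fraction
    cnt <- round(raw)
    # largest-remainder reconciliation to the global test size
    while (sum(cnt) != target) {
      rem <- raw - cnt
      if (sum(cnt) < target) {
        i <- which.max(rem); cnt[i] <- cnt[i] + 1
      } else {
        i <- which.min(rem); cnt[i] <- cnt[i] - 1
      }
    }
    test_counts <- stats::setNames(cnt, classes)
  }
  test_idx <- local_seed(seed, {
    unlist(lapply(classes, function(cl) {
      idx <- which(y == cl)
      sample(idx, test_counts[[cl]])
    }))
  })
  structure(
    list(train = table[-test_idx, , drop = FALSE],
         test = table[test_idx, , drop = FALSE],
         counts = list(train = table(y[-test_idx]),
                       test = table(y[test_idx]))),
    class = "split_dataset")
}

#' SMOTE minority oversampling
#'
#' Synthetic Minority Over-sampling Technique: each synthetic row is
#' drawn by picking a minority row, one of its `k_neighbors` nearest
#' minority neighbours (Euclidean distance on the feature columns), and a
#' point uniformly at random on the segment between them. The minority
#' class is raised to the majority count; majority rows are untouched and
#' the test partition never enters. Synthetic rows are flagged in an
#' `is_synthetic` column.
#'
#' @param train Training feature table with a label column.
#' @param k_neighbors Number of nearest neighbours (default 5; reduced
#'   with a warning when the minority class is too small).
#' @param seed RNG seed.
#' @param label_col Name of the class column.
#' @param feature_cols Numeric feature columns; default: all numeric
#'   columns except the label.
#' @return The balanced training table.
#' @export
smote <- function(train, k_neighbors = 5, seed = 1, label_col = "label",
                  feature_cols = NULL) {
  y <- as.character(train[[label_col]])
  tab <- table(y)
  if (length(tab) != 2) stop("SMOTE expects exactly two classes")
  minority <- names(tab)[which.min(tab)]
  n_min <- min(tab); n_maj <- max(tab)
  if (is.null(train$is_synthetic)) train$is_synthetic <- FALSE
  if (n_min == n_maj) return(train)
  if (n_min < 2) stop("minority class needs at least 2 members")
  if (n_min <= k_neighbors) {
    k_neighbors <- n_min - 1
    warning("minority class smaller than k; using k = ", k_neighbors)
  }
  if (is.null(feature_cols)) {
    feature_cols <- names(train)[vapply(train, is.numeric, logical(1))]
    feature_cols <- setdiff(feature_cols, label_col)
  }
  X <- as.matrix(train[y == minority, feature_cols, drop = FALSE])
  d <- as.matrix(stats::dist(X))
  diag(d) <- Inf
  nn <- t(apply(d, 1, function(r) order(r)[seq_len(k_neighbors)]))
  n_new <- n_maj - n_min
  local_seed(seed, {
    base_i <- sample(nrow(X), n_new, replace = TRUE)
    nb_i <- nn[cbind(base_i, sample(k_neighbors, n_new, replace = TRUE))]
    u <- stats::runif(n_new)
    synth_X <- X[base_i, , drop = FALSE] +
      u * (X[nb_i, , drop = FALSE] - X[base_i, , drop = FALSE])
    synth <- train[y == minority, , drop = FALSE][base_i, , drop = FALSE]
    synth[, feature_cols] <- synth_X
    synth$is_synthetic <- TRUE
    if ("id" %in% names(synth)) {
      synth$id <- sprintf("SYN%03d", seq_len(n_new))
    }
    out <- rbind(train, synth)
    rownames(out) <- NULL
    out
  })
}

#' Training-median imputation of missing feature values
#'
#' Some features are undefined for some sessions (no blinks means no
#' median blink duration; an empty saccadic plane has no median
#' velocity). `impute_fit` learns per-feature medians on the training
#' rows only; `impute_apply` fills missing values in any table with them,
#' so the test split never informs the imputation.
#'
#' @param train Training table.
#' @param feature_cols Columns to impute; default: all numeric columns.
#' @return `impute_fit`: an `impute_state` list; `impute_apply`: the
#'   completed table.
#' @export
impute_fit <- function(train, feature_cols = NULL) {
  if (is.null(feature_cols)) {
    feature_cols <- names(train)[vapply(train, is.numeric, logical(1))]
  }
  med <- vapply(train[feature_cols], function(v) {
    m <- stats::median(v, na.rm = TRUE)
    if (is.finite(m)) m else 0
  }, numeric(1))
  structure(list(median = med, cols = feature_cols),
            class = "impute_state")
}

#' @rdname impute_fit
#' @param state A fitted `impute_state`.
#' @param table Table to complete.
#' @export
impute_apply <- function(state, table) {
  for (f in state$cols) {
    miss <- is.na(table[[f]])
    if (any(miss)) table[[f]][miss] <- state$median[[f]]
  }
  table
}

#' Fit and apply z-score standardization
#'
#' `standardize_fit` learns per-feature mean and SD on the training table
#' (zero-variance features get SD 1 with a warning);
#' `standardize_apply` applies a fitted state to any table, and
#' `destandardize` inverts it.
#'
#' @param train Training table (fit only ever sees training rows).
#' @param feature_cols Columns to standardize; default: all numeric
#'   columns except `label`-like bookkeeping columns.
#' @return `standardize_fit`: a `scaler_state` list with `mean`, `sd`,
#'   `cols`; the others: the transformed table.
#' @export
standardize_fit <- function(train, feature_cols = NULL) {
  if (is.null(feature_cols)) {
    feature_cols <- names(train)[vapply(train, is.numeric, logical(1))]
  }
  m <- vapply(train[feature_cols], mean, numeric(1))
  s <- vapply(train[feature_cols], stats::sd, numeric(1))
  zero <- !is.finite(s) | s == 0
  if (any(zero)) {
    warning("zero-variance feature(s): ",
            paste(feature_cols[zero], collapse = ", "), "; SD set to 1")
    s[zero] <- 1
  }
  structure(list(mean = m, sd = s, cols = feature_cols),
            class = "scaler_state")
}

#' @rdname standardize_fit
#' @param state A fitted `scaler_state`.
#' @param table Table to transform.
#' @export
standardize_apply <- function(state, table) {
  for (f in state$cols) {
    table[[f]] <- (table[[f]] - state$mean[[f]]) / state$sd[[f]]
  }
  table
}

#' @rdname standardize_fit
#' @export
destandardize <- function(state, table) {
  for (f in state$cols) {
    table[[f]] <- table[[f]] * state$sd[[f]] + state$mean[[f]]
  }
  table
}
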