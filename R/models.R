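#' Train an L2-regularized logistic regression
#'
#' Ridge-penalized binary logistic regression on standardized features
#' with an unpenalized intercept. The penalty applies to the
#' per-observation (mean) log-likelihood, so the fit depends only on the
#' empirical distribution of the training data — duplicating every row
#' leaves the coefficients unchanged. The default `lambda = 0.005` is a
#' weak ridge comparable, at cohort-scale training sizes (a few hundred
#' rows), to the common default of penalized solvers. The model outputs
#' the probability of the positive (PMCI) class.
#'
#' @param train Standardized training table with a `label` column.
#' @param feature_cols Feature columns; default: all numeric columns
#'   except bookkeeping ones.
#' @param label_col Name of the class column.
#' @param positive Positive class (default `"PMCI"`).
#' @param lambda Ridge penalty on the per-observation objective
#'   (default 0.005).
#' @return An object of class `ocat_lr`.
#' @export
train_lr <- function(train, feature_cols = NULL, label_col = "label",
                     positive = "PMCI", lambda = 0.005) {
  feature_cols <- feature_cols %||% model_feature_cols(train, label_col)
  y <- factor(train[[label_col]])
  stopifnot(nlevels(y) == 2, positive %in% levels(y))
  y <- stats::relevel(y, ref = setdiff(levels(y), positive))
  X <- as.matrix(train[, feature_cols, drop = FALSE])
  # glmnet requires >= 2 columns; a single-feature model is padded with
  # an all-zero column whose coefficient is identically zero
  pad <- ncol(X) == 1
  if (pad) X <- cbind(X, .pad = 0)
  fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                        lambda = lambda, standardize = FALSE,
                        thresh = 1e-10, maxit = 1e6)
  if (!fit$jerr == 0 && fit$npasses >= 1e6) {
    stop("logistic regression failed to converge after ", fit$npasses,
         " passes")
  }
  structure(list(fit = fit, feature_cols = feature_cols,
                 positive = positive, lambda = lambda, pad = pad),
            class = "ocat_lr")
}

model_feature_cols <- function(train, label_col) {
  cols <- names(train)[vapply(train, is.numeric, logical(1))]
  setdiff(cols, c(label_col, "drs"))
}

#' Predicted positive-class probabilities
#'
#' @param model An `ocat_lr` or `ocat_knn` model.
#' @param newdata Table with the model's feature columns.
#' @return Numeric vector of P(positive class).
#' @export
predict_prob <- function(model, newdata) UseMethod("predict_prob")

#' @export
predict_prob.ocat_lr <- function(model, newdata) {
  X <- as.matrix(newdata[, model$feature_cols, drop = FALSE])
  if (isTRUE(model$pad)) X <- cbind(X, .pad = 0)
  as.numeric(stats::predict(model$fit, X, type = "response"))
}

#' @export
predict_prob.ocat_knn <- function(model, newdata) {
  X <- as.matrix(newdata[, model$feature_cols, drop = FALSE])
  pred <- class::knn(model$X, X, model$y, k = model$k, prob = TRUE)
  win <- attr(pred, "prob")
  ifelse(pred == model$positive, win, 1 - win)
}

#' Threshold predicted probabilities into class labels
#'
#' Positive (PMCI) when the predicted probability is at or above the
#' decision threshold (ties count positive).
#'
#' @param model A model with a [predict_prob()] method.
#' @param newdata Feature table.
#' @param dt Decision threshold in (0, 1).
#' @return Character vector of predicted labels.
#' @export
predict_threshold <- function(model, newdata, dt = 0.5) {
  stopifnot(dt > 0, dt < 1)
  p <- predict_prob(model, newdata)
  ifelse(p >= dt, model$positive, model$negative %||%
           setdiff(c("CN", "PMCI"), model$positive))
}

#' Train a k-nearest-neighbour classifier with training-only grid search
#'
#' Chooses k over a grid (default 3-10) by mean stratified
#' cross-validated F1 for the positive class on the training set only
#' (configurable to accuracy), then stores the training data for
#' prediction with Euclidean distance and uniform neighbour weights.
#' Ties in the criterion pick the smallest k.
#'
#' @param train Standardized training table with a `label` column.
#' @param feature_cols Feature columns.
#' @param label_col Name of the class column.
#' @param positive Positive class.
#' @param k_grid Candidate neighbourhood sizes.
#' @param folds CV folds for the grid search.
#' @param criterion `"f1"` or `"accuracy"`.
#' @param seed RNG seed (fold assignment and vote tie-breaks).
#' @return An object of class `ocat_knn` with the chosen `k` and the
#'   grid scores in `grid`.
#' @export
train_knn <- function(train, feature_cols = NULL, label_col = "label",
                      positive = "PMCI", k_grid = 3:10, folds = 5,
                      criterion = c("f1", "accuracy"), seed = 1) {
  criterion <- match.arg(criterion)
  if (!length(k_grid)) stop("`k_grid` must be non-empty")
  feature_cols <- feature_cols %||% model_feature_cols(train, label_col)
  y <- factor(train[[label_col]])
  X <- as.matrix(train[, feature_cols, drop = FALSE])
  stopifnot(nrow(X) >= max(k_grid) + 1)
  fold_id <- local_seed(seed, {
    id <- integer(length(y))
    for (cl in levels(y)) {
      idx <- which(y == cl)
      id[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
    }
    id
  })
  score_k <- function(k) {
    mean(vapply(seq_len(folds), function(fd) {
      tr <- fold_id != fd; te <- fold_id == fd
      pred <- local_seed(seed + fd,
                         class::knn(X[tr, , drop = FALSE],
                                    X[te, , drop = FALSE], y[tr], k = k))
      if (criterion == "accuracy") return(mean(pred == y[te]))
      m <- confusion_metrics(as.character(y[te]), as.character(pred),
                             positive = positive)
      m[["f1"]]
    }, numeric(1)))
  }
  grid <- vapply(k_grid, score_k, numeric(1))
  k <- k_grid[which.max(grid)]
  structure(list(X = X, y = y, k = k, feature_cols = feature_cols,
                 positive = positive,
                 grid = stats::setNames(grid, k_grid)),
            class = "ocat_knn")
}
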