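#' Confusion-matrix metrics for binary screening
#'
#' Recall (sensitivity), precision, specificity, F1 and accuracy with the
#' PMCI class as positive. Zero-denominator metrics are reported as 0 and
#' flagged in a `degenerate` attribute rather than returned as NaN.
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @param positive Positive class (default `"PMCI"`).
#' @return Named numeric vector: recall, precision, specificity, f1,
#'   accuracy.
#' @examples
#' confusion_metrics(c("PMCI", "CN"), c("PMCI", "CN"))
#' @export
confusion_metrics <- function(y_true, y_pred, positive = "PMCI") {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have the same length")
  }
  tp <- sum(y_true == positive & y_pred == positive)
  fn <- sum(y_true == positive & y_pred != positive)
  fp <- sum(y_true != positive & y_pred == positive)
  tn <- sum(y_true != positive & y_pred != positive)
  safe <- function(num, den) if (den == 0) 0 else num / den
  recall <- safe(tp, tp + fn)
  precision <- safe(tp, tp + fp)
  f1 <- safe(2 * precision * recall, precision + recall)
  out <- c(recall = recall, precision = precision,
           specificity = safe(tn, tn + fp), f1 = f1,
           accuracy = (tp + tn) / length(y_true))
  attr(out, "degenerate") <-
    c(recall = tp + fn == 0, precision = tp + fp == 0,
      specificity = tn + fp == 0, f1 = precision + recall == 0,
      accuracy = FALSE)
  out
}

#' Precision-recall curve
#'
#' One point per distinct score threshold, thresholds descending, with
#' predictions positive at score >= threshold.
#'
#' @param y_true Label vector containing both classes.
#' @param scores Positive-class scores.
#' @param positive Positive class.
#' @return A data.frame: `threshold`, `recall`, `precision`.
#' @export
pr_curve <- function(y_true, scores, positive = "PMCI") {
  pos <- y_true == positive
  if (!any(pos) || all(pos)) {
    stop("precision-recall analysis needs both classes present")
  }
  th <- sort(unique(scores), decreasing = TRUE)
  P <- sum(pos)
  tp <- vapply(th, function(t) sum(pos & scores >= t), numeric(1))
  pp <- vapply(th, function(t) sum(scores >= t), numeric(1))
  data.frame(threshold = th, recall = tp / P, precision = tp / pp)
}

#' Area under the precision-recall curve (average precision)
#'
#' The average-precision formulation: the sum of precision times the
#' recall increment over descending score thresholds. No interpolation
#' is applied, so the value is deterministic and never optimistic.
#'
#' @inheritParams pr_curve
#' @return AUPRC in \[0, 1\].
#' @export
auprc <- function(y_true, scores, positive = "PMCI") {
  curve <- pr_curve(y_true, scores, positive)
  r <- c(0, curve$recall)
  sum(diff(r) * curve$precision)
}

#' Bootstrap means and confidence intervals of test-set metrics
#'
#' Resamples the held-out test set with replacement (the trained model —
#' i.e. its scores — is fixed), recomputes recall, precision,
#' specificity, F1, accuracy and AUPRC on every replicate, and reports
#' each metric's replicate mean with percentile confidence limits.
#' Replicates without any positive case are redrawn (their count is
#' recorded in the `n_redrawn` attribute) so that recall and AUPRC stay
#' defined; all metrics share the same replicates.
#'
#' @param y_true Test labels.
#' @param scores Predicted positive-class probabilities.
#' @param dt Decision threshold for the label-based metrics.
#' @param B Number of bootstrap replicates (default 1000).
#' @param level Confidence level (default 0.95, i.e. the 2.5th/97.5th
#'   percentiles).
#' @param seed RNG seed.
#' @param positive Positive class.
#' @return A data.frame with one row per metric: `metric`, `mean`, `lo`,
#'   `hi`.
#' @export
bootstrap_metrics <- function(y_true, scores, dt = 0.5, B = 1000,
                              level = 0.95, seed = 1,
                              positive = "PMCI") {
  stopifnot(B >= 1, length(y_true) == length(scores))
  n <- length(y_true)
  neg_lab <- setdiff(unique(c(y_true, "CN")), positive)[1]
  pred <- ifelse(scores >= dt, positive, neg_lab)
  metric_names <- c("recall", "precision", "specificity", "f1",
                    "accuracy", "auprc")
  reps <- matrix(NA_real_, B, length(metric_names),
                 dimnames = list(NULL, metric_names))
  n_redrawn <- 0L
  local_seed(seed, {
    for (b in seq_len(B)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (any(y_true[idx] == positive) &&
            !all(y_true[idx] == positive)) break
        n_redrawn <- n_redrawn + 1L
      }
      cm <- confusion_metrics(y_true[idx], pred[idx], positive)
      reps[b, ] <- c(cm, auprc(y_true[idx], scores[idx], positive))
    }
  })
  alpha <- (1 - level) / 2
  out <- data.frame(
    metric = metric_names,
    mean = colMeans(reps),
    lo = apply(reps, 2, stats::quantile, alpha),
    hi = apply(reps, 2, stats::quantile, 1 - alpha),
    row.names = NULL)
  attr(out, "n_redrawn") <- n_redrawn
  out
}
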