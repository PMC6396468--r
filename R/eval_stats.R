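#' Benchmark metrics
#'
#' Standard evaluation metrics: Pearson correlation, root-mean-square error,
#' and areas under the ROC and precision-recall curves. Both areas are
#' computed by trapezoidal integration; the precision-recall curve is
#' anchored at recall 0 with the precision of the top-ranked threshold, and
#' tied prediction values are collapsed into single thresholds.
#'
#' @param kind One of `"pearson_r"`, `"rmse"`, `"auPR"`, `"auROC"`.
#' @param observed Observed values; binary (two classes present) for the
#'   area metrics.
#' @param predicted Numeric predictions.
#' @return Scalar metric value.
#' @export
metric <- function(kind = c("pearson_r", "rmse", "auPR", "auROC"),
                   observed, predicted) {
  kind <- match.arg(kind)
  stopifnot(length(observed) == length(predicted), length(observed) >= 2L)
  if (any(!is.finite(observed)) || any(!is.finite(predicted))) {
    stop("metric inputs must be finite")
  }
  switch(kind,
    pearson_r = {
      if (stats::sd(observed) == 0 || stats::sd(predicted) == 0) {
        stop("zero-variance input for Pearson correlation")
      }
      stats::cor(observed, predicted)
    },
    rmse = sqrt(mean((observed - predicted)^2)),
    auPR = pr_curve_auc(observed, predicted),
    auROC = roc_curve_auc(observed, predicted)
  )
}

check_binary <- function(observed) {
  u <- sort(unique(observed))
  if (!all(u %in% c(0, 1)) || length(u) != 2L) {
    stop("observed must be binary with both classes present")
  }
}

# cumulative TP/FP at the unique descending prediction thresholds
threshold_counts <- function(observed, predicted) {
  check_binary(observed)
  o <- order(predicted, decreasing = TRUE)
  y <- observed[o]
  p <- predicted[o]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  last <- !duplicated(p, fromLast = TRUE)   # collapse tied scores
  list(tp = tp[last], fp = fp[last], P = sum(y), N = sum(1 - y))
}

pr_curve_auc <- function(observed, predicted) {
  tc <- threshold_counts(observed, predicted)
  recall <- tc$tp / tc$P
  precision <- tc$tp / (tc$tp + tc$fp)
  pracma::trapz(c(0, recall), c(precision[1], precision))
}

roc_curve_auc <- function(observed, predicted) {
  tc <- threshold_counts(observed, predicted)
  pracma::trapz(c(0, tc$fp / tc$N, 1), c(0, tc$tp / tc$P, 1))
}

#' One-sided basic-bootstrap P value
#'
#' `P = (1 + #{d_i* <= 0}) / (B + 1)` over `B` bootstrapped metric
#' differences `d* = t1* - t2*`. The smallest attainable value is
#' `1 / (B + 1)` (0.001 at the conventional `B = 999`).
#'
#' @param d_star Numeric vector of `B` bootstrapped differences.
#' @param B Number of resamples; must equal `length(d_star)`.
#' @return P value in `[1/(B+1), 1]`.
#' @export
bootstrap_p <- function(d_star, B = length(d_star)) {
  if (length(d_star) == 0L) stop("empty bootstrap sample")
  if (length(d_star) != B) stop("B must equal length(d_star)")
  if (any(!is.finite(d_star))) stop("non-finite bootstrap differences")
  (1 + sum(d_star <= 0)) / (B + 1)
}

#' Compare two models by paired bootstrap
#'
#' Computes the metric for both prediction columns on the full data, then
#' resamples items (rows) with replacement `B` times — keeping observed
#' value and both predictions together — and recomputes the metric
#' difference `d* = t1* - t2*` on every resample. A resample on which the
#' metric is undefined (for instance a single-class draw for an area metric)
#' is redrawn and counted.
#'
#' @param data Data frame with columns `observed`, `pred1`, `pred2` (no
#'   missing values).
#' @param kind Metric kind, see [metric()].
#' @param B Number of bootstrap resamples (default 999).
#' @param seed Integer seed.
#' @return List with `t1`, `t2`, `p` (one-sided P value that model 1 beats
#'   model 2), `d_star`, and `n_redraws`.
#' @export
compare_models <- function(data, kind = "pearson_r", B = 999L, seed = 1L) {
  stopifnot(all(c("observed", "pred1", "pred2") %in% names(data)), B >= 1L)
  if (anyNA(data[, c("observed", "pred1", "pred2")])) stop("missing values in data")
  n <- nrow(data)
  t1 <- metric(kind, data$observed, data$pred1)
  t2 <- metric(kind, data$observed, data$pred2)
  set.seed(seed)
  d_star <- numeric(B)
  redraws <- 0L
  for (i in seq_len(B)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      d <- tryCatch(
        metric(kind, data$observed[idx], data$pred1[idx]) -
          metric(kind, data$observed[idx], data$pred2[idx]),
        error = function(e) NULL
      )
      if (!is.null(d)) break
      redraws <- redraws + 1L
      if (redraws > 100L * B) stop("metric undefined on almost every resample")
    }
    d_star[i] <- d
  }
  list(t1 = t1, t2 = t2, p = bootstrap_p(d_star, B), d_star = d_star,
       n_redraws = redraws)
}

#' Percentile bootstrap confidence interval
#'
#' Resamples the data `B` times with replacement, recomputes the statistic,
#' and reports the 2.5th and 97.5th percentiles of the bootstrap
#' distribution (linear interpolation between closest ranks). Resamples on
#' which the statistic is undefined are redrawn.
#'
#' @param values Numeric vector or data frame of items to resample.
#' @param statistic Function mapping a resampled `values` subset to a scalar.
#' @param B Number of resamples (default 1000).
#' @param seed Integer seed.
#' @param probs Interval probabilities, default `c(0.025, 0.975)`.
#' @return Named numeric vector `c(lo, hi)`.
#' @export
percentile_ci <- function(values, statistic, B = 1000L, seed = 1L,
                          probs = c(0.025, 0.975)) {
  n <- if (is.data.frame(values)) nrow(values) else length(values)
  stopifnot(n >= 2L, B >= 1L)
  take <- function(idx) if (is.data.frame(values)) values[idx, , drop = FALSE] else values[idx]
  set.seed(seed)
  theta <- numeric(B)
  redraws <- 0L
  for (i in seq_len(B)) {
    repeat {
      s <- tryCatch(statistic(take(sample.int(n, n, replace = TRUE))),
                    error = function(e) NULL)
      if (!is.null(s) && is.finite(s)) break
      redraws <- redraws + 1L
      if (redraws > 100L * B) stop("statistic undefined on almost every resample")
    }
    theta[i] <- s
  }
  ci <- stats::quantile(theta, probs = probs, names = FALSE, type = 7)
  stats::setNames(ci, c("lo", "hi"))
}
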