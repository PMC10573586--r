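# Confusion-matrix metrics, ROC/AUROC, per-fold optimal (Youden) thresholds
# and fold aggregation. Albinism (label 1) is the positive class throughout;
# the prediction rule is score >= threshold (ties predicted positive).
# Undefined metrics (zero denominators) are NA, never silently 0.

#' Confusion counts at a threshold
#'
#' @param scores Numeric scores (higher = more albinism-like).
#' @param labels 0/1 labels, same length; 1 (albinism) is positive.
#' @param threshold Predict positive iff `score >= threshold`.
#' @return A `confusion_counts` list: `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_at_threshold <- function(scores, labels, threshold) {
  if (length(scores) != length(labels)) {
    stop("confusion_at_threshold: scores and labels differ in length",
         call. = FALSE)
  }
  stopifnot(all(labels %in% c(0, 1)))
  pred <- scores >= threshold
  confusion_counts(tp = sum(pred & labels == 1),
                   fp = sum(pred & labels == 0),
                   fn = sum(!pred & labels == 1),
                   tn = sum(!pred & labels == 0))
}

#' @rdname confusion_at_threshold
#' @param tp,fp,fn,tn Non-negative counts; fractional values are allowed
#'   (fold-averaged confusion matrices are generally non-integer).
#' @export
confusion_counts <- function(tp, fp, fn, tn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Accuracy `(TP+TN)/(TP+FP+FN+TN)`, precision `TP/(TP+FP)`, recall
#' (sensitivity) `TP/(TP+FN)`, F1 `2TP/(2TP+FP+FN)`, plus specificity
#' `TN/(TN+FP)`. A zero denominator yields `NA` (undefined), never an
#' exception; all-zero counts are an error.
#'
#' @param counts A `confusion_counts`.
#' @return A `metrics_report` list (no `auroc`; see [roc_and_auroc()]).
#' @export
compute_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  n <- tp + fp + fn + tn
  if (n <= 0) {
    stop("compute_metrics: all-zero confusion counts", call. = FALSE)
  }
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  structure(list(
    accuracy = (tp + tn) / n,
    precision = safe_div(tp, tp + fp),
    recall = safe_div(tp, tp + fn),
    f1 = safe_div(2 * tp, 2 * tp + fp + fn),
    specificity = safe_div(tn, tn + fp),
    auroc = NA_real_
  ), class = "metrics_report")
}

#' ROC curve and AUROC
#'
#' Thresholds are the distinct scores (descending) plus an `Inf` sentinel;
#' the AUROC is the trapezoidal area under the curve and equals the
#' Mann-Whitney U statistic (ties counted one half) exactly.
#'
#' @param scores,labels As in [confusion_at_threshold()]; both classes must
#'   be present.
#' @return A list: `roc` (data.frame `threshold`, `tpr`, `fpr`) and `auroc`.
#' @export
roc_and_auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("roc_and_auroc: AUROC undefined, only one class present",
         call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  distinct <- c(which(diff(s) != 0), length(s)) # last index of each tie group
  tp <- cumsum(y == 1)[distinct]
  fp <- cumsum(y == 0)[distinct]
  roc <- data.frame(threshold = c(Inf, s[distinct]),
                    tpr = c(0, tp / n_pos),
                    fpr = c(0, fp / n_neg))
  auroc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) +
                                  utils::tail(roc$tpr, -1)) / 2)
  list(roc = roc, auroc = auroc)
}

#' Optimal decision threshold (Youden J)
#'
#' The threshold maximizing `tpr - fpr` (Youden J); ties are broken toward
#' the highest threshold (fewest positive calls). Any value in the
#' half-open interval between the optimal ROC point's score and the next
#' lower distinct score realizes the same confusion matrix under the
#' `score >= threshold` rule; the midpoint of that interval is returned
#' (the usual robust convention), so the operating point does not sit
#' exactly on an observed score. For a completely uninformative curve
#' (J = 0 everywhere) the `Inf` sentinel wins and nothing is called
#' positive.
#'
#' @param roc ROC data.frame from [roc_and_auroc()].
#' @return The selected threshold (predict positive at
#'   `score >= threshold`).
#' @export
optimal_threshold <- function(roc) {
  stopifnot(all(c("threshold", "tpr", "fpr") %in% names(roc)))
  j <- roc$tpr - roc$fpr
  best <- which(j == max(j))[1] # thresholds are descending: first = highest
  t_best <- roc$threshold[best]
  if (!is.finite(t_best)) return(t_best)
  if (best < nrow(roc)) (t_best + roc$threshold[best + 1]) / 2 else t_best
}

#' Aggregate per-fold evaluation results
#'
#' Arithmetic mean and population standard deviation (divide by k, the
#' fold-count convention used here) of each metric over folds, excluding
#' undefined (`NA`) per-fold values with a logged count, plus the
#' arithmetic average of the confusion matrices (fractional cells are
#' expected).
#'
#' @param per_fold List of lists, each with elements `counts`
#'   (`confusion_counts`) and `metrics` (`metrics_report`).
#' @return A list: `metrics` (data.frame metric/mean/sd/n_defined),
#'   `confusion` (averaged `confusion_counts`).
#' @export
aggregate_folds <- function(per_fold) {
  if (length(per_fold) == 0) {
    stop("aggregate_folds: no folds supplied", call. = FALSE)
  }
  metric_names <- c("accuracy", "precision", "recall", "f1", "specificity",
                    "auroc")
  rows <- lapply(metric_names, function(m) {
    vals <- vapply(per_fold, function(f) {
      v <- f$metrics[[m]]
      if (is.null(v)) NA_real_ else v
    }, numeric(1))
    ok <- !is.na(vals)
    mu <- if (any(ok)) mean(vals[ok]) else NA_real_
    sd_pop <- if (any(ok)) sqrt(mean((vals[ok] - mu)^2)) else NA_real_
    data.frame(metric = m, mean = mu, sd = sd_pop, n_defined = sum(ok))
  })
  avg <- function(cell) mean(vapply(per_fold,
                                    function(f) f$counts[[cell]],
                                    numeric(1)))
  list(metrics = do.call(rbind, rows),
       confusion = confusion_counts(tp = avg("tp"), fp = avg("fp"),
                                    fn = avg("fn"), tn = avg("tn")))
}
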