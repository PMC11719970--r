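# Confusion-matrix metrics (accuracy, precision, recall, MCC, F1; macro
# variants for the four-class task), ROC construction, and the
# TPR - FPR (Youden J) threshold-selection rule.
#
# Degenerate-denominator policy: any metric whose denominator is zero is
# reported as 0 and listed in the `degenerate` attribute, so reports stay
# total instead of propagating NaN.

#' Binary confusion counts
#'
#' Class 1 is the positive ("disease") class.
#'
#' @param y_true,y_pred Equal-length vectors with values in `{0, 1}`.
#' @return List with integer fields `tp`, `fp`, `fn`, `tn`.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stopf("label vectors differ in length")
  if (length(y_true) < 1L) stopf("need at least one sample")
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (!all(y_true %in% c(0L, 1L)) || !all(y_pred %in% c(0L, 1L))) {
    stopf("labels must be binary 0/1")
  }
  list(tp = sum(y_true == 1L & y_pred == 1L),
       fp = sum(y_true == 0L & y_pred == 1L),
       fn = sum(y_true == 1L & y_pred == 0L),
       tn = sum(y_true == 0L & y_pred == 0L))
}

safe_div <- function(num, den) if (den == 0) NA_real_ else num / den

#' Binary classification metrics from confusion counts
#'
#' Accuracy, precision, recall, F1 and the Matthews correlation coefficient
#' `(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`.
#'
#' @param cm Confusion counts from [confusion()].
#' @return Named numeric vector `accuracy`, `precision`, `recall`, `f1`,
#'   `mcc`, with a `degenerate` attribute naming any zero-denominator
#'   metrics (reported as 0).
#' @export
binary_metrics <- function(cm) {
  tp <- cm$tp; fp <- cm$fp; fn <- cm$fn; tn <- cm$tn
  n <- tp + fp + fn + tn
  if (n <= 0) stopf("empty confusion counts")
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    NA_real_
  } else {
    2 * precision * recall / (precision + recall)
  }
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den == 0) NA_real_ else (tp * tn - fp * fn) / mcc_den
  out <- c(accuracy = (tp + tn) / n, precision = precision, recall = recall,
           f1 = f1, mcc = mcc)
  degenerate <- names(out)[is.na(out)]
  out[is.na(out)] <- 0
  attr(out, "degenerate") <- degenerate
  out
}

#' Multi-class metrics with macro averaging
#'
#' Accuracy is the fraction correct; precision, recall and F1 are
#' macro-averaged one-vs-rest, with undefined per-class terms counted as 0
#' and flagged.
#'
#' @param y_true,y_pred Label vectors drawn from `classes`.
#' @param classes Class label set (defaults to the labels present).
#' @return Named numeric vector `accuracy`, `precision`, `recall`, `f1`
#'   (macro), with a `degenerate` attribute listing flagged per-class terms.
#' @export
multiclass_metrics <- function(y_true, y_pred,
                               classes = sort(unique(c(y_true, y_pred)))) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred)) stopf("label vectors differ in length")
  unknown <- setdiff(unique(c(y_true, y_pred)), as.character(classes))
  if (length(unknown) > 0L) stopf("unknown label '%s'", unknown[1L])
  degenerate <- character(0)
  per <- lapply(classes, function(cl) {
    m <- binary_metrics(confusion(as.integer(y_true == cl),
                                  as.integer(y_pred == cl)))
    if (length(attr(m, "degenerate")) > 0L) {
      degenerate <<- c(degenerate,
                       paste0(cl, ":", attr(m, "degenerate")))
    }
    m
  })
  out <- c(accuracy = mean(y_true == y_pred),
           precision = mean(vapply(per, `[[`, 0, "precision")),
           recall = mean(vapply(per, `[[`, 0, "recall")),
           f1 = mean(vapply(per, `[[`, 0, "f1")))
  attr(out, "degenerate") <- degenerate
  out
}

#' ROC-based threshold selection maximizing TPR - FPR
#'
#' Candidate thresholds are midpoints between consecutive distinct sorted
#' scores plus sentinels below the minimum and above the maximum. The
#' classification rule is `score > threshold -> 1`; among candidates with
#' equal TPR - FPR the largest threshold (fewest positives) wins, so the
#' returned J is never negative (the above-max sentinel gives J = 0).
#'
#' @param scores Numeric prediction scores in `[0, 1]`.
#' @param y_true Binary labels, both classes present.
#' @return List `threshold`, `tpr`, `fpr`, `j` (= tpr - fpr).
#' @export
roc_and_threshold <- function(scores, y_true) {
  y_true <- as.integer(y_true)
  if (length(scores) != length(y_true)) stopf("scores/labels length mismatch")
  if (!all(y_true %in% c(0L, 1L)) || length(unique(y_true)) < 2L) {
    stopf("need binary labels with both classes present")
  }
  s <- sort(unique(scores))
  eps <- 1e-8
  candidates <- c(s[1L] - eps,
                  if (length(s) > 1L) (head(s, -1L) + tail(s, -1L)) / 2,
                  s[length(s)] + eps)
  n_pos <- sum(y_true == 1L); n_neg <- sum(y_true == 0L)
  best <- NULL
  for (thr in candidates) {
    pred <- scores > thr
    tpr <- sum(pred & y_true == 1L) / n_pos
    fpr <- sum(pred & y_true == 0L) / n_neg
    j <- tpr - fpr
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 && thr > best$threshold)) {
      best <- list(threshold = thr, tpr = tpr, fpr = fpr, j = j)
    }
  }
  best
}
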