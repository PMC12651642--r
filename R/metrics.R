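# Confusion-matrix metrics: accuracy, per-class one-vs-rest precision /
# recall / F1 / MCC, macro and micro averages, and the generalized multiclass
# MCC from the full contingency table.

#' Confusion counts from predictions
#'
#' Builds the class-by-class contingency table (rows = truth, columns =
#' prediction) and the per-class one-vs-rest TP/TN/FP/FN counts derived from
#' it.
#'
#' @param truth true class vector.
#' @param pred predicted class vector (same length; levels are unioned).
#' @return a `confusion_counts`: list with `table` and `per_class`
#'   (data.frame of TP/TN/FP/FN per class).
#' @export
confusion_counts <- function(truth, pred) {
  levs <- union(levels(factor(truth)), levels(factor(pred)))
  truth <- factor(truth, levels = levs)
  pred <- factor(pred, levels = levs)
  if (length(truth) != length(pred) || length(truth) == 0)
    thal_error("thal_argument_error", "truth and pred must be equal-length, non-empty")
  tab <- table(truth = truth, pred = pred)
  per <- data.frame(class = levs,
                    tp = NA_real_, tn = NA_real_, fp = NA_real_, fn = NA_real_)
  n <- sum(tab)
  for (i in seq_along(levs)) {
    tp <- tab[i, i]
    fp <- sum(tab[, i]) - tp
    fn <- sum(tab[i, ]) - tp
    per$tp[i] <- tp; per$fp[i] <- fp; per$fn[i] <- fn
    per$tn[i] <- n - tp - fp - fn
  }
  structure(list(table = tab, per_class = per), class = "confusion_counts")
}

safe_div <- function(num, den) if (den == 0) 0 else num / den

binary_mcc <- function(tp, tn, fp, fn) {
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) 0 else (tp * tn - fp * fn) / sqrt(den)
}

#' Metric suite from confusion counts
#'
#' Computes accuracy, per-class one-vs-rest precision, recall, F1 and MCC,
#' and their macro (and micro) averages. The overall MCC uses the generalized
#' contingency-table form, which reduces to the familiar binary formula for
#' two classes. Zero denominators yield 0 and are flagged
#' (`zero_denominator` attribute), following the usual convention for
#' degenerate all-one-class predictions.
#'
#' @param confusion a `confusion_counts` from [confusion_counts()].
#' @param average `"macro"` (default) or `"micro"` for the headline
#'   precision/recall/F1.
#' @return a `metrics_report`: list with `accuracy`, `precision`, `recall`,
#'   `f1`, `mcc`, `per_class` (data.frame), `average`, `zero_denominator`.
#' @export
compute_metrics <- function(confusion, average = c("macro", "micro")) {
  average <- match.arg(average)
  tab <- confusion$table
  per <- confusion$per_class
  n <- sum(tab)
  if (n == 0) thal_error("thal_argument_error", "empty confusion table")
  flagged <- FALSE
  per$precision <- per$recall <- per$f1 <- per$mcc <- NA_real_
  for (i in seq_len(nrow(per))) {
    tp <- per$tp[i]; tn <- per$tn[i]; fp <- per$fp[i]; fn <- per$fn[i]
    if (tp + fp == 0 || tp + fn == 0) flagged <- TRUE
    per$precision[i] <- safe_div(tp, tp + fp)
    per$recall[i] <- safe_div(tp, tp + fn)
    per$f1[i] <- safe_div(2 * per$precision[i] * per$recall[i],
                          per$precision[i] + per$recall[i])
    if ((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn) == 0) flagged <- TRUE
    per$mcc[i] <- binary_mcc(tp, tn, fp, fn)
  }
  accuracy <- sum(diag(tab)) / n
  if (average == "macro") {
    precision <- mean(per$precision); recall <- mean(per$recall)
    f1 <- mean(per$f1)
  } else {
    tp <- sum(per$tp); fp <- sum(per$fp); fn <- sum(per$fn)
    precision <- safe_div(tp, tp + fp)
    recall <- safe_div(tp, tp + fn)
    f1 <- safe_div(2 * precision * recall, precision + recall)
  }
  # generalized multiclass MCC from the contingency table
  tvec <- rowSums(tab); pvec <- colSums(tab); s <- n; c_ <- sum(diag(tab))
  num <- c_ * s - sum(pvec * tvec)
  den <- sqrt(s^2 - sum(pvec^2)) * sqrt(s^2 - sum(tvec^2))
  mcc <- if (den == 0) { flagged <- TRUE; 0 } else num / den
  structure(list(accuracy = accuracy, precision = precision, recall = recall,
                 f1 = f1, mcc = mcc, per_class = per, average = average,
                 zero_denominator = flagged),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> acc=%.4f prec=%.4f rec=%.4f F1=%.4f MCC=%.4f (%s)\n",
              x$accuracy, x$precision, x$recall, x$f1, x$mcc, x$average))
  invisible(x)
}
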