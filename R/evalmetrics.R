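# Evaluation metrics: Dice overlap for segmentation, confusion-matrix
# metrics for classification, and a threshold-sweep ROC curve with
# trapezoidal AUC.

#' Dice coefficient between two binary masks
#'
#' `2|T intersect P| / (|T| + |P|)`. Two empty masks are defined to agree
#' perfectly (Dice 1), so correctly predicted all-background tiles score 1.
#'
#' @param t,p Binary (logical or 0/1 numeric) arrays of equal shape.
#' @return Scalar in `[0, 1]`.
#' @export
dice <- function(t, p) {
  stopifnot(all(dim(t) == dim(p) | is.null(dim(t)) & is.null(dim(p))))
  t <- as.logical(t); p <- as.logical(p)
  st <- sum(t); sp <- sum(p)
  if (st + sp == 0) return(1)
  2 * sum(t & p) / (st + sp)
}

#' Metrics derived from confusion counts
#'
#' Accuracy, sensitivity (recall), precision and F1. Ratios with a zero
#' denominator are reported as `NA` rather than substituted with 0, so
#' that cross-validation means are not biased by undefined folds.
#'
#' @param tp,tn,fp,fn Nonnegative integer counts; their total must be > 0.
#' @return Named list `accuracy`, `sensitivity`, `precision`, `f1`.
#' @export
confusion_metrics <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  if (tp + tn + fp + fn == 0) stop("all confusion counts are zero")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- ratio(tp, tp + fn)
  prec <- ratio(tp, tp + fp)
  f1 <- if (is.na(sens) || is.na(prec) || sens + prec == 0) NA_real_ else
    2 * prec * sens / (prec + sens)
  list(accuracy = (tp + tn) / (tp + tn + fp + fn),
       sensitivity = sens, precision = prec, f1 = f1)
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps thresholds over the unique scores (ties grouped), yielding ROC
#' points from (0,0) to (1,1) with nondecreasing FPR, and the trapezoidal
#' area under the curve.
#'
#' @param scores Numeric positive-class scores.
#' @param labels Truth, coerced to logical/0-1 or compared against
#'   `positive`.
#' @param positive The label counted as positive when `labels` is not
#'   already logical/0-1.
#' @return List with `roc` (data frame `fpr`, `tpr`, `threshold`) and
#'   `auc`.
#' @export
roc_auc <- function(scores, labels, positive = "malignant") {
  if (is.character(labels) || is.factor(labels))
    labels <- as.character(labels) == positive
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0 || nn == 0) stop("both classes must be present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  keep <- c(diff(s) != 0, TRUE)      # last index of each tied score block
  tpr <- cumsum(y)[keep] / np
  fpr <- cumsum(!y)[keep] / nn
  roc <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr),
                    threshold = c(Inf, s[keep]))
  auc <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
  list(roc = roc, auc = auc)
}

#' Assemble an evaluation report from predictions
#'
#' @param truth True labels (character/factor/logical).
#' @param pred Predicted labels, same coding as `truth`.
#' @param scores Optional positive-class scores; enables ROC/AUC.
#' @param dice Optional segmentation Dice value carried alongside.
#' @param positive Label treated as positive.
#' @return An `eval_report`: confusion counts, derived metrics, optional
#'   ROC points and AUC, optional Dice.
#' @export
eval_report <- function(truth, pred, scores = NULL, dice = NULL,
                        positive = "malignant") {
  tb <- as.character(truth) == positive
  pb <- as.character(pred) == positive
  counts <- list(tp = sum(tb & pb), tn = sum(!tb & !pb),
                 fp = sum(!tb & pb), fn = sum(tb & !pb))
  rep <- c(counts, confusion_metrics(counts$tp, counts$tn,
                                     counts$fp, counts$fn))
  if (!is.null(scores) && length(unique(tb)) == 2) {
    ra <- roc_auc(scores, tb)
    rep$roc <- ra$roc; rep$auc <- ra$auc
  }
  rep$dice <- dice
  structure(rep, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Evaluation report\n")
  cat(sprintf("  counts: TP=%d TN=%d FP=%d FN=%d\n", x$tp, x$tn, x$fp, x$fn))
  fmt <- function(v) if (is.null(v) || is.na(v)) "NA" else sprintf("%.4f", v)
  cat(sprintf("  accuracy=%s sensitivity=%s precision=%s f1=%s\n",
              fmt(x$accuracy), fmt(x$sensitivity), fmt(x$precision),
              fmt(x$f1)))
  if (!is.null(x$auc)) cat(sprintf("  auc=%s\n", fmt(x$auc)))
  if (!is.null(x$dice)) cat(sprintf("  dice=%s\n", fmt(x$dice)))
  invisible(x)
}
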