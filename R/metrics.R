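#' Confusion counts for binary predictions
#'
#' Standard 2x2 cross-tabulation with class 1 (inducing) as positive.
#'
#' @param labelsTrue,labelsPred equal-length vectors of 0/1 values.
#' @return named integer vector with \code{TP}, \code{TN}, \code{FP},
#'   \code{FN}.
#' @examples
#' confusionCounts(c(1, 1, 0, 0), c(1, 0, 0, 1))
#' @export
confusionCounts <- function(labelsTrue, labelsPred) {
  if (length(labelsTrue) != length(labelsPred) || length(labelsTrue) < 1)
    stop("labels must be non-empty vectors of equal length",
         call. = FALSE)
  if (anyNA(labelsTrue) || anyNA(labelsPred) ||
      !all(labelsTrue %in% c(0, 1)) || !all(labelsPred %in% c(0, 1)))
    stop("labels must be binary 0/1", call. = FALSE)
  c(TP = sum(labelsTrue == 1 & labelsPred == 1),
    TN = sum(labelsTrue == 0 & labelsPred == 0),
    FP = sum(labelsTrue == 0 & labelsPred == 1),
    FN = sum(labelsTrue == 1 & labelsPred == 0))
}

safeRatio <- function(num, den, what) {
  if (den == 0) {
    warning(what, " undefined (zero denominator); reporting 0",
            call. = FALSE)
    return(0)
  }
  num / den
}

#' Rank-based AUC (Mann-Whitney estimator)
#'
#' The probability that a uniformly random positive's score exceeds a
#' uniformly random negative's, with ties counted one-half; equal to
#' the trapezoidal area under the ROC curve.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labelsTrue 0/1 labels; both classes must be present.
#' @return AUC in [0, 1].
#' @export
aucScore <- function(scores, labelsTrue) {
  pos <- labelsTrue == 1
  nPos <- sum(pos); nNeg <- sum(!pos)
  if (nPos == 0 || nNeg == 0)
    stop("AUC requires both classes", call. = FALSE)
  r <- rank(scores)  # midranks handle ties with half credit
  (sum(r[pos]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' The seven evaluation statistics
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP), accuracy
#' (TP+TN)/total, MCC (TP*TN - FP*FN)/sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)),
#' precision TP/(TP+FP), F1 = 2*precision*recall/(precision+recall),
#' and rank-based AUC when scores are supplied.  Any ratio with a zero
#' denominator reports 0 with a warning (MCC likewise when a factor of
#' its denominator is 0, the standard convention).
#'
#' @param counts output of [confusionCounts()].
#' @param scores,labelsTrue optional score vector and true labels for
#'   AUC (omitted: AUC is \code{NA}).
#' @return named numeric vector: sensitivity, specificity, accuracy,
#'   mcc, precision, f1, auc.
#' @examples
#' computeMetrics(confusionCounts(c(1, 1, 0, 0), c(1, 0, 0, 1)))
#' @export
computeMetrics <- function(counts, scores = NULL, labelsTrue = NULL) {
  stopifnot(all(c("TP", "TN", "FP", "FN") %in% names(counts)))
  tp <- as.numeric(counts[["TP"]]); tn <- as.numeric(counts[["TN"]])
  fp <- as.numeric(counts[["FP"]]); fn <- as.numeric(counts[["FN"]])
  sens <- safeRatio(tp, tp + fn, "sensitivity")
  spec <- safeRatio(tn, tn + fp, "specificity")
  acc <- safeRatio(tp + tn, tp + tn + fp + fn, "accuracy")
  prec <- safeRatio(tp, tp + fp, "precision")
  mccDen <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (mccDen == 0) {
    warning("mcc undefined (zero denominator); reporting 0",
            call. = FALSE)
    0
  } else (tp * tn - fp * fn) / sqrt(mccDen)
  f1 <- if (prec + sens == 0) {
    warning("f1 undefined (zero denominator); reporting 0",
            call. = FALSE)
    0
  } else 2 * prec * sens / (prec + sens)
  auc <- if (is.null(scores)) NA_real_ else aucScore(scores, labelsTrue)
  c(sensitivity = sens, specificity = spec, accuracy = acc, mcc = mcc,
    precision = prec, f1 = f1, auc = auc)
}

#' ROC curve points
#'
#' Thresholds at every distinct score (descending), yielding a curve
#' that is monotone non-decreasing in both coordinates with endpoints
#' (0,0) and (1,1).  Its trapezoidal area equals [aucScore()] to within
#' numerical round-off.
#'
#' @param scores numeric scores.
#' @param labelsTrue 0/1 labels; both classes must be present.
#' @return data.frame with columns \code{fpr}, \code{tpr},
#'   \code{threshold} and attribute \code{"auc"} (trapezoidal area).
#' @export
rocCurve <- function(scores, labelsTrue) {
  nPos <- sum(labelsTrue == 1); nNeg <- sum(labelsTrue == 0)
  if (nPos == 0 || nNeg == 0)
    stop("ROC requires both classes", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labelsTrue[ord]
  lastOfGroup <- cumsum(rle(s)$lengths)  # last index of each distinct score
  tpr <- c(0, cumsum(y == 1)[lastOfGroup] / nPos, 1)
  fpr <- c(0, cumsum(y == 0)[lastOfGroup] / nNeg, 1)
  thr <- c(Inf, rle(s)$values, -Inf)
  df <- data.frame(fpr = fpr, tpr = tpr, threshold = thr)
  df <- df[!duplicated(df[c("fpr", "tpr")]), , drop = FALSE]
  rownames(df) <- NULL
  auc <- sum(diff(df$fpr) * (utils::head(df$tpr, -1) +
                               utils::tail(df$tpr, -1)) / 2)
  attr(df, "auc") <- auc
  df
}

#' Write a metrics report as JSON and an aligned text table
#'
#' @param metrics named numeric vector from [computeMetrics()].
#' @param jsonPath optional JSON output path.
#' @return the report as a one-row data.frame, invisibly writes JSON
#'   when \code{jsonPath} is given.
#' @export
metricsReport <- function(metrics, jsonPath = NULL) {
  df <- as.data.frame(as.list(metrics))
  if (!is.null(jsonPath))
    jsonlite::write_json(as.list(metrics), jsonPath, auto_unbox = TRUE,
                         digits = NA)
  df
}
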