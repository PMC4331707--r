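#' Select the decision threshold maximising training accuracy
#'
#' Scans candidate thresholds at the midpoints between consecutive distinct
#' sorted scores, plus -Inf/+Inf sentinels (classify-all-positive /
#' classify-all-negative), and returns the candidate with the highest
#' accuracy under the strict rule "positive iff score > threshold". Ties
#' are broken by the larger sensitivity + specificity, then by the smaller
#' threshold, so the result is deterministic and favours balanced errors.
#'
#' @param pos_scores,neg_scores Numeric training scores of the two classes.
#' @return The selected threshold (a single numeric).
#' @export
#' @examples
#' select_threshold(c(900, 800), c(100, 200))  # 500
select_threshold <- function(pos_scores, neg_scores) {
  np <- length(pos_scores); nn <- length(neg_scores)
  if (np == 0L || nn == 0L)
    stop("both classes must contribute scores to threshold selection")
  s <- sort(unique(c(pos_scores, neg_scores)))
  if (length(s) == 1L) {
    warning("all training scores identical; threshold is degenerate")
    return(s)
  }
  cand <- c(-Inf, (s[-1L] + s[-length(s)]) / 2, Inf)
  acc <- ss <- numeric(length(cand))
  for (i in seq_along(cand)) {
    sens <- mean(pos_scores > cand[i])
    spec <- mean(neg_scores <= cand[i])
    acc[i] <- (sens * np + spec * nn) / (np + nn)
    ss[i] <- sens + spec
  }
  best <- which(acc == max(acc))
  best <- best[ss[best] == max(ss[best])]
  cand[min(best)]
}

#' Classify sequences with a scoring card and threshold
#'
#' Scores each sequence by the card's weighted sum and labels it positive
#' iff its score strictly exceeds the threshold (a score equal to the
#' threshold is negative).
#'
#' @param scores Named numeric vector of 400 dipeptide scores.
#' @param seqs Character vector of query sequences.
#' @param threshold Decision threshold on the score scale.
#' @return Data frame with columns `id`, `score`, `label` (factor
#'   positive/negative).
#' @export
classify_sequences <- function(scores, seqs, threshold) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L)
  sc <- score_sequences(scores, seqs)
  ids <- if (is.null(names(seqs))) paste0("seq", seq_along(seqs)) else names(seqs)
  data.frame(id = ids, score = unname(sc),
             label = factor(ifelse(sc > threshold, "positive", "negative"),
                            levels = c("positive", "negative")),
             row.names = NULL)
}

# metrics from a confusion layout; MCC guarded at zero marginals
.confusion_metrics <- function(tp, fp, tn, fn) {
  n <- tp + fp + tn + fn
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den == 0) {
    warning("MCC undefined (zero marginal); reporting 0")
    0
  } else (tp * tn - fp * fn) / mcc_den
  list(accuracy = (tp + tn) / n,
       sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp),
       mcc = mcc)
}

#' Evaluate a scoring card on a labelled dataset
#'
#' Computes the confusion counts under the strict decision rule and the
#' standard binary metrics: accuracy, sensitivity, specificity, Matthews
#' correlation coefficient, and the rank-based ROC AUC (threshold-free).
#'
#' @param scores Named numeric vector of 400 dipeptide scores.
#' @param positives,negatives Sequences of the two classes.
#' @param threshold Decision threshold.
#' @return List of class `"scm_evaluation"` with elements `accuracy`,
#'   `sensitivity`, `specificity`, `mcc`, `auc`, `threshold`, and `counts`
#'   (named vector TP, FP, TN, FN).
#' @export
evaluate_card <- function(scores, positives, negatives, threshold) {
  if (length(positives) == 0L || length(negatives) == 0L)
    stop("evaluation requires sequences on both sides")
  sp <- score_sequences(scores, positives)
  sn <- score_sequences(scores, negatives)
  tp <- sum(sp > threshold); fn <- length(sp) - tp
  fp <- sum(sn > threshold); tn <- length(sn) - fp
  m <- .confusion_metrics(tp, fp, tn, fn)
  structure(c(m, list(auc = auc_rank(sp, sn), threshold = threshold,
                      counts = c(TP = tp, FP = fp, TN = tn, FN = fn))),
            class = "scm_evaluation")
}

#' @export
print.scm_evaluation <- function(x, ...) {
  cat("Scoring-card evaluation\n")
  cat(sprintf("  accuracy    : %.2f%%\n", 100 * x$accuracy))
  cat(sprintf("  sensitivity : %.4f\n", x$sensitivity))
  cat(sprintf("  specificity : %.4f\n", x$specificity))
  cat(sprintf("  MCC         : %.4f\n", x$mcc))
  cat(sprintf("  AUC         : %.4f\n", x$auc))
  cat(sprintf("  threshold   : %.4f\n", x$threshold))
  cat(sprintf("  counts      : TP=%d FP=%d TN=%d FN=%d\n",
              x$counts["TP"], x$counts["FP"], x$counts["TN"], x$counts["FN"]))
  invisible(x)
}

#' ROC curve points for two score sets
#'
#' Sweeps the decision threshold through every distinct score, from
#' classify-all-negative to classify-all-positive, and reports the
#' (FPR, TPR) pairs. Both coordinates are monotone non-decreasing, and the
#' trapezoidal area under the polyline equals the rank-based AUC (ties
#' contribute diagonal segments worth exactly 0.5 per tied pair).
#'
#' @param pos_scores,neg_scores Numeric score vectors.
#' @return Data frame with columns `threshold`, `fpr`, `tpr`, ordered from
#'   (0, 0) to (1, 1).
#' @export
roc_points <- function(pos_scores, neg_scores) {
  np <- length(pos_scores); nn <- length(neg_scores)
  if (np == 0L || nn == 0L) stop("both classes must contribute scores")
  cuts <- sort(unique(c(pos_scores, neg_scores)), decreasing = TRUE)
  tpr <- vapply(cuts, function(t) sum(pos_scores >= t), numeric(1L)) / np
  fpr <- vapply(cuts, function(t) sum(neg_scores >= t), numeric(1L)) / nn
  data.frame(threshold = c(Inf, cuts), fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Trapezoidal area under ROC points
#'
#' @param roc Data frame from [roc_points()].
#' @return Area under the curve.
#' @export
roc_auc_trapezoid <- function(roc) {
  sum(diff(roc$fpr) * (roc$tpr[-1L] + roc$tpr[-nrow(roc)]) / 2)
}
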