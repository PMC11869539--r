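#' Confusion counts for benign/malignant calls
#'
#' Tallies TP/TN/FP/FN with *malignant* as the positive class. The four
#' counts always partition the input.
#'
#' @param predicted,truth equal-length character/factor vectors of
#'   `"benign"` / `"malignant"`.
#' @return object of class `confusion_counts`: list with integers TP, TN,
#'   FP, FN.
#' @export
confusion <- function(predicted, truth) {
  predicted <- as.character(predicted); truth <- as.character(truth)
  if (length(predicted) != length(truth)) {
    stopf("predicted (%d) and truth (%d) lengths differ",
          length(predicted), length(truth))
  }
  bad <- setdiff(unique(c(predicted, truth)), c("benign", "malignant"))
  if (length(bad)) stopf("unknown labels: %s", paste(bad, collapse = ", "))
  pos <- "malignant"
  structure(list(TP = sum(predicted == pos & truth == pos),
                 TN = sum(predicted != pos & truth != pos),
                 FP = sum(predicted == pos & truth != pos),
                 FN = sum(predicted != pos & truth == pos)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP %d  TN %d  FP %d  FN %d\n",
              x$TP, x$TN, x$FP, x$FN))
  invisible(x)
}

#' Classification metrics from confusion counts
#'
#' All rates are percentages:
#' sensitivity = TP/(TP+FN), specificity = TN/(TN+FP),
#' precision = TP/(TP+FP), accuracy = (TP+TN)/total,
#' f_score = harmonic mean of precision and sensitivity (F1),
#' error_rate = 100 - accuracy. A metric whose denominator is zero is
#' reported as NA rather than raising an error.
#'
#' @param counts a `confusion_counts` (or list with TP, TN, FP, FN).
#' @return named numeric vector of the six rates, in percent.
#' @export
compute_metrics <- function(counts) {
  tp <- counts$TP; tn <- counts$TN; fp <- counts$FP; fn <- counts$FN
  if (any(c(tp, tn, fp, fn) < 0)) stopf("confusion counts must be >= 0")
  total <- tp + tn + fp + fn
  if (total == 0) stopf("all confusion counts are zero")
  rate <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  sens <- rate(tp, tp + fn)
  spec <- rate(tn, tn + fp)
  prec <- rate(tp, tp + fp)
  acc <- rate(tp + tn, total)
  f1 <- if (!is.na(sens) && !is.na(prec) && (sens + prec) > 0) {
    2 * prec * sens / (prec + sens)
  } else NA_real_
  c(sensitivity = sens, specificity = spec, precision = prec,
    accuracy = acc, f_score = f1, error_rate = 100 - acc)
}
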