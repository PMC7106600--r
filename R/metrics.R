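# Classification metrics derived from a confusion matrix
# (positive class = with_sb).

#' Build a confusion matrix from predictions
#'
#' @param truth,predicted Character vectors with values `with_sb` /
#'   `without_sb`.
#' @return An object of class `pvq_confusion`: list with integer counts
#'   `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_matrix <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  pos <- "with_sb"
  structure(list(
    tp = sum(truth == pos & predicted == pos),
    fp = sum(truth != pos & predicted == pos),
    fn = sum(truth == pos & predicted != pos),
    tn = sum(truth != pos & predicted != pos)
  ), class = "pvq_confusion")
}

#' The eleven-metric classification summary
#'
#' Computes, from confusion counts with `with_sb` as the positive class:
#' sensitivity tp/(tp+fn), specificity tn/(tn+fp), positive and negative
#' predictive value, precision (= PPV), recall (= sensitivity), F1 (their
#' harmonic mean), prevalence (tp+fn)/N, detection rate tp/N, detection
#' prevalence (tp+fp)/N, and balanced accuracy (sensitivity+specificity)/2.
#' A ratio with a zero denominator is reported as `NaN` with a warning,
#' never silently 0.
#'
#' @param cm A `pvq_confusion`, or a list/vector with components `tp`,
#'   `fp`, `fn`, `tn`.
#' @return A one-row tibble with the 11 metrics plus `n`.
#' @export
#' @examples
#' metrics(list(tp = 223, fp = 89, fn = 103, tn = 235))
metrics <- function(cm) {
  cm <- as.list(cm)
  tp <- cm$tp; fp <- cm$fp; fn <- cm$fn; tn <- cm$tn
  n <- tp + fp + fn + tn
  if (n == 0) rlang::abort("empty confusion matrix", class = "pvq_metric_error")
  safe_div <- function(num, den, what) {
    if (den == 0) {
      rlang::warn(paste0(what, " undefined (zero denominator)"))
      return(NaN)
    }
    num / den
  }
  sens <- safe_div(tp, tp + fn, "sensitivity")
  spec <- safe_div(tn, tn + fp, "specificity")
  ppv <- safe_div(tp, tp + fp, "pos_pred_value")
  npv <- safe_div(tn, tn + fn, "neg_pred_value")
  f1 <- if (is.nan(ppv) || is.nan(sens) || ppv + sens == 0) {
    rlang::warn("f1 undefined")
    NaN
  } else 2 * ppv * sens / (ppv + sens)
  tibble::tibble(
    sensitivity = sens, specificity = spec,
    pos_pred_value = ppv, neg_pred_value = npv,
    precision = ppv, recall = sens, f1 = f1,
    prevalence = (tp + fn) / n,
    detection_rate = tp / n,
    detection_prevalence = (tp + fp) / n,
    balanced_accuracy = (sens + spec) / 2,
    accuracy = (tp + tn) / n,
    n = n
  )
}
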