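#' Evaluation metrics from confusion counts
#'
#' Computes sensitivity, specificity, accuracy and the Matthews correlation
#' coefficient from error counts, parameterized the way jackknife reports are
#' tallied: `n_pos`/`n_neg` are the class totals, `fn` the positives predicted
#' negative, `fp` the negatives predicted positive. The formulas used are
#'
#' \deqn{Sn = 1 - FN/N^+,\quad Sp = 1 - FP/N^-,\quad
#'       Acc = 1 - (FN + FP)/(N^+ + N^-)}
#' \deqn{MCC = \frac{1 - (FN/N^+ + FP/N^-)}
#'   {\sqrt{(1 + (FP - FN)/N^+)\,(1 + (FN - FP)/N^-)}}}
#'
#' which agree exactly with the familiar TP/TN/FP/FN forms wherever both are
#' defined. Metrics whose denominator class is empty (or whose MCC
#' denominator vanishes) are reported as `NA`.
#'
#' @param n_pos,n_neg Total positive / negative samples.
#' @param fn Positives predicted negative. @param fp Negatives predicted
#'   positive.
#' @return A one-row tibble: `n_pos`, `n_neg`, `fn`, `fp`, `sn`, `sp`, `acc`,
#'   `mcc`.
#' @examples
#' metrics_from_counts(50, 40, fn = 7, fp = 5)
#' @export
metrics_from_counts <- function(n_pos, n_neg, fn, fp) {
  if (fn < 0 || fp < 0 || fn > n_pos || fp > n_neg) {
    abort("need 0 <= fn <= n_pos and 0 <= fp <= n_neg")
  }
  sn <- if (n_pos > 0) 1 - fn / n_pos else NA_real_
  sp <- if (n_neg > 0) 1 - fp / n_neg else NA_real_
  acc <- if (n_pos + n_neg > 0) 1 - (fn + fp) / (n_pos + n_neg) else NA_real_
  mcc <- NA_real_
  if (n_pos > 0 && n_neg > 0) {
    denom2 <- (1 + (fp - fn) / n_pos) * (1 + (fn - fp) / n_neg)
    if (denom2 > 0) {
      mcc <- (1 - (fn / n_pos + fp / n_neg)) / sqrt(denom2)
    }
  }
  tibble(n_pos = n_pos, n_neg = n_neg, fn = fn, fp = fp,
         sn = sn, sp = sp, acc = acc, mcc = mcc)
}

#' Metrics from predicted and true labels
#'
#' Tallies the confusion counts of binary predictions against truth and
#' forwards to [metrics_from_counts()].
#'
#' @param truth Logical/0-1 vector of true labels (1 = positive).
#' @param predicted Logical/0-1 vector of predicted labels.
#' @return One-row metric tibble (see [metrics_from_counts()]).
#' @export
metrics_from_predictions <- function(truth, predicted) {
  truth <- as.integer(as.logical(truth))
  predicted <- as.integer(as.logical(predicted))
  stopifnot(length(truth) == length(predicted))
  metrics_from_counts(
    n_pos = sum(truth == 1), n_neg = sum(truth == 0),
    fn = sum(truth == 1 & predicted == 0),
    fp = sum(truth == 0 & predicted == 1)
  )
}
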