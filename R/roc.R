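#' ROC curve and area under it
#'
#' Computes the receiver operating characteristic of continuous scores
#' against binary labels. The area is the Mann-Whitney U statistic normalized
#' by `n_pos * n_neg` — the probability that a random positive outscores a
#' random negative, with ties counted 0.5 — computed from midranks, so it is
#' exact under ties. Curve points are returned at every distinct score
#' threshold (plus the (0,0) and (1,1) endpoints); trapezoidal integration of
#' the curve reproduces the area.
#'
#' @param scores Numeric prediction scores (higher = more positive).
#' @param labels Binary truth (logical or 0/1); both classes must be present.
#' @return An object of class `roc_result`: list with `auc` and `curve`
#'   (tibble `threshold`, `fpr`, `tpr`).
#' @examples
#' roc_auc(c(.9, .8, .3, .2), c(1, 1, 0, 0))$auc  # 1
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(labels))
  if (any(!is.finite(scores))) abort("scores must be finite")
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    abort("both classes must be present to compute a ROC curve")
  }
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  # cumulative counts at each distinct threshold (predict positive if
  # score >= threshold)
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(l)[last_of_tie]
  fp <- cumsum(1 - l)[last_of_tie]
  curve <- tibble(
    threshold = c(Inf, s[last_of_tie]),
    fpr = c(0, fp / n_neg),
    tpr = c(0, tp / n_pos)
  )
  structure(list(auc = auc, curve = curve, n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: auROC = %.4f (%d positive, %d negative)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
tidy.roc_result <- function(x, ...) x$curve

#' @export
glance.roc_result <- function(x, ...) {
  tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @rdname roc_auc
#' @param object A `roc_result`.
#' @param ... Ignored.
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate (1 - Sp)", y = "True positive rate (Sn)",
      title = sprintf("auROC = %.4f", object$auc)
    )
}
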