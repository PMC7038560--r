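#' Stratified cross-validation fold assignment
#'
#' Assigns each sample to one of `folds` folds, stratified by class so every
#' fold carries a near-equal share of positives and negatives. Deterministic
#' under `seed`.
#'
#' @param y Binary label vector (0/1 or logical).
#' @param folds Number of folds (>= 2).
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1..folds`, one per sample.
#' @export
make_folds <- function(y, folds = 10L, seed) {
  y <- as.integer(as.logical(y))
  if (folds < 2) abort("folds must be >= 2")
  if (min(sum(y == 1), sum(y == 0)) < folds) {
    abort(sprintf("folds (%d) exceeds the size of the smaller class (%d)",
                  folds, min(sum(y == 1), sum(y == 0))))
  }
  assignment <- integer(length(y))
  withr::with_seed(seed, {
    for (cls in c(0L, 1L)) {
      idx <- which(y == cls)
      assignment[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  assignment
}

#' Cheap logistic-regression trainer
#'
#' A trainer suitable for fast incremental-feature-selection sweeps and unit
#' tests: ridge-free `glm` logistic fit with probability predictions. Any
#' trainer is a function `f(X, y)` returning an object whose
#' `predict_scores(model, X)` gives scores in \[0, 1\].
#'
#' @return A trainer function.
#' @export
glm_trainer <- function() {
  function(X, y) {
    df <- as.data.frame(X)
    colnames(df) <- paste0("V", seq_len(ncol(df)))
    fit <- suppressWarnings(
      stats::glm(y ~ ., data = cbind(df, y = y), family = stats::binomial())
    )
    structure(list(fit = fit, p = ncol(X)), class = "sixma_glm")
  }
}

#' Score new samples with a fitted trainer model
#' @param model Object returned by a trainer. @param X Feature matrix.
#' @return Numeric scores in \[0, 1\].
#' @export
predict_scores <- function(model, X) UseMethod("predict_scores")

#' @export
predict_scores.sixma_glm <- function(model, X) {
  df <- as.data.frame(X)
  colnames(df) <- paste0("V", seq_len(ncol(df)))
  suppressWarnings(unname(predict(model$fit, newdata = df, type = "response")))
}

#' Cross-validated accuracy of a trainer under fixed folds
#'
#' Pooled held-out accuracy at a 0.5 score threshold (boundary classified
#' positive) for a precomputed fold assignment — the shared building block
#' of [ifs_select()] and [grid_search()].
#'
#' @param X Numeric feature matrix. @param y Binary labels.
#' @param fold_id Fold assignment from [make_folds()].
#' @param trainer Trainer function (see [glm_trainer()], [xgb_trainer()]).
#' @param threshold Score threshold for calling a positive.
#' @param feature_builder Optional `f(train_idx)` rebuilding the full matrix
#'   with fit-from-data encoders restricted to training rows.
#' @param columns Optional feature-name subset used for training/scoring.
#' @return Pooled accuracy in \[0, 1\].
#' @export
cv_accuracy <- function(X, y, fold_id, trainer, threshold = 0.5,
                        feature_builder = NULL, columns = NULL) {
  correct <- 0L
  for (f in sort(unique(fold_id))) {
    test_idx <- which(fold_id == f)
    train_idx <- which(fold_id != f)
    Xf <- if (is.null(feature_builder)) X else feature_builder(train_idx)
    if (!is.null(columns)) Xf <- Xf[, columns, drop = FALSE]
    model <- trainer(Xf[train_idx, , drop = FALSE], y[train_idx])
    s <- predict_scores(model, Xf[test_idx, , drop = FALSE])
    correct <- correct + sum((s >= threshold) == (y[test_idx] == 1))
  }
  correct / length(y)
}
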