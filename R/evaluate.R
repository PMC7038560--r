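# Encode the training-independent feature blocks (EIIP + physicochemical)
# once; only the PSTNP blocks depend on which rows are in the training fold.
static_feature_blocks <- function(seqs, prop_table, lam) {
  t(vapply(seqs, function(s) {
    c(eiip_features(s), physicochemical_features(s, prop_table, lam))
  }, numeric(64L + lam * (ncol(prop_table) - 1L))))
}

pstnp_feature_blocks <- function(seqs, model) {
  t(vapply(seqs, function(s) {
    c(pstnp_features(s, model, "ss"), pstnp_features(s, model, "ds"))
  }, numeric(2L * (model$L - 2L))))
}

#' Cross-validated or jackknife evaluation of the full pipeline
#'
#' Evaluates end-to-end prediction of 6mA status: within every fold the PSTNP
#' propensity matrices are refitted on the fold's training samples only (the
#' leak-free protocol; `refit_pstnp = FALSE` mimics whole-dataset fitting),
#' all samples are encoded, a boosted-tree model is trained on the training
#' rows, and the held-out rows are scored. Held-out scores are pooled over
#' folds, then thresholded for the confusion metrics and used raw for the
#' ROC. `folds = NULL` gives the jackknife (leave-one-out) test; a small
#' fold count is the documented fast mode for desk-scale runs.
#'
#' @param positives,negatives Sample tibbles (`id`, `seq`) or character
#'   vectors of equal-length windows.
#' @param params [hyper_params()] for the boosted trees.
#' @param folds Number of stratified CV folds, or `NULL` for leave-one-out.
#' @param seed Integer seed (fold assignment; ignored for leave-one-out).
#' @param refit_pstnp Refit PSTNP inside each fold (default) or fit once on
#'   all data.
#' @param selected_features Optional feature-name subset.
#' @param threshold Decision threshold (default 0.5, boundary positive).
#' @param lam,prop_table Encoder configuration.
#' @return An object of class `sixma_eval`: list with `metrics` (one-row
#'   tibble: sn, sp, acc, mcc, auroc), `roc` ([roc_auc()] result), `scores`
#'   (tibble `id`, `label`, `score`, `fold`), `folds`.
#' @export
evaluate_cv <- function(positives, negatives, params = hyper_params(),
                        folds = 10L, seed = 1L, refit_pstnp = TRUE,
                        selected_features = NULL, threshold = 0.5,
                        lam = 5L, prop_table = dinuc_properties()) {
  pos <- if (is.data.frame(positives)) positives else tibble(id = paste0("pos", seq_along(positives)), seq = positives)
  neg <- if (is.data.frame(negatives)) negatives else tibble(id = paste0("neg", seq_along(negatives)), seq = negatives)
  samples <- bind_rows(mutate(pos, label = "positive"),
                       mutate(neg, label = "negative"))
  seqs <- toupper(samples$seq)
  y <- as.integer(samples$label == "positive")
  n <- length(y)
  if (n < 3) abort("need at least 3 samples")
  if (!is.null(folds) && folds > n) abort("folds cannot exceed the sample count")
  fold_id <- if (is.null(folds) || folds == n) seq_len(n) else make_folds(y, folds, seed)

  static <- static_feature_blocks(seqs, prop_table, lam)
  full_model <- fit_pstnp(seqs[y == 1], seqs[y == 0])
  full_pstnp <- pstnp_feature_blocks(seqs, full_model)

  scores <- numeric(n)
  for (f in sort(unique(fold_id))) {
    test_idx <- which(fold_id == f)
    train_idx <- which(fold_id != f)
    if (refit_pstnp) {
      m <- fit_pstnp(seqs[intersect(train_idx, which(y == 1))],
                     seqs[intersect(train_idx, which(y == 0))])
      pstnp <- pstnp_feature_blocks(seqs, m)
    } else {
      pstnp <- full_pstnp
    }
    X <- cbind(static[, 1:64, drop = FALSE], pstnp,
               static[, -(1:64), drop = FALSE])
    if (!is.null(selected_features)) {
      X <- X[, selected_features, drop = FALSE]
    }
    booster <- fit_booster(X[train_idx, , drop = FALSE], y[train_idx], params)
    scores[test_idx] <- booster_scores(booster, X[test_idx, , drop = FALSE])
  }

  predicted <- as.integer(scores >= threshold)
  metrics <- metrics_from_predictions(y, predicted)
  roc <- roc_auc(scores, y)
  structure(
    list(
      metrics = bind_cols(metrics, tibble(auroc = roc$auc)),
      roc = roc,
      scores = tibble(id = samples$id, label = samples$label,
                      score = scores, fold = fold_id),
      folds = if (is.null(folds)) n else folds
    ),
    class = "sixma_eval"
  )
}

#' Jackknife (leave-one-out) evaluation
#'
#' The jackknife test: every sample is held out once and predicted by a model
#' trained — PSTNP refit included — on the remaining n - 1 samples.
#' Equivalent to [evaluate_cv()] with `folds = NULL`.
#'
#' @inheritParams evaluate_cv
#' @return A `sixma_eval` (see [evaluate_cv()]).
#' @export
jackknife <- function(positives, negatives, params = hyper_params(),
                      refit_pstnp = TRUE, selected_features = NULL,
                      threshold = 0.5, lam = 5L,
                      prop_table = dinuc_properties()) {
  evaluate_cv(positives, negatives, params = params, folds = NULL,
              refit_pstnp = refit_pstnp,
              selected_features = selected_features, threshold = threshold,
              lam = lam, prop_table = prop_table)
}

#' @export
print.sixma_eval <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "Evaluation (%d folds): Sn %.4f, Sp %.4f, Acc %.4f, MCC %.4f, auROC %.4f\n",
    x$folds, m$sn, m$sp, m$acc, m$mcc, m$auroc
  ))
  invisible(x)
}

#' @export
tidy.sixma_eval <- function(x, ...) x$scores

#' @export
glance.sixma_eval <- function(x, ...) x$metrics
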