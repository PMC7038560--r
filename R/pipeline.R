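#' Full training pipeline: encode, rank, select, tune, fit
#'
#' Runs the complete model-building recipe on labeled windows: fit the PSTNP
#' propensity matrices, encode all samples (172 features for defaults), rank
#' features by the maximum-relevance maximum-distance score, choose the
#' optimal prefix by incremental feature selection under cross-validated
#' accuracy, tune gamma/eta/max_depth by grid search on the selected
#' features, and fit the final boosted-tree predictor. Deterministic under
#' `seed`.
#'
#' @param positives,negatives Sample tibbles (`id`, `seq`) of equal-length
#'   windows.
#' @param folds CV folds for IFS and grid search. @param seed Integer seed.
#' @param grid Hyperparameter grid ([coarse_grid()] by default).
#' @param n_rounds Boosting rounds. @param threshold Decision threshold.
#' @param max_k Cap on IFS prefix sizes (default: all features); IFS cost
#'   grows linearly in this cap.
#' @param ifs_trainer Trainer used inside the IFS sweep; default
#'   [xgb_trainer()] with default parameters (tuning happens after
#'   selection).
#' @param lam,prop_table Encoder configuration.
#' @return A list of class `sixma_pipeline`: `predictor`, `ranking`, `ifs`,
#'   `grid`, `pstnp_model`, `features`, `seed`.
#' @export
train_pipeline <- function(positives, negatives, folds = 10L, seed = 1L,
                           grid = coarse_grid(), n_rounds = 100L,
                           threshold = 0.5, max_k = NULL,
                           ifs_trainer = NULL, lam = 5L,
                           prop_table = dinuc_properties()) {
  if (nrow(positives) == 0 || nrow(negatives) == 0) {
    abort("both classes must be non-empty")
  }
  samples <- bind_rows(mutate(positives, label = "positive"),
                       mutate(negatives, label = "negative"))
  samples$seq <- toupper(samples$seq)
  pstnp <- fit_pstnp(samples$seq[samples$label == "positive"],
                     samples$seq[samples$label == "negative"])
  features <- featurize(samples, pstnp, prop_table = prop_table, lam = lam)
  ranking <- mrmd_rank(features)
  if (is.null(ifs_trainer)) {
    ifs_trainer <- xgb_trainer(hyper_params(n_rounds = n_rounds, seed = seed))
  }
  ifs <- ifs_select(ranking, features, folds = folds, seed = seed,
                    trainer = ifs_trainer, max_k = max_k)
  gs <- grid_search(features[c("label", ifs$selected_features)],
                    grid = grid, folds = folds, seed = seed,
                    n_rounds = n_rounds)
  predictor <- train(features, params = gs$best, pstnp_model = pstnp,
                     selected_features = ifs$selected_features,
                     threshold = threshold, lam = lam,
                     prop_table = prop_table)
  structure(
    list(predictor = predictor, ranking = ranking, ifs = ifs, grid = gs,
         pstnp_model = pstnp, features = features, seed = seed),
    class = "sixma_pipeline"
  )
}

#' @export
print.sixma_pipeline <- function(x, ...) {
  cat("6mA training pipeline\n")
  print(x$ifs)
  print(x$grid)
  print(x$predictor)
  invisible(x)
}

#' @export
glance.sixma_pipeline <- function(x, ...) {
  bind_cols(
    tibble(selected_k = x$ifs$selected_k,
           ifs_accuracy = x$ifs$curve$accuracy[x$ifs$selected_k]),
    glance(x$grid)[c("gamma", "eta", "max_depth", "best_accuracy")],
    tibble(seed = x$seed)
  )
}
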