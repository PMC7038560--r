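#' Incremental feature selection over a ranked list
#'
#' Starting from an MRMD-style ranking, adds features one at a time in rank
#' order and evaluates each prefix by stratified k-fold cross-validated
#' accuracy (fixed seed, shared folds across prefixes). The selected prefix
#' size is the one with the highest accuracy; ties go to the smallest
#' prefix.
#'
#' @param ranking An [mrmd_rank()] result (or any tibble with a `feature`
#'   column in rank order).
#' @param features Feature tibble (with `label`) or numeric matrix.
#' @param y Binary labels; taken from `features$label` when absent.
#' @param folds CV folds (default 10). @param seed Integer seed.
#' @param trainer Trainer function (see [glm_trainer()]); defaults to the
#'   gradient-boosted trainer [xgb_trainer()].
#' @param max_k Evaluate prefixes `1..max_k` only (default: all ranked
#'   features).
#' @param feature_builder Optional function `f(train_idx)` returning the full
#'   n-x-p feature matrix rebuilt so that fit-from-data encoders (the PSTNP
#'   propensities) use only the training rows of the fold — the leak-free
#'   protocol. Default `NULL` uses `features` as given.
#' @return An object of class `ifs_result`: list with `curve` (tibble `k`,
#'   `accuracy`), `selected_k`, `selected_features`, `folds`, `seed`.
#' @export
ifs_select <- function(ranking, features, y = NULL, folds = 10L, seed,
                       trainer = xgb_trainer(), max_k = NULL,
                       feature_builder = NULL) {
  if (is.null(y)) {
    xy <- feature_xy(features)
    X <- xy$X
    y <- xy$y
    if (is.null(y)) abort("supply y or a 'label' column")
  } else {
    X <- as.matrix(features)
  }
  ranked <- ranking$feature
  if (is.null(ranked)) abort("ranking must have a 'feature' column")
  if (!all(ranked %in% colnames(X))) {
    abort("ranking names features absent from the feature matrix")
  }
  K <- if (is.null(max_k)) length(ranked) else min(max_k, length(ranked))
  fold_id <- make_folds(y, folds, seed)
  acc <- vapply(seq_len(K), function(k) {
    cv_accuracy(X, y, fold_id, trainer,
                feature_builder = feature_builder,
                columns = ranked[seq_len(k)])
  }, numeric(1))
  selected_k <- which.max(acc)  # which.max takes the first (smallest) maximum
  structure(
    list(
      curve = tibble(k = seq_len(K), accuracy = acc),
      selected_k = selected_k,
      selected_features = ranked[seq_len(selected_k)],
      folds = folds, seed = seed
    ),
    class = "ifs_result"
  )
}

#' @export
print.ifs_result <- function(x, ...) {
  cat(sprintf(
    "IFS: selected %d feature(s), CV accuracy %.4f (%d-fold, seed %d)\n",
    x$selected_k, x$curve$accuracy[x$selected_k], x$folds, x$seed
  ))
  invisible(x)
}

#' @export
tidy.ifs_result <- function(x, ...) x$curve

#' @export
glance.ifs_result <- function(x, ...) {
  tibble(selected_k = x$selected_k,
         best_accuracy = x$curve$accuracy[x$selected_k],
         folds = x$folds, seed = x$seed)
}

#' @rdname ifs_select
#' @param object An `ifs_result`. @param ... Ignored.
#' @export
autoplot.ifs_result <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(.data$k, .data$accuracy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = object$selected_k, linetype = "dashed",
                        colour = "red") +
    ggplot2::labs(x = "Number of top-ranked features",
                  y = "Cross-validated accuracy",
                  title = sprintf("IFS optimum: %d features", object$selected_k))
}
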