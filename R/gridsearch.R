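#' Hyperparameter grids
#'
#' `coarse_grid()` is the default tuning space: gamma in \{0, 0.1, 0.2\},
#' eta in \{0.1, 0.2, 0.3, 0.4, 0.5\}, max_depth in \{2, 4, 6, 8, 10\}
#' (75 combinations). `fine_grid()` is a much denser preset (gamma step
#' 0.002, eta step 0.05, depth step 1) for production-scale tuning.
#'
#' @return A tibble with columns `gamma`, `eta`, `max_depth`.
#' @export
coarse_grid <- function() {
  tidyr::expand_grid(gamma = c(0, 0.1, 0.2),
                     eta = seq(0.1, 0.5, by = 0.1),
                     max_depth = c(2L, 4L, 6L, 8L, 10L))
}

#' @rdname coarse_grid
#' @export
fine_grid <- function() {
  tidyr::expand_grid(gamma = seq(0, 0.2, by = 0.002),
                     eta = seq(0.1, 0.9, by = 0.05),
                     max_depth = 2:10)
}

#' Grid search over boosting hyperparameters
#'
#' Evaluates every grid point by stratified k-fold cross-validated accuracy
#' with one shared fold assignment (so the comparison across points is
#' paired and invariant to enumeration order), and returns the best point —
#' ties broken by smallest grid index — together with the full accuracy
#' table.
#'
#' @param features Feature tibble (with `label`) or numeric matrix.
#' @param y Binary labels; taken from `features$label` when absent.
#' @param grid Tibble of `gamma`, `eta`, `max_depth` combinations.
#' @param folds CV folds (default 10). @param seed Integer seed.
#' @param n_rounds Boosting rounds used at every grid point.
#' @return An object of class `grid_result`: list with `best`
#'   ([hyper_params()]), `table` (grid plus `accuracy`), `folds`, `seed`.
#' @export
grid_search <- function(features, y = NULL, grid = coarse_grid(), folds = 10L,
                        seed = 1L, n_rounds = 100L) {
  if (is.null(y)) {
    xy <- feature_xy(features)
    X <- xy$X
    y <- xy$y
    if (is.null(y)) abort("supply y or a 'label' column")
  } else {
    X <- as.matrix(features)
  }
  if (nrow(grid) == 0) abort("grid is empty")
  # validate the whole grid before any training
  for (i in seq_len(nrow(grid))) {
    hyper_params(gamma = grid$gamma[i], eta = grid$eta[i],
                 max_depth = grid$max_depth[i], n_rounds = n_rounds,
                 seed = seed)
  }
  fold_id <- make_folds(y, folds, seed)
  acc <- vapply(seq_len(nrow(grid)), function(i) {
    p <- hyper_params(gamma = grid$gamma[i], eta = grid$eta[i],
                      max_depth = grid$max_depth[i], n_rounds = n_rounds,
                      seed = seed)
    cv_accuracy(X, y, fold_id, xgb_trainer(p))
  }, numeric(1))
  best_i <- which.max(acc)
  structure(
    list(
      best = hyper_params(gamma = grid$gamma[best_i], eta = grid$eta[best_i],
                          max_depth = grid$max_depth[best_i],
                          n_rounds = n_rounds, seed = seed),
      table = mutate(grid, accuracy = acc),
      folds = folds, seed = seed
    ),
    class = "grid_result"
  )
}

#' @export
print.grid_result <- function(x, ...) {
  cat(sprintf(
    "Grid search: %d points, best accuracy %.4f at gamma %.3g, eta %.3g, depth %d\n",
    nrow(x$table), max(x$table$accuracy), x$best$gamma, x$best$eta,
    x$best$max_depth
  ))
  invisible(x)
}

#' @export
tidy.grid_result <- function(x, ...) x$table

#' @export
glance.grid_result <- function(x, ...) {
  tibble(gamma = x$best$gamma, eta = x$best$eta,
         max_depth = x$best$max_depth,
         best_accuracy = max(x$table$accuracy),
         n_points = nrow(x$table), folds = x$folds, seed = x$seed)
}

#' @rdname grid_search
#' @param object A `grid_result`. @param ... Ignored.
#' @export
autoplot.grid_result <- function(object, ...) {
  ggplot2::ggplot(
    object$table,
    ggplot2::aes(.data$eta, .data$accuracy, colour = factor(.data$max_depth))
  ) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~gamma, labeller = ggplot2::label_both) +
    ggplot2::labs(colour = "max_depth", y = "CV accuracy")
}
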