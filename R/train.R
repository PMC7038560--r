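#' Boosted-tree hyperparameters
#'
#' Container for the tuned gradient-boosting parameters. `gamma` (minimum
#' loss reduction to split), `eta` (learning rate) and `max_depth` are the
#' three parameters explored by [grid_search()]; `n_rounds` (boosting
#' iterations) defaults to the library-conventional 100. Training is
#' single-threaded and seeded so results are reproducible.
#'
#' @param gamma Non-negative split penalty. @param eta Learning rate in
#'   (0, 1\]. @param max_depth Maximum tree depth (>= 1). @param n_rounds
#'   Boosting iterations (>= 1). @param seed Integer seed.
#' @return A list of class `sixma_params`.
#' @export
hyper_params <- function(gamma = 0, eta = 0.3, max_depth = 6L,
                         n_rounds = 100L, seed = 1L) {
  if (gamma < 0) abort("gamma must be >= 0")
  if (eta <= 0 || eta > 1) abort("eta must be in (0, 1]")
  if (max_depth < 1) abort("max_depth must be >= 1")
  if (n_rounds < 1) abort("n_rounds must be >= 1")
  structure(list(gamma = gamma, eta = eta, max_depth = as.integer(max_depth),
                 n_rounds = as.integer(n_rounds), seed = as.integer(seed)),
            class = "sixma_params")
}

fit_booster <- function(X, y, params) {
  dtrain <- xgboost::xgb.DMatrix(data = X, label = y, nthread = 1)
  xgboost::xgb.train(
    params = list(
      objective = "binary:logistic",
      gamma = params$gamma, eta = params$eta, max_depth = params$max_depth,
      nthread = 1, seed = params$seed
    ),
    data = dtrain, nrounds = params$n_rounds, verbose = 0
  )
}

booster_scores <- function(booster, X) {
  as.numeric(predict(booster, xgboost::xgb.DMatrix(X, nthread = 1)))
}

#' Gradient-boosted trainer for CV sweeps
#'
#' Wraps the boosted-tree fit behind the trainer interface used by
#' [ifs_select()] and [cv_accuracy()]-style loops: a function `f(X, y)`
#' returning an object scored by [predict_scores()].
#'
#' @param params [hyper_params()].
#' @return A trainer function.
#' @export
xgb_trainer <- function(params = hyper_params()) {
  function(X, y) {
    structure(list(booster = fit_booster(X, y, params)), class = "sixma_xgb")
  }
}

#' @export
predict_scores.sixma_xgb <- function(model, X) {
  booster_scores(model$booster, as.matrix(X))
}

#' Train a 6mA predictor on encoded features
#'
#' Fits the gradient-boosted ensemble on a feature matrix and packages it
#' with everything needed to score raw 41-nt windows end-to-end: the fitted
#' PSTNP propensity model, the encoder configuration, the selected feature
#' names and the decision threshold.
#'
#' @param features Feature tibble from [featurize()] (with `label`), or a
#'   numeric matrix if `y` is given.
#' @param y Binary labels (0/1); taken from `features$label` when absent.
#' @param params [hyper_params()].
#' @param pstnp_model The [fit_pstnp()] model used to encode `features`
#'   (stored so the predictor can encode raw sequences).
#' @param selected_features Feature-name subset to train on (default: all
#'   feature columns).
#' @param threshold Decision threshold on the probability score; scores at or
#'   above it are called 6mA. Default 0.5.
#' @param lam,prop_table Encoder configuration (see
#'   [physicochemical_features()]).
#' @return An object of class `sixma_predictor`.
#' @export
train <- function(features, y = NULL, params = hyper_params(),
                  pstnp_model = NULL, selected_features = NULL,
                  threshold = 0.5, lam = 5L, prop_table = dinuc_properties()) {
  if (is.null(y)) {
    xy <- feature_xy(features)
    X <- xy$X
    y <- xy$y
    if (is.null(y)) abort("supply y or a 'label' column")
  } else {
    X <- as.matrix(features)
  }
  if (length(unique(y)) < 2) abort("labels are degenerate: one class only")
  if (threshold <= 0 || threshold >= 1) abort("threshold must be in (0, 1)")
  if (is.null(selected_features)) selected_features <- colnames(X)
  if (!all(selected_features %in% colnames(X))) {
    abort("selected_features must be a subset of the feature columns")
  }
  X <- X[, selected_features, drop = FALSE]
  booster <- fit_booster(X, y, params)
  structure(
    list(
      booster = booster,
      pstnp_model = pstnp_model,
      selected_features = selected_features,
      params = params,
      threshold = threshold,
      lam = as.integer(lam),
      prop_table = prop_table,
      n_train = length(y)
    ),
    class = "sixma_predictor"
  )
}

#' @export
print.sixma_predictor <- function(x, ...) {
  cat(sprintf(
    "6mA predictor: %d features, %d boosting rounds (eta %.3g, gamma %.3g, depth %d), threshold %.2f\n",
    length(x$selected_features), x$params$n_rounds, x$params$eta,
    x$params$gamma, x$params$max_depth, x$threshold
  ))
  invisible(x)
}

#' @export
glance.sixma_predictor <- function(x, ...) {
  tibble(
    n_features = length(x$selected_features), n_train = x$n_train,
    gamma = x$params$gamma, eta = x$params$eta,
    max_depth = x$params$max_depth, n_rounds = x$params$n_rounds,
    threshold = x$threshold
  )
}

#' @export
tidy.sixma_predictor <- function(x, ...) {
  imp <- xgboost::xgb.importance(model = x$booster)
  as_tibble(as.data.frame(imp)) |>
    rlang::set_names(tolower) |>
    select(feature = "feature", gain = "gain", cover = "cover",
           frequency = "frequency")
}

# Encode raw samples with the predictor's stored encoders, keeping only the
# selected features.
predictor_encode <- function(predictor, samples) {
  if (is.null(predictor$pstnp_model)) {
    abort("predictor has no stored PSTNP model; cannot encode raw sequences")
  }
  feats <- featurize(samples, predictor$pstnp_model,
                     prop_table = predictor$prop_table, lam = predictor$lam)
  as.matrix(feats[predictor$selected_features])
}

#' Score samples with a trained predictor
#'
#' @param object A `sixma_predictor`.
#' @param newdata Sample tibble (`id`, `seq`) or a precomputed feature
#'   tibble/matrix containing the selected feature columns.
#' @param type `"score"` for probabilities, `"label"` for thresholded calls.
#' @param ... Ignored.
#' @return Numeric scores in \[0, 1\] or character labels.
#' @export
predict.sixma_predictor <- function(object, newdata, type = c("score", "label"),
                                    ...) {
  type <- arg_match(type)
  X <- if (is.data.frame(newdata) && "seq" %in% names(newdata)) {
    predictor_encode(object, newdata)
  } else if (is.data.frame(newdata)) {
    as.matrix(newdata[object$selected_features])
  } else {
    as.matrix(newdata)[, object$selected_features, drop = FALSE]
  }
  s <- booster_scores(object$booster, X)
  if (type == "score") s else ifelse(s >= object$threshold, "6mA", "non-6mA")
}

#' Save / load a trained predictor
#'
#' Serializes the predictor as a single-file bundle: the boosted ensemble in
#' the library's raw UBJSON form plus all encoder state, under a versioned
#' format tag. A load followed by prediction reproduces scores bit-exactly.
#'
#' @param predictor A `sixma_predictor`. @param path Bundle file path.
#' @return `path` (save) / the predictor (load).
#' @export
save_predictor <- function(predictor, path) {
  bundle <- list(
    format = "sixmapred/1",
    booster_raw = xgboost::xgb.save.raw(predictor$booster),
    pstnp_model = predictor$pstnp_model,
    selected_features = predictor$selected_features,
    params = predictor$params,
    threshold = predictor$threshold,
    lam = predictor$lam,
    prop_table = predictor$prop_table,
    n_train = predictor$n_train
  )
  saveRDS(bundle, path)
  invisible(path)
}

#' @rdname save_predictor
#' @export
load_predictor <- function(path) {
  bundle <- readRDS(path)
  if (!identical(bundle$format, "sixmapred/1")) {
    abort("unrecognized predictor bundle format")
  }
  structure(
    list(
      booster = xgboost::xgb.load.raw(bundle$booster_raw),
      pstnp_model = bundle$pstnp_model,
      selected_features = bundle$selected_features,
      params = bundle$params,
      threshold = bundle$threshold,
      lam = bundle$lam,
      prop_table = bundle$prop_table,
      n_train = bundle$n_train
    ),
    class = "sixma_predictor"
  )
}
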