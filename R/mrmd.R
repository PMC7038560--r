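#' Rank features by a maximum-relevance maximum-distance score
#'
#' Scores every feature as the sum of a relevance term — the absolute Pearson
#' correlation between the feature and the binary label — and a distance term
#' — the mean distance between the feature's standardized column and every
#' other standardized column, divided by the maximum pairwise column distance
#' so the term is scale-free and bounded by 1. Features are returned sorted
#' by total score descending; ties are broken by original column order.
#' Constant features get relevance 0 (their standardized column is all
#' zeros), not an error.
#'
#' @param features Feature tibble from [featurize()] (with `label` column),
#'   or a bare numeric matrix/data frame if `y` is supplied.
#' @param y Binary labels (0/1); taken from `features$label` when absent.
#' @param distance_metric `"euclidean"` or `"cosine"` distance between
#'   standardized feature columns.
#' @return An object of class `mrmd_ranking`: tibble with columns `rank`,
#'   `feature`, `relevance`, `distance`, `score`.
#' @export
mrmd_rank <- function(features, y = NULL,
                      distance_metric = c("euclidean", "cosine")) {
  distance_metric <- arg_match(distance_metric)
  if (is.null(y)) {
    xy <- feature_xy(features)
    X <- xy$X
    y <- xy$y
    if (is.null(y)) abort("supply y or a 'label' column")
  } else {
    meta <- intersect(c("id", "label"), colnames(features))
    X <- as.matrix(as.data.frame(features)[setdiff(colnames(features), meta)])
  }
  y <- as.numeric(y)
  if (length(unique(y)) < 2) abort("labels must contain both classes")
  if (nrow(X) < 3) abort("need at least 3 samples")
  p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(p))

  # relevance: |Pearson(x_i, y)|; constant columns contribute 0
  relevance <- apply(X, 2, function(x) {
    if (sd(x) == 0) return(0)
    abs(cor(x, y))
  })

  # standardized columns (constant columns -> all-zero)
  Xs <- apply(X, 2, function(x) {
    s <- sd(x)
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  })

  if (p == 1) {
    distance <- 0
  } else {
    D <- switch(distance_metric,
      euclidean = as.matrix(stats::dist(t(Xs))),
      cosine = {
        nrm <- sqrt(colSums(Xs^2))
        nrm[nrm == 0] <- 1
        Xn <- sweep(Xs, 2, nrm, "/")
        1 - crossprod(Xn)
      }
    )
    diag(D) <- 0
    max_d <- max(D)
    if (max_d == 0) max_d <- 1
    distance <- rowSums(D) / (p - 1) / max_d
  }

  out <- tibble(
    feature = colnames(X),
    relevance = as.numeric(relevance),
    distance = as.numeric(distance),
    score = as.numeric(relevance) + as.numeric(distance)
  )
  # stable sort: ties resolved by original column order
  out <- out[order(-out$score), , drop = FALSE]
  out <- mutate(out, rank = row_number()) |>
    select("rank", "feature", "relevance", "distance", "score")
  class(out) <- c("mrmd_ranking", class(out))
  out
}

#' @export
tidy.mrmd_ranking <- function(x, ...) as_tibble(unclass(x))

#' Write an MRMD ranking as TSV
#' @param ranking An `mrmd_ranking`. @param path Output TSV.
#' @export
write_ranking <- function(ranking, path) {
  readr::write_tsv(as_tibble(unclass(ranking)), path)
  invisible(path)
}
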