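separable_features <- function(n = 40, seed = 1) {
  set.seed(seed)
  y <- rep(c(0, 1), n / 2)
  X <- cbind(x1 = y * 2 + rnorm(n, sd = 0.05), x2 = rnorm(n))
  list(X = X, y = y)
}

test_that("confusion metrics hit their closed forms at the extremes", {
  perfect <- metrics_from_counts(10, 10, fn = 0, fp = 0)
  expect_equal(unlist(perfect[c("sn", "sp", "acc", "mcc")]),
               c(sn = 1, sp = 1, acc = 1, mcc = 1))
  all_pos <- metrics_from_counts(10, 8, fn = 0, fp = 8)
  expect_equal(all_pos$sn, 1)
  expect_equal(all_pos$sp, 0)
  # one empty class: metrics reported as NA, not an error
  expect_true(is.na(metrics_from_counts(0, 10, fn = 0, fp = 2)$sn))
  expect_error(metrics_from_counts(5, 5, fn = 6, fp = 0), "fn <= n_pos")
})

test_that("error-rate metric forms agree with textbook TP/TN formulas", {
  m <- metrics_from_counts(50, 40, fn = 7, fp = 5)
  o <- oracle_metrics(tp = 43, tn = 35, fp = 5, fn = 7)
  expect_equal(m$sn, o$sn)
  expect_equal(m$sp, o$sp)
  expect_equal(m$acc, o$acc)
  expect_equal(m$mcc, o$mcc)
})

test_that("ROC area matches pair counting, symmetry and the curve integral", {
  # perfect separation
  expect_equal(roc_auc(c(.9, .8, .7), c(1, 1, 0))$auc, 1)

  set.seed(3)
  scores <- round(runif(10), 1)  # coarse rounding forces ties
  labels <- rbinom(10, 1, 0.5)
  if (sum(labels) == 0) labels[1] <- 1
  if (sum(labels) == 10) labels[10] <- 0
  r <- roc_auc(scores, labels)
  expect_equal(r$auc, oracle_auc(scores, labels))

  # label inversion complements the area
  expect_equal(roc_auc(scores, 1 - labels)$auc, 1 - r$auc)

  # trapezoidal integration of the returned curve reproduces the area
  trap <- sum(diff(r$curve$fpr) * (head(r$curve$tpr, -1) + r$curve$tpr[-1]) / 2)
  expect_equal(trap, r$auc, tolerance = 1e-10)

  expect_error(roc_auc(c(1, 2), c(1, 1)), "both classes")
  expect_error(roc_auc(c(1, NA), c(1, 0)), "finite")
})

test_that("ROC agrees with an independent library implementation", {
  skip_if_not_installed("pROC")
  set.seed(4)
  scores <- rnorm(50)
  labels <- rbinom(50, 1, 0.4)
  expect_equal(
    roc_auc(scores, labels)$auc,
    as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                   direction = "<")))
  )
})

test_that("boosted training separates separable data deterministically", {
  d <- separable_features()
  p <- train(d$X, d$y, params = hyper_params(n_rounds = 30, seed = 5))
  s <- predict(p, d$X)
  expect_true(all(s >= 0 & s <= 1))
  expect_equal(mean((s >= 0.5) == (d$y == 1)), 1)

  p2 <- train(d$X, d$y, params = hyper_params(n_rounds = 30, seed = 5))
  expect_identical(predict(p2, d$X), s)

  expect_error(train(d$X, rep(1, length(d$y))), "degenerate")
})

test_that("grid search validates first, shares folds, and breaks ties low", {
  d <- separable_features(n = 30, seed = 6)
  one <- grid_search(d$X, d$y, grid = tibble::tibble(gamma = 0, eta = 0.3,
                                                     max_depth = 3),
                     folds = 3, seed = 2, n_rounds = 10)
  expect_equal(one$best$max_depth, 3L)
  expect_equal(nrow(one$table), 1)

  expect_equal(nrow(coarse_grid()), 75)

  bad <- tibble::tibble(gamma = c(0, -1), eta = c(0.3, 0.3),
                        max_depth = c(3, 3))
  expect_error(grid_search(d$X, d$y, grid = bad, folds = 3, seed = 2),
               "gamma")

  g <- tibble::tibble(gamma = c(0, 0.1), eta = c(0.3, 0.2),
                      max_depth = c(2, 4))
  r1 <- grid_search(d$X, d$y, grid = g, folds = 3, seed = 7, n_rounds = 10)
  r2 <- grid_search(d$X, d$y, grid = g[2:1, ], folds = 3, seed = 7,
                    n_rounds = 10)
  expect_equal(
    dplyr::arrange(r1$table, gamma)$accuracy,
    dplyr::arrange(r2$table, gamma)$accuracy
  )
})

test_that("k-fold evaluation with folds = n reproduces the jackknife", {
  s <- generate_samples(synth_config(n_pos = 8, n_neg = 8, seed = 21))
  pos <- dplyr::filter(s, label == "positive")
  neg <- dplyr::filter(s, label == "negative")
  params <- hyper_params(n_rounds = 10, seed = 3)
  jk <- jackknife(pos, neg, params = params)
  kf <- evaluate_cv(pos, neg, params = params, folds = 16, seed = 99)
  expect_equal(jk$metrics, kf$metrics)
  expect_equal(jk$scores$score, kf$scores$score)
  expect_equal(nrow(jk$scores), 16)  # n models, n pooled predictions
  expect_error(evaluate_cv(pos, neg, params = params, folds = 17, seed = 1),
               "exceed")
})

test_that("jackknife on strongly planted synthetic data is near-perfect", {
  s <- generate_samples(synth_config(n_pos = 20, n_neg = 20, seed = 31))
  jk <- jackknife(dplyr::filter(s, label == "positive"),
                  dplyr::filter(s, label == "negative"),
                  params = hyper_params(n_rounds = 30, seed = 1))
  expect_gte(jk$metrics$acc, 0.95)
})

test_that("prediction output is total, boundary-inclusive and rerunnable", {
  s <- generate_samples(synth_config(n_pos = 15, n_neg = 15, seed = 41))
  m <- fit_pstnp(s$seq[s$label == "positive"], s$seq[s$label == "negative"])
  feats <- featurize(s, m)
  p <- train(feats, params = hyper_params(n_rounds = 20, seed = 2),
             pstnp_model = m)

  query <- generate_samples(synth_config(n_pos = 3, n_neg = 3, seed = 43))
  query$seq[2] <- "ACGT"  # too short -> flagged, not dropped
  expect_warning(out <- predict_fasta(p, query), "invalid")
  expect_equal(nrow(out), nrow(query))
  expect_equal(out$status[2], "invalid")
  expect_true(is.na(out$score[2]))
  expect_true(all(out$status[out$valid] %in% c("6mA", "non-6mA")))

  # a score exactly at the threshold is called 6mA (boundary inclusive)
  p_at <- p
  p_at$threshold <- out$score[1]
  out_at <- predict_fasta(p_at, query[1, ])
  expect_equal(out_at$status, "6mA")

  # rerun gives the identical table; TSV round-trip keeps the contract
  expect_warning(out2 <- predict_fasta(p, query))
  expect_identical(out, out2)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_predictions(out, f)
  expect_equal(names(readr::read_tsv(f, show_col_types = FALSE))[1:3],
               c("name", "score", "status"))
})

test_that("serialization round-trips predictions bit-exactly", {
  s <- generate_samples(synth_config(n_pos = 12, n_neg = 12, seed = 51))
  m <- fit_pstnp(s$seq[s$label == "positive"], s$seq[s$label == "negative"])
  feats <- featurize(s, m)
  p <- train(feats, params = hyper_params(n_rounds = 15, seed = 4),
             pstnp_model = m)
  f <- withr::local_tempfile(fileext = ".rds")
  save_predictor(p, f)
  p2 <- load_predictor(f)
  expect_identical(predict(p, s), predict(p2, s))
  expect_identical(p2$selected_features, p$selected_features)
  expect_equal(p2$pstnp_model$Zss, p$pstnp_model$Zss)
})
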