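#' Score candidate windows and call modification status
#'
#' Applies a trained predictor to a sample table, producing one output row
#' per input record: the id, the probability score, and the status call
#' `"6mA"` when the score is at or above the predictor's threshold (boundary
#' inclusive), `"non-6mA"` otherwise. Records that fail window validation are
#' kept in the output with `valid = FALSE`, an `NA` score and status
#' `"invalid"` — never silently dropped.
#'
#' @param predictor A `sixma_predictor` from [train()] or [load_predictor()].
#' @param samples Sample tibble (`id`, `seq`), e.g. from [read_fasta()].
#' @return A tibble with columns `id`, `score`, `status`, `valid`, `reason`.
#' @export
predict_fasta <- function(predictor, samples) {
  stopifnot(inherits(predictor, "sixma_predictor"))
  L <- if (!is.null(predictor$pstnp_model)) predictor$pstnp_model$L else 41L
  checked <- validate_samples(samples, L = L)
  out <- tibble(
    id = checked$id,
    score = NA_real_,
    status = "invalid",
    valid = checked$valid,
    reason = checked$reason
  )
  ok <- which(checked$valid)
  if (length(ok) > 0) {
    s <- predict(predictor,
                 mutate(checked[ok, ], seq = toupper(.data$seq)),
                 type = "score")
    out$score[ok] <- s
    out$status[ok] <- ifelse(s >= predictor$threshold, "6mA", "non-6mA")
  }
  n_bad <- sum(!checked$valid)
  if (n_bad > 0) {
    warn(sprintf("%d record(s) failed validation and were flagged invalid",
                 n_bad))
  }
  out
}

#' Write prediction records as TSV
#'
#' Output columns: `name`, `score`, `status` (the prediction text-file
#' contract), plus validity flags for flagged records.
#'
#' @param predictions Tibble from [predict_fasta()]. @param path Output TSV.
#' @export
write_predictions <- function(predictions, path) {
  readr::write_tsv(
    select(predictions, name = "id", "score", "status", "valid", "reason"),
    path
  )
  invisible(path)
}
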