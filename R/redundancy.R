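#' Greedy sequence-identity redundancy filter
#'
#' Order-dependent redundancy reduction for equal-length windows: samples are
#' visited in input order and kept only if their ungapped column-wise identity
#' fraction with every previously kept sample is below `identity_threshold`.
#' Because all windows have equal length, identity is a plain Hamming match
#' fraction — no alignment is attempted. The output therefore has maximum
#' pairwise identity strictly below the threshold.
#'
#' @param samples Sample tibble (`id`, `seq`, ...); all sequences must share
#'   one length.
#' @param identity_threshold Fraction of identical columns at or above which a
#'   sequence counts as redundant. Default 0.6.
#' @return The kept rows, in input order.
#' @examples
#' s <- tibble::tibble(id = c("a", "b"), seq = c("AAAA", "AAAT"))
#' greedy_redundancy_filter(s, identity_threshold = 0.6)
#' @export
greedy_redundancy_filter <- function(samples, identity_threshold = 0.6) {
  stopifnot(is.data.frame(samples), "seq" %in% names(samples))
  if (nrow(samples) == 0) return(samples)
  lens <- nchar(samples$seq)
  if (length(unique(lens)) != 1) {
    abort("all sequences must have the same length for identity filtering")
  }
  L <- lens[1]
  mat <- do.call(rbind, strsplit(toupper(samples$seq), "", fixed = TRUE))
  kept_idx <- integer(0)
  for (i in seq_len(nrow(mat))) {
    redundant <- FALSE
    for (j in kept_idx) {
      if (sum(mat[i, ] == mat[j, ]) / L >= identity_threshold) {
        redundant <- TRUE
        break
      }
    }
    if (!redundant) kept_idx <- c(kept_idx, i)
  }
  samples[kept_idx, , drop = FALSE]
}

#' Pairwise identity fraction between equal-length sequences
#'
#' Helper used by tests and diagnostics: fraction of positions at which two
#' equal-length sequences carry the same base.
#'
#' @param a,b Sequence strings of equal length.
#' @return A number in \[0, 1\].
#' @export
pairwise_identity <- function(a, b) {
  if (nchar(a) != nchar(b)) abort("sequences must have equal length")
  mean(seq_chars(toupper(a)) == seq_chars(toupper(b)))
}
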