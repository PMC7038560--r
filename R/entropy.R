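#' Positional trinucleotide entropy profile
#'
#' For each trinucleotide start position `i = 1 .. L - 2`, computes the
#' Shannon entropy (bits) of the empirical distribution of trinucleotides
#' observed at `i` across the samples:
#' `Ent_i = -sum_j p(3mer_j | i) * log2 p(3mer_j | i)`, with zero-probability
#' terms contributing 0. Values lie in \[0, 6\] bits (6 = log2 64, the uniform
#' maximum). Lower entropy means a more conserved position; around true 6mA
#' sites the central positions are typically more conserved than background.
#'
#' @param samples Sample tibble with a `seq` column (equal-length sequences),
#'   or a character vector of sequences.
#' @return A tibble with columns `position` (1 .. L-2) and `entropy` (bits);
#'   39 rows for 41-nt windows.
#' @examples
#' positional_entropy(c("AAAA", "AAAA"))        # all zero
#' positional_entropy(c("AAAA", "CCCC"))        # 1 bit everywhere
#' @export
positional_entropy <- function(samples) {
  seqs <- if (is.data.frame(samples)) samples$seq else samples
  if (length(seqs) == 0) abort("cannot compute entropy of an empty sample set")
  seqs <- toupper(seqs)
  lens <- unique(nchar(seqs))
  if (length(lens) != 1) abort("all sequences must share one length")
  L <- lens
  if (L < 3) abort("sequences must be at least 3 nt")
  ent <- vapply(seq_len(L - 2L), function(i) {
    p <- table(substr(seqs, i, i + 2L)) / length(seqs)
    -sum(p * log2(p))
  }, numeric(1))
  tibble(position = seq_len(L - 2L), entropy = ent)
}

#' Compare entropy profiles of positive and negative samples
#'
#' Convenience wrapper computing [positional_entropy()] per label class.
#'
#' @param samples Labeled sample tibble (`seq`, `label`).
#' @return A tibble with columns `label`, `position`, `entropy`.
#' @export
entropy_by_class <- function(samples) {
  stopifnot(all(c("seq", "label") %in% names(samples)))
  samples |>
    group_by(.data$label) |>
    group_modify(~ positional_entropy(.x)) |>
    ungroup()
}
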