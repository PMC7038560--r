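#' Validate candidate 6mA windows
#'
#' Checks each sample against the window contract: fixed length `L`, a pure
#' A/C/G/T alphabet (after uppercasing), and — when `require_center_a` — an
#' adenine at the central position `(L + 1) / 2` (position 21 for the default
#' 41-nt windows). The first violated rule is reported per sample; validation
#' never errors.
#'
#' @param samples Tibble with columns `id` and `seq`, as from [read_fasta()].
#' @param L Required window length (odd). Default 41.
#' @param require_center_a Require an `A` at the central position.
#' @return The input with two added columns: `valid` (logical) and `reason`
#'   (`NA` for valid samples, otherwise one of `"length"`, `"alphabet"`,
#'   `"center base"`).
#' @examples
#' validate_samples(tibble::tibble(
#'   id = c("ok", "short"),
#'   seq = c(paste0(strrep("C", 20), "A", strrep("C", 20)), "ACGT")
#' ))
#' @export
validate_samples <- function(samples, L = 41L, require_center_a = TRUE) {
  stopifnot(is.data.frame(samples), all(c("id", "seq") %in% names(samples)))
  center <- (L + 1L) %/% 2L
  seqs <- toupper(samples$seq)
  reason <- rep(NA_character_, length(seqs))
  reason[is.na(reason) & nchar(seqs) != L] <- "length"
  reason[is.na(reason) & grepl("[^ACGT]", seqs)] <- "alphabet"
  if (require_center_a) {
    reason[is.na(reason) & substr(seqs, center, center) != "A"] <- "center base"
  }
  samples |>
    mutate(valid = is.na(reason), reason = reason)
}

#' @describeIn validate_samples Validate a single sequence string; returns a
#'   list with `valid` and `reason`.
#' @param seq A single sequence string.
#' @export
validate_sample <- function(seq, L = 41L, require_center_a = TRUE) {
  res <- validate_samples(tibble(id = "x", seq = seq), L = L,
                          require_center_a = require_center_a)
  list(valid = res$valid[1], reason = res$reason[1])
}
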