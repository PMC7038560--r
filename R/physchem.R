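#' Dinucleotide physicochemical property table
#'
#' Returns the bundled table of six double-stranded B-DNA step properties
#' (Rise, Roll, Shift, Slide, Tilt, Twist) for the 16 dinucleotides. The
#' bundled values are a synthetic, complementary-symmetric compilation of
#' typical crystallographic B-DNA step parameters (file
#' `dinuc_bdna_properties_synthetic.tsv`), not a snapshot of any external
#' database; because the encoder standardizes every property across the 16
#' dinucleotides before use (see [standardize_properties()]), features are
#' invariant to any affine rescaling of a property, and only the relative
#' pattern across dinucleotides matters.
#'
#' @param path Optional path to an alternative TSV with a `dinucleotide`
#'   column plus one numeric column per property.
#' @param standardize Return the z-standardized table (the form the encoder
#'   consumes) rather than raw values.
#' @return A tibble: `dinucleotide` plus one column per property.
#' @export
dinuc_properties <- function(path = NULL, standardize = TRUE) {
  if (is.null(path)) {
    path <- system.file("extdata", "dinuc_bdna_properties_synthetic.tsv",
                        package = "sixmapred", mustWork = TRUE)
  }
  raw <- readr::read_tsv(path, show_col_types = FALSE)
  if (!"dinucleotide" %in% names(raw)) {
    abort("property table must have a 'dinucleotide' column")
  }
  missing_dn <- setdiff(dinucleotides(), raw$dinucleotide)
  if (length(missing_dn) > 0) {
    abort(paste0("property table lacks dinucleotide(s): ",
                 paste(missing_dn, collapse = ", ")))
  }
  raw <- as_tibble(raw)[match(dinucleotides(), raw$dinucleotide), ]
  if (standardize) standardize_properties(raw) else raw
}

#' Standardize a dinucleotide property table
#'
#' Centers and scales each property to mean 0 and standard deviation 1 across
#' the 16 dinucleotides (the population of values the property takes), the
#' required preprocessing before lagged-correlation features are computed.
#'
#' @param raw_table Tibble with `dinucleotide` plus numeric property columns,
#'   16 rows.
#' @return The table with every property column z-scored; properties with
#'   zero spread raise an error.
#' @export
standardize_properties <- function(raw_table) {
  stopifnot(is.data.frame(raw_table), nrow(raw_table) == 16)
  props <- setdiff(names(raw_table), "dinucleotide")
  out <- raw_table
  for (p in props) {
    v <- raw_table[[p]]
    s <- sd(v)
    if (!is.finite(s) || s == 0) {
      abort(sprintf("property '%s' has zero standard deviation", p))
    }
    out[[p]] <- (v - mean(v)) / s
  }
  out
}

#' Physicochemical Type-II pseudo k-tuple features
#'
#' Long-range sequence-order features over standardized dinucleotide
#' properties: for each lag `m = 1 .. lam` and property `psi`, the feature is
#' the mean lagged product
#' `d = (1 / (L - k - 1)) * sum_{i=1}^{L - k - m} H_psi(i) * H_psi(i + m)`
#' with `k = 2`, where `H_psi(i)` is the standardized property value of the
#' dinucleotide starting at position `i`. Features are ordered lag-major:
#' all properties at lag 1, then lag 2, and so on — `lam * Lambda` values
#' (30 for the defaults of 5 lags and 6 properties).
#'
#' The fixed `1 / (L - k - 1)` normalizer is applied to every lag by default;
#' `normalize_per_lag = TRUE` switches to `1 / (L - k - m)`, which normalizes
#' each lag by its own number of summands.
#'
#' @param seq A single A/C/G/T sequence string.
#' @param table Standardized property table from [dinuc_properties()] or
#'   [standardize_properties()].
#' @param lam Number of correlation tiers (lags); must satisfy
#'   `lam < L - 2`. Default 5.
#' @param normalize_per_lag Use a per-lag normalizer instead of the fixed one.
#' @return Named numeric vector of length `lam * Lambda`
#'   (`pc.d1` ... `pc.d30` for defaults).
#' @export
physicochemical_features <- function(seq, table = dinuc_properties(), lam = 5L,
                                     normalize_per_lag = FALSE) {
  seq <- toupper(seq)
  assert_acgt(seq)
  L <- nchar(seq)
  k <- 2L
  if (lam >= L - k) {
    abort(sprintf("lam (%d) must be less than L - %d = %d", lam, k, L - k))
  }
  props <- setdiff(names(table), "dinucleotide")
  H <- as.matrix(table[props])
  rownames(H) <- table$dinucleotide
  dn <- seq_kmers(seq, 2)
  Hseq <- H[match(dn, rownames(H)), , drop = FALSE]  # (L-1) x Lambda
  out <- numeric(lam * length(props))
  idx <- 1L
  for (m in seq_len(lam)) {
    upper <- L - k - m
    norm <- if (normalize_per_lag) upper else L - k - 1L
    for (p in seq_along(props)) {
      out[idx] <- sum(Hseq[seq_len(upper), p] * Hseq[seq_len(upper) + m, p]) / norm
      idx <- idx + 1L
    }
  }
  names(out) <- paste0("pc.d", seq_along(out))
  out
}
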