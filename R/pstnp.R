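#' Collapse a DNA sequence to the two-letter double-stranded alphabet
#'
#' Complementary bases are treated as equivalent in double-stranded encodings:
#' A and T map to `A`, C and G map to `C`. Length is preserved, e.g.
#' `"TCGAGTGAC"` becomes `"ACCACACAC"`.
#'
#' @param seq A/C/G/T sequence string (vectorised).
#' @return Sequence(s) over the alphabet \{A, C\}.
#' @export
ds_reduce <- function(seq) {
  seq <- toupper(seq)
  assert_acgt(seq)
  chartr("TG", "AC", seq)
}

pstnp_rows <- function(stranded) {
  switch(stranded,
    ss = trinucleotides(DNA_BASES),
    ds = trinucleotides(c("A", "C")),
    abort("stranded must be 'ss' or 'ds'")
  )
}

# Positional trinucleotide frequency matrix: rows = trinucleotides (lexico),
# cols = start positions 1..L-2; each column sums to 1.
positional_freqs <- function(seqs, rows) {
  L <- nchar(seqs[1])
  n <- length(seqs)
  starts <- seq_len(L - 2L)
  mat <- matrix(0, nrow = length(rows), ncol = L - 2L,
                dimnames = list(rows, NULL))
  for (j in starts) {
    tri_j <- substr(seqs, j, j + 2L)
    counts <- table(factor(tri_j, levels = rows))
    mat[, j] <- as.numeric(counts) / n
  }
  mat
}

#' Fit a position-specific trinucleotide propensity (PSTNP) model
#'
#' For every trinucleotide `i` and start position `j` the propensity is the
#' difference between its positional frequency in the positive and negative
#' training sets, `Z[i, j] = F+(3mer_i | j) - F-(3mer_i | j)`. Two matrices
#' are fitted: the single-stranded `Zss` over the 64 A/C/G/T trinucleotides
#' and the double-stranded `Zds` over the 8 trinucleotides of the collapsed
#' \{A, C\} alphabet (see [ds_reduce()]). Rows are ordered lexicographically;
#' columns are start positions `1 .. L - 2`. All entries lie in \[-1, 1\].
#'
#' @param positives,negatives Character vectors of equal-length sequences, or
#'   sample tibbles with a `seq` column.
#' @return An object of class `pstnp_model` with elements `Zss` (64 x L-2),
#'   `Zds` (8 x L-2), `L`, `n_pos`, `n_neg`.
#' @seealso [pstnp_features()] to encode a query sequence.
#' @export
fit_pstnp <- function(positives, negatives) {
  pos <- if (is.data.frame(positives)) positives$seq else positives
  neg <- if (is.data.frame(negatives)) negatives$seq else negatives
  if (length(pos) == 0 || length(neg) == 0) {
    abort("both positive and negative training sets must be non-empty")
  }
  pos <- toupper(pos); neg <- toupper(neg)
  assert_acgt(pos, "positive set"); assert_acgt(neg, "negative set")
  lens <- unique(c(nchar(pos), nchar(neg)))
  if (length(lens) != 1) abort("all training sequences must share one length")
  L <- lens
  if (L < 3) abort("sequences must be at least 3 nt")
  rows_ss <- pstnp_rows("ss")
  rows_ds <- pstnp_rows("ds")
  Zss <- positional_freqs(pos, rows_ss) - positional_freqs(neg, rows_ss)
  Zds <- positional_freqs(ds_reduce(pos), rows_ds) -
    positional_freqs(ds_reduce(neg), rows_ds)
  structure(
    list(Zss = Zss, Zds = Zds, L = L,
         n_pos = length(pos), n_neg = length(neg)),
    class = "pstnp_model"
  )
}

#' @export
print.pstnp_model <- function(x, ...) {
  cat(sprintf(
    "PSTNP model: L = %d (%d positions), fitted on %d positive / %d negative\n",
    x$L, x$L - 2L, x$n_pos, x$n_neg
  ))
  invisible(x)
}

#' @export
tidy.pstnp_model <- function(x, ...) {
  long <- function(Z, strand) {
    tibble(
      strand = strand,
      trinucleotide = rep(rownames(Z), times = ncol(Z)),
      position = rep(seq_len(ncol(Z)), each = nrow(Z)),
      propensity = as.numeric(Z)
    )
  }
  bind_rows(long(x$Zss, "ss"), long(x$Zds, "ds"))
}

#' @export
glance.pstnp_model <- function(x, ...) {
  tibble(L = x$L, n_positions = x$L - 2L, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Encode a sequence with a fitted PSTNP model
#'
#' Walks the query sequence and, at each start position `u = 1 .. L - 2`,
#' looks up the propensity of the trinucleotide observed there. With
#' `stranded = "ds"` the query is first collapsed with [ds_reduce()] and looked
#' up in the 8-row double-stranded matrix.
#'
#' @param seq A single sequence string of the model's length `L`.
#' @param model A `pstnp_model` from [fit_pstnp()].
#' @param stranded `"ss"` (single-stranded, 64 trinucleotides) or `"ds"`
#'   (double-stranded, 8 reduced trinucleotides).
#' @return Named numeric vector of length `L - 2` (39 for 41-nt windows),
#'   names `pstnp_ss.pos1` ... or `pstnp_ds.pos1` ....
#' @export
pstnp_features <- function(seq, model, stranded = c("ss", "ds")) {
  stranded <- arg_match(stranded)
  stopifnot(inherits(model, "pstnp_model"))
  seq <- toupper(seq)
  assert_acgt(seq)
  if (nchar(seq) != model$L) {
    abort(sprintf("sequence length %d does not match model L = %d",
                  nchar(seq), model$L))
  }
  Z <- if (stranded == "ss") model$Zss else model$Zds
  q <- if (stranded == "ds") ds_reduce(seq) else seq
  tris <- seq_kmers(q, 3)
  out <- Z[cbind(match(tris, rownames(Z)), seq_along(tris))]
  names(out) <- paste0("pstnp_", stranded, ".pos", seq_along(tris))
  out
}
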