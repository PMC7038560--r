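#' Electron-ion interaction pseudopotential values per nucleotide
#'
#' The per-base EIIP pseudopotentials used by the trinucleotide encoder:
#' A = 0.1260, C = 0.1340, G = 0.0806, T = 0.1335.
#'
#' @return Named numeric vector of length 4.
#' @export
eiip_table <- function() {
  c(A = 0.1260, C = 0.1340, G = 0.0806, T = 0.1335)
}

# Mean EIIP per trinucleotide, in lexicographic order.
eiip_trinucleotide_means <- function(values = eiip_table()) {
  tri <- trinucleotides()
  vapply(tri, function(t) mean(values[seq_chars(t)]), numeric(1))
}

#' EIIP trinucleotide features of one sequence
#'
#' Encodes a window as 64 values, one per trinucleotide `xyz` in lexicographic
#' order (A < C < G < T): the mean per-base EIIP of `x`, `y`, `z` multiplied by
#' the trinucleotide's overlapping-occurrence frequency
#' `f_xyz = count(xyz) / (L - 2)`. Frequencies over all 64 trinucleotides sum
#' to 1, so each feature lies in \[0, 0.1340\].
#'
#' @param seq A single A/C/G/T sequence string (any length >= 3).
#' @param values Per-base EIIP values, as from [eiip_table()].
#' @return Named numeric vector of length 64 (`eiip.AAA` ... `eiip.TTT`).
#' @examples
#' eiip_features(strrep("A", 41))[["eiip.AAA"]]
#' @export
eiip_features <- function(seq, values = eiip_table()) {
  seq <- toupper(seq)
  assert_acgt(seq)
  if (nchar(seq) < 3) abort("sequence must be at least 3 nt for trinucleotides")
  tri <- trinucleotides()
  counts <- table(factor(seq_kmers(seq, 3), levels = tri))
  freqs <- as.numeric(counts) / (nchar(seq) - 2)
  out <- eiip_trinucleotide_means(values) * freqs
  names(out) <- paste0("eiip.", tri)
  out
}
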