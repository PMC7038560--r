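#' Read or write a modification-site table
#'
#' Site tables are TSV with columns `chrom`, `pos` (1-based position of the
#' adenine), `strand` (`+`/`-`) and `qv` (non-negative modification confidence
#' score from SMRT kinetics; Qv 30 corresponds to p < 0.001).
#'
#' @param path TSV file path.
#' @param header Whether the file has a header row; when `FALSE` the four
#'   columns are assumed in the order chrom, pos, strand, qv.
#' @return A tibble with columns `chrom`, `pos`, `strand`, `qv`.
#' @export
read_site_table <- function(path, header = TRUE) {
  cols <- c("chrom", "pos", "strand", "qv")
  df <- if (header) {
    readr::read_tsv(path, show_col_types = FALSE)
  } else {
    readr::read_tsv(path, col_names = cols, show_col_types = FALSE)
  }
  if (!all(cols %in% names(df))) {
    abort(paste0("site table must have columns ", paste(cols, collapse = ", ")))
  }
  df <- as_tibble(df)[cols]
  if (any(df$pos < 1)) abort("site positions must be >= 1 (1-based)")
  if (any(df$qv < 0)) abort("Qv scores must be non-negative")
  if (!all(df$strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  df
}

#' @rdname read_site_table
#' @param sites Site tibble to write.
#' @export
write_site_table <- function(sites, path) {
  readr::write_tsv(sites[c("chrom", "pos", "strand", "qv")], path)
  invisible(path)
}

#' Filter modification sites by confidence score
#'
#' Drops sites whose Qv score falls below `min_qv`; sites at exactly the
#' threshold are kept. The default of 30 corresponds to a modification
#' detection p-value below 0.001. Row order is preserved.
#'
#' @param sites Tibble with a `qv` column.
#' @param min_qv Minimum Qv score to keep (inclusive).
#' @return The filtered tibble.
#' @export
qv_filter <- function(sites, min_qv = 30) {
  stopifnot(is.data.frame(sites), "qv" %in% names(sites))
  filter(sites, .data$qv >= min_qv)
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

#' Extract adenine-centered windows from a genome
#'
#' For each site, slices `genome[pos - flank .. pos + flank]` (1-based,
#' inclusive) from the site's chromosome, giving a window of length
#' `2 * flank + 1`. Minus-strand sites yield the reverse complement of that
#' slice, so the methylated adenine always reads `A` at the window center on
#' the reported strand.
#'
#' @param genome Named character vector of chromosome sequences (or a single
#'   unnamed sequence, addressed as chromosome `"chr1"`).
#' @param sites Site tibble (`chrom`, `pos`, `strand`; `qv` optional) or a
#'   single-site list.
#' @param flank Number of nucleotides on each side of the site. Default 20,
#'   giving 41-nt windows.
#' @param check_center Error unless the centered base reads `A` on the
#'   reported strand.
#' @return A tibble of samples (`id`, `seq`, `label = "unknown"`), one row per
#'   site, ids of the form `chrom:pos(strand)`.
#' @examples
#' extract_windows(c(chr1 = "CCCCCACCCC"),
#'                 tibble::tibble(chrom = "chr1", pos = 6, strand = "+"),
#'                 flank = 2)
#' @export
extract_windows <- function(genome, sites, flank = 20L, check_center = TRUE) {
  if (is.null(names(genome))) {
    if (length(genome) != 1) abort("multiple genome sequences must be named")
    names(genome) <- "chr1"
  }
  genome <- toupper(genome)
  if (!is.data.frame(sites)) sites <- as_tibble(sites[c("chrom", "pos", "strand")])
  missing_chrom <- setdiff(unique(sites$chrom), names(genome))
  if (length(missing_chrom) > 0) {
    abort(paste0("chromosome(s) absent from genome: ",
                 paste(missing_chrom, collapse = ", ")))
  }
  n <- nrow(sites)
  seqs <- character(n)
  for (i in seq_len(n)) {
    chrom_seq <- genome[[sites$chrom[i]]]
    pos <- sites$pos[i]
    lo <- pos - flank
    hi <- pos + flank
    if (lo < 1 || hi > nchar(chrom_seq)) {
      abort(sprintf(
        "window [%d, %d] out of bounds for %s (length %d)",
        lo, hi, sites$chrom[i], nchar(chrom_seq)
      ))
    }
    w <- substr(chrom_seq, lo, hi)
    if (sites$strand[i] == "-") w <- revcomp(w)
    if (check_center && substr(w, flank + 1L, flank + 1L) != "A") {
      abort(sprintf(
        "site %s:%d(%s): center base is '%s', not 'A', on the reported strand",
        sites$chrom[i], pos, sites$strand[i], substr(w, flank + 1L, flank + 1L)
      ))
    }
    seqs[i] <- w
  }
  tibble(
    id = sprintf("%s:%d(%s)", sites$chrom, sites$pos, sites$strand),
    seq = seqs,
    label = "unknown"
  )
}

#' Sample negative (non-6mA) windows from a genome
#'
#' Draws `n` adenine-centered windows whose centers are plus-strand adenines
#' lying strictly more than `exclusion_flank` bp from every positive site on
#' the same chromosome, mirroring the benchmark rule that negatives avoid the
#' +/- 500 bp neighbourhood of any positive. Sampling is without replacement
#' and deterministic under `seed`.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param positive_sites Site tibble of known positives (`chrom`, `pos`).
#' @param n Number of negatives to draw.
#' @param exclusion_flank Half-width of the exclusion zone around each
#'   positive site (bp). Default 500.
#' @param flank Window half-width, as in [extract_windows()].
#' @param seed Integer seed; required for reproducibility.
#' @return A tibble of samples labeled `"negative"`, plus attribute `"sites"`
#'   holding the sampled site table.
#' @export
sample_negatives <- function(genome, positive_sites, n, exclusion_flank = 500L,
                             flank = 20L, seed) {
  if (is.null(names(genome))) names(genome) <- "chr1"
  genome <- toupper(genome)
  eligible <- purrr::imap(genome, function(chrom_seq, chrom) {
    a_pos <- which(seq_chars(chrom_seq) == "A")
    a_pos <- a_pos[a_pos > flank & a_pos <= nchar(chrom_seq) - flank]
    pos_here <- positive_sites$pos[positive_sites$chrom == chrom]
    if (length(pos_here) > 0 && length(a_pos) > 0) {
      near <- purrr::map_lgl(a_pos, function(p) any(abs(p - pos_here) <= exclusion_flank))
      a_pos <- a_pos[!near]
    }
    if (length(a_pos) == 0) return(NULL)
    tibble(chrom = chrom, pos = a_pos)
  }) |> bind_rows()
  if (n == 0) {
    return(tibble(id = character(), seq = character(), label = character()))
  }
  if (nrow(eligible) < n) {
    abort(sprintf(
      "requested %d negative sites but only %d eligible adenines found",
      n, nrow(eligible)
    ))
  }
  picked <- withr::with_seed(seed, {
    eligible[sample.int(nrow(eligible), n), , drop = FALSE]
  })
  picked$strand <- "+"
  picked$qv <- 0
  out <- extract_windows(genome, picked, flank = flank)
  out$label <- "negative"
  attr(out, "sites") <- picked
  out
}
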