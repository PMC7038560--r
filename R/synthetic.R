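#' Configuration for the synthetic window generator
#'
#' Describes a labeled synthetic dataset of 41-nt adenine-centered windows.
#' Negatives are i.i.d. draws from `base_composition` with the center forced
#' to `A`. Positives start the same way, then with probability `plant_prob`
#' the `motif` is written at `motif_offset`, and with probability
#' `plus_four_A_prob` the base four positions downstream of the center is set
#' to `A` — emulating the centered GAGG enrichment and the +4 adenine
#' enrichment observed around genuine 6mA sites. The default offset of 20
#' places the motif's own adenine on the central position, so planting never
#' overwrites the center with a non-A base.
#'
#' @param n_pos,n_neg Class sizes (default 400 each).
#' @param motif Planted motif (default `"GAGG"`).
#' @param motif_offset 1-based start of the motif in the window (default 20).
#' @param plant_prob Probability a positive carries the motif (default 1).
#' @param plus_four_A_prob Probability the center+4 base of a positive is
#'   forced to `A` (default 0.8).
#' @param base_composition Named probabilities for A, C, G, T (sum 1).
#' @param L Window length (odd, default 41). @param seed Integer seed.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_pos = 400L, n_neg = 400L, motif = "GAGG",
                         motif_offset = 20L, plant_prob = 1,
                         plus_four_A_prob = 0.8,
                         base_composition = c(A = 0.25, C = 0.25,
                                              G = 0.25, T = 0.25),
                         L = 41L, seed = 1L) {
  if (plant_prob < 0 || plant_prob > 1) abort("plant_prob must be in [0, 1]")
  if (plus_four_A_prob < 0 || plus_four_A_prob > 1) {
    abort("plus_four_A_prob must be in [0, 1]")
  }
  if (!setequal(names(base_composition), DNA_BASES)) {
    abort("base_composition must be named A, C, G, T")
  }
  base_composition <- base_composition[DNA_BASES]
  if (abs(sum(base_composition) - 1) > 1e-9) {
    abort("base_composition must sum to 1")
  }
  motif <- toupper(motif)
  assert_acgt(motif, "motif")
  if (L %% 2 == 0) abort("window length L must be odd")
  center <- (L + 1L) %/% 2L
  m_end <- motif_offset + nchar(motif) - 1L
  if (motif_offset < 1 || m_end > L) abort("motif does not fit in the window")
  if (motif_offset <= center && center <= m_end) {
    if (substr(motif, center - motif_offset + 1L, center - motif_offset + 1L) != "A") {
      abort("motif would overwrite the central adenine with a non-A base")
    }
  }
  structure(
    list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg), motif = motif,
         motif_offset = as.integer(motif_offset), plant_prob = plant_prob,
         plus_four_A_prob = plus_four_A_prob,
         base_composition = base_composition, L = as.integer(L),
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

random_windows <- function(n, L, center, base_composition) {
  if (n == 0) return(character(0))
  mat <- matrix(
    sample(DNA_BASES, n * L, replace = TRUE, prob = base_composition),
    nrow = n
  )
  mat[, center] <- "A"
  apply(mat, 1, paste0, collapse = "")
}

#' Generate a labeled synthetic dataset
#'
#' Draws the dataset described by a [synth_config()]; deterministic under the
#' config's seed, and every generated window passes [validate_samples()].
#'
#' @param config A [synth_config()].
#' @return A sample tibble (`id`, `seq`, `label`) with exactly
#'   `n_pos + n_neg` rows.
#' @examples
#' generate_samples(synth_config(n_pos = 5, n_neg = 5, seed = 42))
#' @export
generate_samples <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  center <- (config$L + 1L) %/% 2L
  withr::with_seed(config$seed, {
    neg <- random_windows(config$n_neg, config$L, center,
                          config$base_composition)
    pos <- random_windows(config$n_pos, config$L, center,
                          config$base_composition)
    if (config$n_pos > 0) {
      plant <- runif(config$n_pos) < config$plant_prob
      if (any(plant)) {
        substr(pos[plant], config$motif_offset,
               config$motif_offset + nchar(config$motif) - 1L) <- config$motif
      }
      a4 <- runif(config$n_pos) < config$plus_four_A_prob
      if (center + 4L <= config$L && any(a4)) {
        substr(pos[a4], center + 4L, center + 4L) <- "A"
      }
    }
    tibble(
      id = c(sprintf("pos_%04d", seq_len(config$n_pos)),
             sprintf("neg_%04d", seq_len(config$n_neg))),
      seq = c(pos, neg),
      label = rep(c("positive", "negative"), c(config$n_pos, config$n_neg))
    )
  })
}

#' Generate a toy genome with designated modification sites
#'
#' Builds a random single-chromosome genome and marks `n_sites` adenines as
#' candidate 6mA sites with Qv scores spanning the filtering threshold of 30,
#' so window extraction, Qv filtering and exclusion-aware negative sampling
#' can be exercised end-to-end without any download. Sites are spaced at
#' least 41 nt from the contig ends.
#'
#' @param length Genome length (nt).
#' @param n_sites Number of designated adenine sites.
#' @param seed Integer seed.
#' @param qv_range Range the site Qv scores are drawn from (uniform);
#'   defaults to (10, 50) so some sites fall below the threshold of 30.
#' @return A list with `genome` (named character vector, one chromosome
#'   `chr1`) and `sites` (tibble `chrom`, `pos`, `strand`, `qv`).
#' @export
toy_genome <- function(length = 5000L, n_sites = 10L, seed = 1L,
                       qv_range = c(10, 50)) {
  withr::with_seed(seed, {
    g <- paste0(sample(DNA_BASES, length, replace = TRUE), collapse = "")
    chars <- seq_chars(g)
    a_pos <- which(chars == "A")
    a_pos <- a_pos[a_pos > 41 & a_pos <= length - 41]
    if (base::length(a_pos) < n_sites) {
      abort(sprintf("genome too short: only %d eligible adenines for %d sites",
                    base::length(a_pos), n_sites))
    }
    pos <- sort(sample(a_pos, n_sites))
    sites <- tibble(
      chrom = "chr1", pos = pos, strand = "+",
      qv = round(runif(n_sites, qv_range[1], qv_range[2]), 1)
    )
  })
  list(genome = c(chr1 = g), sites = sites)
}
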