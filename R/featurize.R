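#' Full feature vector of one window
#'
#' Concatenates the four encoder blocks in fixed order: EIIP trinucleotide
#' features (64), single-stranded PSTNP (`L - 2` = 39), double-stranded PSTNP
#' (39), and physicochemical Type-II pseudo k-tuple features (`lam * Lambda`
#' = 30) — 172 named values for the 41-nt default window.
#'
#' @param seq A single sequence string of the PSTNP model's length.
#' @param pstnp_model Fitted [fit_pstnp()] model.
#' @param eiip_values Per-base EIIP values ([eiip_table()]).
#' @param prop_table Standardized property table ([dinuc_properties()]).
#' @param lam Correlation tiers for the physicochemical block.
#' @return Named numeric vector; 172 values for defaults.
#' @export
extract_all <- function(seq, pstnp_model, eiip_values = eiip_table(),
                        prop_table = dinuc_properties(), lam = 5L) {
  c(
    eiip_features(seq, eiip_values),
    pstnp_features(seq, pstnp_model, "ss"),
    pstnp_features(seq, pstnp_model, "ds"),
    physicochemical_features(seq, prop_table, lam)
  )
}

#' Names of the full feature schema
#'
#' @param L Window length. @param lam Correlation tiers.
#' @return Character vector of the 64 + (L-2) + (L-2) + lam*6 feature names.
#' @export
feature_schema <- function(L = 41L, lam = 5L) {
  c(
    paste0("eiip.", trinucleotides()),
    paste0("pstnp_ss.pos", seq_len(L - 2L)),
    paste0("pstnp_ds.pos", seq_len(L - 2L)),
    paste0("pc.d", seq_len(lam * 6L))
  )
}

#' Encode a sample table as a feature matrix
#'
#' Applies [extract_all()] to every row of a sample table, returning one
#' feature column per encoder dimension alongside the sample `id` and
#' `label`.
#'
#' @param samples Sample tibble (`id`, `seq`, optionally `label`).
#' @inheritParams extract_all
#' @return A tibble: `id`, `label`, then 172 feature columns (defaults).
#' @export
featurize <- function(samples, pstnp_model, eiip_values = eiip_table(),
                      prop_table = dinuc_properties(), lam = 5L) {
  stopifnot(is.data.frame(samples), "seq" %in% names(samples))
  feats <- purrr::map(samples$seq, extract_all,
                      pstnp_model = pstnp_model, eiip_values = eiip_values,
                      prop_table = prop_table, lam = lam)
  mat <- do.call(rbind, feats)
  out <- as_tibble(mat)
  id <- if ("id" %in% names(samples)) samples$id else paste0("s", seq_len(nrow(samples)))
  label <- if ("label" %in% names(samples)) samples$label else "unknown"
  bind_cols(tibble(id = id, label = label), out)
}

#' Write / read a feature matrix as TSV
#'
#' @param features Feature tibble from [featurize()].
#' @param path TSV path.
#' @return `path` (write) or the feature tibble (read).
#' @export
write_feature_matrix <- function(features, path) {
  readr::write_tsv(features, path)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  as_tibble(readr::read_tsv(path, show_col_types = FALSE))
}

# Strip id/label columns, returning the bare numeric matrix + label vector.
feature_xy <- function(features) {
  meta <- intersect(c("id", "label"), names(features))
  X <- as.matrix(features[setdiff(names(features), meta)])
  y <- if ("label" %in% meta) as.integer(features$label == "positive") else NULL
  list(X = X, y = y)
}
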