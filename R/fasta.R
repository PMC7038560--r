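#' Read a FASTA file into a sample table
#'
#' Reads a (possibly line-wrapped) multi-record FASTA file and returns one row
#' per record. Sequences are uppercased; record order is preserved. Labels are
#' `"unknown"` unless the record id carries a `|positive` / `|negative` suffix
#' (the convention [write_fasta()] uses for labeled sets).
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` (character), `seq` (character, uppercase)
#'   and `label` (`"positive"`, `"negative"` or `"unknown"`).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">s1", "acgtA", ">s2", "GGGTT"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(paste0("malformed FASTA in ", path, ": ",
                                     conditionMessage(e)))
  )
  if (length(set) == 0) {
    warn(paste0("empty FASTA file: ", path))
    return(tibble(id = character(), seq = character(), label = character()))
  }
  ids <- names(set)
  if (is.null(ids)) ids <- paste0("seq", seq_along(set))
  seqs <- toupper(as.character(set))
  label <- rep("unknown", length(ids))
  tagged <- grepl("\\|(positive|negative)$", ids)
  label[tagged] <- sub("^.*\\|", "", ids[tagged])
  ids[tagged] <- sub("\\|(positive|negative)$", "", ids[tagged])
  dup <- duplicated(ids)
  if (any(dup)) {
    warn(sprintf("%d duplicated record id(s); suffixing to keep ids unique",
                 sum(dup)))
    ids <- make.unique(ids, sep = "_dup")
  }
  tibble(id = ids, seq = unname(seqs), label = label)
}

#' Write a sample table to FASTA
#'
#' Inverse of [read_fasta()]. Labeled samples (`positive`/`negative`) get the
#' label appended to the record id as `id|label` so a round-trip preserves it.
#'
#' @param samples Tibble with columns `id`, `seq` and optionally `label`.
#' @param path Output file path.
#' @param width Line-wrap width for sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(samples, path, width = 60L) {
  ids <- samples$id
  if ("label" %in% names(samples)) {
    lab <- samples$label
    ids <- ifelse(lab %in% c("positive", "negative"), paste0(ids, "|", lab), ids)
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(samples))) {
    writeLines(paste0(">", ids[i]), con)
    s <- samples$seq[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
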