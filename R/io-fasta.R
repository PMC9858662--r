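#' Read a FASTA file into a tidy sequence table
#'
#' Sequences are upcased; with `dna = TRUE` (default) RNA `U` is mapped
#' to `T` so downstream exact matching happens in a single alphabet
#' space. Duplicate ids are an error.
#'
#' @param path Path to a FASTA file.
#' @param dna Normalize to DNA space (U -> T)?
#' @return A tibble with columns `id` (first whitespace-delimited token
#'   of the header) and `seq`.
#' @export
read_fasta <- function(path, dna = TRUE) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate FASTA id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  if (dna) seqs <- normalize_dna(seqs)
  tibble::tibble(id = ids, seq = unname(seqs))
}

#' Write a sequence table as FASTA
#' @param seqs Tibble with columns `id` and `seq`.
#' @param path Output path.
#' @param width Line-wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  wrap <- function(s) {
    if (nchar(s) <= width) return(s)
    starts <- seq(1L, nchar(s), by = width)
    substring(s, starts, pmin(starts + width - 1L, nchar(s)))
  }
  out <- unlist(lapply(seq_len(nrow(seqs)), function(i) {
    c(paste0(">", seqs$id[i]), wrap(seqs$seq[i]))
  }))
  writeLines(out, path)
  invisible(path)
}
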