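.DOMAINS <- c("Bacteria", "Archaea", "Eukarya")

.METADATA_COLS <- c("genome_id", "species", "domain", "group",
                    "genome_size_mb", "protein_coding_genes")

#' Read a per-genome metadata table
#'
#' A TSV with one row per genome and required columns `genome_id`,
#' `species`, `domain` (one of Bacteria/Archaea/Eukarya), `group`
#' (phylum or eukaryote lineage label), `genome_size_mb` (> 0) and
#' `protein_coding_genes` (>= 0).
#'
#' @param path Path to a tab-separated metadata file with a header row.
#' @return A validated tibble.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(.METADATA_COLS, names(df))
  if (length(missing)) {
    stop("metadata schema error: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- tibble::as_tibble(df)
  validate_metadata(df)
}

#' Validate an in-memory metadata table
#' @param metadata Tibble with the metadata schema.
#' @return The validated tibble (invisibly unchanged).
#' @export
validate_metadata <- function(metadata) {
  bad_dom <- setdiff(unique(metadata$domain), .DOMAINS)
  if (length(bad_dom)) {
    stop("unknown domain(s): ", paste(bad_dom, collapse = ", "),
         "; expected one of ", paste(.DOMAINS, collapse = "/"), call. = FALSE)
  }
  if (any(!is.finite(metadata$genome_size_mb) | metadata$genome_size_mb <= 0)) {
    stop("genome_size_mb must be > 0 for every genome", call. = FALSE)
  }
  if (any(metadata$protein_coding_genes < 0)) {
    stop("protein_coding_genes must be >= 0", call. = FALSE)
  }
  if (anyDuplicated(metadata$genome_id)) {
    stop("duplicated genome_id in metadata", call. = FALSE)
  }
  metadata
}

#' Write a metadata table as TSV
#' @param metadata Metadata tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
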