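#' Validate a table of mature-tRNA models
#'
#' Models carry the mature tRNA sequence (DNA space, 5'->3', optionally
#' CCA-terminated) and the genomic 3' trailer up to the pol-III
#' terminator.
#'
#' @param models Tibble with columns `trna_id`, `mature_seq`,
#'   `trailer_seq`.
#' @return The validated tibble, sequences normalized to DNA space.
#' @export
validate_models <- function(models) {
  need <- c("trna_id", "mature_seq", "trailer_seq")
  missing <- setdiff(need, names(models))
  if (length(missing)) {
    stop("model table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  models$mature_seq <- normalize_dna(models$mature_seq)
  models$trailer_seq <- normalize_dna(models$trailer_seq)
  if (any(nchar(models$mature_seq) < 60L)) {
    stop("mature_seq shorter than 60 nt", call. = FALSE)
  }
  if (any(nchar(models$trailer_seq) < 1L)) {
    stop("empty trailer_seq", call. = FALSE)
  }
  if (anyDuplicated(models$trna_id)) {
    stop("duplicated trna_id in models", call. = FALSE)
  }
  models
}

#' Classify tRNA-derived fragments against gene models
#'
#' Exact-match typing of small-RNA fragments by their position on the
#' source tRNA: a fragment that is an exact prefix of a mature sequence
#' is a 5'-derived tRF (tRF-5); an exact suffix of a mature sequence
#' (tried both with and without a post-transcriptional CCA appended) is
#' a 3'-derived tRF (tRF-3); an exact prefix of a 3' trailer is a
#' trailer-derived tRF (tRF-1). All models matching in the assigned
#' category accumulate in `sources`. A fragment matching several
#' categories is assigned by the fixed priority tRF-5 > tRF-3 > tRF-1
#' and flagged `ambiguous`, so totals are conserved. Fragments shorter
#' than `min_len` are rejected with a reason; fragments matching no
#' model are `unclassified`.
#'
#' @param fragments Tibble with columns `id` and `seq` (e.g. from
#'   [read_fasta()]), or a character vector of sequences.
#' @param models Model tibble, see [validate_models()].
#' @param min_len Minimum classifiable fragment length (default 13 nt).
#' @return Tibble of class `trf_records`: `fragment_id`, `seq`,
#'   `length`, `trf_type` (`tRF-5`/`tRF-3`/`tRF-1`/`unclassified`, `NA`
#'   for rejected), `sources` (list of model ids), `n_sources`,
#'   `ambiguous`, `cca_matched`, `reason`.
#' @export
classify_fragments <- function(fragments, models, min_len = 13L) {
  if (is.character(fragments)) {
    ids <- if (!is.null(names(fragments))) names(fragments) else
      paste0("frag_", seq_along(fragments))
    fragments <- tibble::tibble(id = ids, seq = fragments)
  }
  models <- validate_models(models)
  seqs <- unname(normalize_dna(fragments$seq))
  mature <- models$mature_seq
  mature_cca <- paste0(mature, "CCA")
  trailer <- models$trailer_seq

  n <- length(seqs)
  trf_type <- rep(NA_character_, n)
  sources <- vector("list", n)
  ambiguous <- logical(n)
  cca_matched <- logical(n)
  reason <- rep(NA_character_, n)

  for (i in seq_len(n)) {
    s <- seqs[i]
    if (nchar(s) < min_len) {
      reason[i] <- sprintf("length %d < minimum %d nt", nchar(s), min_len)
      sources[i] <- list(character())
      next
    }
    hit5 <- startsWith(mature, s)
    hit3_plain <- endsWith(mature, s)
    hit3_cca <- endsWith(mature_cca, s)
    hit3 <- hit3_plain | hit3_cca
    hit1 <- startsWith(trailer, s)
    cats <- c(`tRF-5` = any(hit5), `tRF-3` = any(hit3), `tRF-1` = any(hit1))
    if (!any(cats)) {
      trf_type[i] <- "unclassified"
      sources[i] <- list(character())
      next
    }
    type <- names(cats)[which(cats)[1L]]  # priority tRF-5 > tRF-3 > tRF-1
    trf_type[i] <- type
    ambiguous[i] <- sum(cats) > 1L
    hits <- switch(type, `tRF-5` = hit5, `tRF-3` = hit3, `tRF-1` = hit1)
    sources[i] <- list(models$trna_id[hits])
    if (type == "tRF-3") cca_matched[i] <- !any(hit3_plain) && any(hit3_cca)
  }

  out <- tibble::tibble(
    fragment_id = fragments$id,
    seq = seqs,
    length = nchar(seqs),
    trf_type = trf_type,
    sources = sources,
    n_sources = lengths(sources),
    ambiguous = ambiguous,
    cca_matched = cca_matched,
    reason = reason
  )
  class(out) <- c("trf_records", class(out))
  out
}

#' Verify classified fragments against their claimed source positions
#'
#' A consistency pass: every classified fragment must be re-findable at
#' the position its type claims on every listed source model (mature 5'
#' end, mature 3' end with or without CCA, or trailer 5' end).
#'
#' @param records Result of [classify_fragments()].
#' @param models Model tibble.
#' @return Logical vector, one value per record (`TRUE` for rejected or
#'   unclassified records, which claim no position).
#' @export
verify_fragments <- function(records, models) {
  models <- validate_models(models)
  idx <- stats::setNames(seq_len(nrow(models)), models$trna_id)
  vapply(seq_len(nrow(records)), function(i) {
    type <- records$trf_type[i]
    if (is.na(type) || type == "unclassified") return(TRUE)
    s <- records$seq[i]
    j <- idx[records$sources[[i]]]
    if (anyNA(j) || !length(j)) return(FALSE)
    all(vapply(j, function(k) {
      switch(type,
        `tRF-5` = startsWith(models$mature_seq[k], s),
        `tRF-3` = endsWith(models$mature_seq[k], s) ||
                  endsWith(paste0(models$mature_seq[k], "CCA"), s),
        `tRF-1` = startsWith(models$trailer_seq[k], s),
        FALSE)
    }, logical(1)))
  }, logical(1))
}

#' Redundancy statistics of a tRF pool
#'
#' `unique` counts distinct fragment sequences; `unique_fraction =
#' unique / total` measures how non-redundant a species' tRF pool is
#' (a highly redundant pool has a fraction near 0). Rejected records
#' are excluded; per-type unique counts are over distinct sequences
#' within each assigned type.
#'
#' @param records Result of [classify_fragments()].
#' @return One-row tibble: `total`, `unique`, `unique_fraction`,
#'   `redundant_fraction`, and list-column `per_type_unique` (tibble of
#'   `trf_type`, `unique`).
#' @export
redundancy_stats <- function(records) {
  rec <- records[!is.na(records$trf_type), , drop = FALSE]
  total <- nrow(rec)
  if (!total) {
    return(tibble::tibble(total = 0L, unique = 0L, unique_fraction = 0,
                          redundant_fraction = 0,
                          per_type_unique = list(tibble::tibble(
                            trf_type = character(), unique = integer()))))
  }
  uniq <- length(unique(rec$seq))
  per_type <- rec |>
    dplyr::distinct(.data$trf_type, .data$seq) |>
    dplyr::count(.data$trf_type, name = "unique")
  tibble::tibble(
    total = total,
    unique = uniq,
    unique_fraction = uniq / total,
    redundant_fraction = 1 - uniq / total,
    per_type_unique = list(per_type)
  )
}

#' Correlation of tRF pool size with tRNA gene copy number
#'
#' Spearman correlations, across species, of (a) total tRF count and
#' (b) unique (non-redundant) tRF count against total tRNA gene copy
#' number. A constant margin yields a missing correlation with a
#' message.
#'
#' @param trf_summary Tibble with one row per species and columns
#'   `species`, `total_trfs`, `unique_trfs`, `trna_cn`.
#' @return Tibble with columns `metric` (`"total_trfs"`,
#'   `"unique_trfs"`), `n`, `spearman_rho`, `p_value`.
#' @export
trf_census_correlation <- function(trf_summary) {
  if (nrow(trf_summary) < 3L) {
    stop("correlation needs at least 3 species", call. = FALSE)
  }
  one <- function(v) {
    x <- trf_summary[[v]]; y <- trf_summary$trna_cn
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      message("constant values for ", v, ": correlation undefined")
      return(tibble::tibble(metric = v, n = length(x),
                            spearman_rho = NA_real_, p_value = NA_real_))
    }
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    tibble::tibble(metric = v, n = length(x),
                   spearman_rho = unname(ct$estimate), p_value = ct$p.value)
  }
  dplyr::bind_rows(one("total_trfs"), one("unique_trfs"))
}

#' Length spectrum of a tRF pool
#'
#' Histogram of fragment lengths per tRF type computed on non-redundant
#' sequences (each distinct sequence counted once within its type).
#'
#' @param records Result of [classify_fragments()].
#' @return Tibble of class `trf_spectrum` with columns `trf_type`,
#'   `length`, `n`; the per-type median length is attached as the
#'   `medians` attribute.
#' @export
length_spectrum <- function(records) {
  rec <- records[!is.na(records$trf_type) &
                   records$trf_type != "unclassified", , drop = FALSE]
  nr <- dplyr::distinct(rec, .data$trf_type, .data$seq, .data$length)
  out <- nr |>
    dplyr::count(.data$trf_type, .data$length, name = "n") |>
    dplyr::arrange(.data$trf_type, .data$length)
  attr(out, "medians") <- nr |>
    dplyr::group_by(.data$trf_type) |>
    dplyr::summarise(median_length = stats::median(.data$length),
                     .groups = "drop")
  class(out) <- c("trf_spectrum", class(out))
  out
}
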