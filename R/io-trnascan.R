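# tRNAscan-SE v2 tabular ".out" dialect: 3 header lines, then
# whitespace-delimited columns
#   seq name | tRNA # | begin | end | type | anticodon |
#   intron begin | intron end | score | [note]
# Coordinates are 1-based inclusive; minus-strand loci are conveyed by
# file begin > end. An extended dialect with semicolon-separated intron
# bounds (multiple introns per locus) is accepted.

.TRNASCAN_HEADER <- c(
  "Sequence\t\ttRNA\tBounds\ttRNA\tAnti\tIntron Bounds\tInf",
  "Name\ttRNA #\tBegin\tEnd\tType\tCodon\tBegin\tEnd\tScore\tNote",
  "--------\t------\t-----\t---\t----\t-----\t-----\t----\t-----\t----"
)

#' Read a tRNAscan-SE tabular output file
#'
#' Parses the tRNAscan-SE v2 `.out` dialect into a tidy per-locus table.
#' Minus-strand rows (file begin > end) are normalized immediately to
#' `begin <= end` with `strand = "-"`; all downstream arithmetic assumes
#' this single convention. An anticodon of `NNN` or `???` marks an
#' undetermined anticodon (stored as `NA`); such loci, and loci whose
#' note column contains "pseudo", are flagged as pseudogenes. Mature
#' length is the encoded length after intron removal (the
#' post-transcriptional CCA tail is not added).
#'
#' @param path Path to a tRNAscan-SE `.out` file.
#' @param genome_id Genome identifier attached to every locus; defaults
#'   to the file name without extension.
#' @return A tibble with one row per locus and columns `genome_id`,
#'   `seq_name`, `trna_num`, `begin`, `end`, `strand`, `isotype`,
#'   `anticodon`, `introns` (canonical `"beg-end;beg-end"` string, `""`
#'   when intronless), `n_introns`, `intron_length`, `score`, `note`,
#'   `is_pseudogene`, `gene_length`, `mature_length`.
#' @export
read_trnascan <- function(path, genome_id = NULL) {
  if (is.null(genome_id)) {
    genome_id <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path)
  if (length(lines) < 3L) stop("not a tRNAscan-SE file: fewer than 3 header lines")
  body <- lines[-(1:3)]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) return(empty_loci())

  fields <- strsplit(trimws(body), "[ \t]+")
  nf <- lengths(fields)
  bad <- which(nf < 9L)
  if (length(bad)) {
    stop(sprintf("line %d: expected >= 9 columns, found %d",
                 bad[1L] + 3L, nf[bad[1L]]), call. = FALSE)
  }
  col <- function(k) vapply(fields, `[[`, character(1), k)

  b_file <- suppressWarnings(as.integer(col(3L)))
  e_file <- suppressWarnings(as.integer(col(4L)))
  score <- suppressWarnings(as.numeric(col(9L)))
  bad <- which(is.na(b_file) | is.na(e_file) | is.na(score))
  if (length(bad)) {
    stop(sprintf("line %d: non-numeric coordinate or score", bad[1L] + 3L),
         call. = FALSE)
  }
  strand <- ifelse(b_file > e_file, "-", "+")
  begin <- pmin(b_file, e_file)
  end <- pmax(b_file, e_file)
  bad <- which(begin <= 0L)
  if (length(bad)) {
    stop(sprintf("line %d: non-positive coordinate %d", bad[1L] + 3L,
                 begin[bad[1L]]), call. = FALSE)
  }

  ib_raw <- col(7L); ie_raw <- col(8L)
  introns <- character(length(body))
  n_introns <- integer(length(body))
  intron_length <- integer(length(body))
  multi <- grepl(";", ib_raw, fixed = TRUE)
  # common case: single intron pair (or "0 0")
  ib1 <- suppressWarnings(as.integer(ib_raw[!multi]))
  ie1 <- suppressWarnings(as.integer(ie_raw[!multi]))
  bad <- which(is.na(ib1) | is.na(ie1))
  if (length(bad)) {
    stop(sprintf("line %d: malformed intron bounds",
                 which(!multi)[bad[1L]] + 3L), call. = FALSE)
  }
  has1 <- !(ib1 == 0L & ie1 == 0L)
  lo1 <- pmin(ib1, ie1); hi1 <- pmax(ib1, ie1)
  idx1 <- which(!multi)
  n_introns[idx1] <- as.integer(has1)
  intron_length[idx1] <- ifelse(has1, hi1 - lo1 + 1L, 0L)
  introns[idx1] <- ifelse(has1, paste0(lo1, "-", hi1), "")
  # extended dialect: semicolon-separated pairs
  for (i in which(multi)) {
    bs <- as.integer(strsplit(ib_raw[i], ";", fixed = TRUE)[[1]])
    es <- as.integer(strsplit(ie_raw[i], ";", fixed = TRUE)[[1]])
    if (anyNA(bs) || anyNA(es) || length(bs) != length(es)) {
      stop(sprintf("line %d: malformed intron bounds '%s'/'%s'",
                   i + 3L, ib_raw[i], ie_raw[i]), call. = FALSE)
    }
    keep <- !(bs == 0L & es == 0L)
    lo <- pmin(bs[keep], es[keep]); hi <- pmax(bs[keep], es[keep])
    o <- order(lo)
    lo <- lo[o]; hi <- hi[o]
    n_introns[i] <- length(lo)
    intron_length[i] <- sum(hi - lo + 1L)
    introns[i] <- paste(paste0(lo, "-", hi), collapse = ";")
  }
  chk <- which(n_introns > 0L)
  if (length(chk)) {
    segs <- strsplit(introns[chk], "[-;]")
    mins <- vapply(segs, function(x) min(as.integer(x)), integer(1))
    maxs <- vapply(segs, function(x) max(as.integer(x)), integer(1))
    bad <- chk[mins < begin[chk] | maxs > end[chk]]
    if (length(bad)) {
      stop(sprintf("line %d: intron outside gene bounds", bad[1L] + 3L),
           call. = FALSE)
    }
  }

  ac <- toupper(col(6L))
  ac[ac %in% c("NNN", "???")] <- NA_character_
  ac[!is.na(ac)] <- normalize_dna(ac[!is.na(ac)])
  note <- character(length(body))
  with_note <- nf >= 10L
  note[with_note] <- vapply(fields[with_note],
                            function(f) paste(f[10:length(f)], collapse = " "),
                            character(1))

  gene_length <- end - begin + 1L
  tibble::tibble(
    genome_id = genome_id,
    seq_name = col(1L),
    trna_num = as.integer(col(2L)),
    begin = begin, end = end, strand = strand,
    isotype = col(5L), anticodon = ac,
    introns = introns, n_introns = n_introns,
    intron_length = intron_length,
    score = score, note = note,
    is_pseudogene = is.na(ac) | grepl("pseudo", note, ignore.case = TRUE),
    gene_length = gene_length,
    mature_length = gene_length - intron_length
  )
}

#' An empty locus table with the canonical schema
#' @return Zero-row locus tibble.
#' @export
empty_loci <- function() {
  tibble::tibble(
    genome_id = character(), seq_name = character(), trna_num = integer(),
    begin = integer(), end = integer(), strand = character(),
    isotype = character(), anticodon = character(), introns = character(),
    n_introns = integer(), intron_length = integer(), score = numeric(),
    note = character(), is_pseudogene = logical(), gene_length = integer(),
    mature_length = integer()
  )
}

#' Read a directory of tRNAscan-SE files into one locus table
#'
#' @param dir Directory containing `.out` files, one per genome.
#' @param pattern File-name pattern (default `"\\.out$"`).
#' @return Combined locus tibble; `genome_id` is taken from each file
#'   name.
#' @export
read_trnascan_dir <- function(dir, pattern = "\\.out$") {
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE))
  if (!length(files)) stop("no tRNAscan-SE files found in ", dir)
  dplyr::bind_rows(lapply(files, read_trnascan))
}

#' Write loci back to tRNAscan-SE tabular format
#'
#' Inverse of [read_trnascan()]: minus-strand loci are emitted with file
#' begin > end, intronless loci as `0 0`, and undetermined anticodons as
#' `NNN`. Parsing the written file recovers the input table exactly
#' (round-trip stability).
#'
#' @param loci Locus tibble as produced by [read_trnascan()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trnascan <- function(loci, path) {
  n <- nrow(loci)
  if (!n) {
    writeLines(.TRNASCAN_HEADER, path)
    return(invisible(path))
  }
  minus <- loci$strand == "-"
  b <- ifelse(minus, loci$end, loci$begin)
  e <- ifelse(minus, loci$begin, loci$end)
  ib <- rep("0", n); ie <- rep("0", n)
  has_intron <- nzchar(loci$introns)
  if (any(has_intron)) {
    parts <- strsplit(loci$introns[has_intron], ";", fixed = TRUE)
    lo <- lapply(parts, function(p) sub("-.*", "", p))
    hi <- lapply(parts, function(p) sub(".*-", "", p))
    flip <- minus[has_intron]
    ib[has_intron] <- mapply(function(a, b, f) {
      paste(if (f) b else a, collapse = ";")
    }, lo, hi, flip)
    ie[has_intron] <- mapply(function(a, b, f) {
      paste(if (f) a else b, collapse = ";")
    }, lo, hi, flip)
  }
  ac <- ifelse(is.na(loci$anticodon), "NNN", loci$anticodon)
  rows <- paste(loci$seq_name, loci$trna_num, b, e, loci$isotype, ac,
                ib, ie, formatC(loci$score, format = "f", digits = 1),
                loci$note, sep = "\t")
  writeLines(c(.TRNASCAN_HEADER, rows), path)
  invisible(path)
}

#' Export loci as BED6
#'
#' Converts 1-based inclusive coordinates to BED's 0-based half-open
#' convention (`bed_start = begin - 1`, `bed_end = end`). The name field
#' is `genome_id:isotype-anticodon`; scores are rounded and clamped to
#' \[0, 1000\]. An empty locus table yields an empty file with no header.
#'
#' @param loci Locus tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(loci, path) {
  if (!nrow(loci)) {
    writeLines(character(), path)
    return(invisible(path))
  }
  ac <- ifelse(is.na(loci$anticodon), "NNN", loci$anticodon)
  bed <- paste(
    loci$seq_name,
    loci$begin - 1L,
    loci$end,
    paste0(loci$genome_id, ":", loci$isotype, "-", ac),
    pmin(pmax(round(loci$score), 0), 1000),
    loci$strand,
    sep = "\t"
  )
  writeLines(bed, path)
  invisible(path)
}
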