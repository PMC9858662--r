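# Standard genetic code, NCBI translation table 1, DNA alphabet.
# Three-letter amino-acid codes; stop codons marked "STOP".
.CODON_TABLE <- c(
  TTT = "Phe", TTC = "Phe", TTA = "Leu", TTG = "Leu",
  CTT = "Leu", CTC = "Leu", CTA = "Leu", CTG = "Leu",
  ATT = "Ile", ATC = "Ile", ATA = "Ile", ATG = "Met",
  GTT = "Val", GTC = "Val", GTA = "Val", GTG = "Val",
  TCT = "Ser", TCC = "Ser", TCA = "Ser", TCG = "Ser",
  CCT = "Pro", CCC = "Pro", CCA = "Pro", CCG = "Pro",
  ACT = "Thr", ACC = "Thr", ACA = "Thr", ACG = "Thr",
  GCT = "Ala", GCC = "Ala", GCA = "Ala", GCG = "Ala",
  TAT = "Tyr", TAC = "Tyr", TAA = "STOP", TAG = "STOP",
  CAT = "His", CAC = "His", CAA = "Gln", CAG = "Gln",
  AAT = "Asn", AAC = "Asn", AAA = "Lys", AAG = "Lys",
  GAT = "Asp", GAC = "Asp", GAA = "Glu", GAG = "Glu",
  TGT = "Cys", TGC = "Cys", TGA = "STOP", TGG = "Trp",
  CGT = "Arg", CGC = "Arg", CGA = "Arg", CGG = "Arg",
  AGT = "Ser", AGC = "Ser", AGA = "Arg", AGG = "Arg",
  GGT = "Gly", GGC = "Gly", GGA = "Gly", GGG = "Gly"
)

.STOP_CODONS <- c("TAA", "TAG", "TGA")

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Normalize nucleotide strings to canonical DNA form
#'
#' Upcases and maps RNA `U` to DNA `T`. DNA notation (T, not U) is the
#' canonical alphabet throughout the package; mature-tRNA sequences
#' distributed in RNA notation are mapped on ingest.
#'
#' @param x Character vector of nucleotide strings.
#' @param quiet Suppress the message emitted when U->T mapping occurs.
#' @return Character vector in uppercase DNA alphabet.
#' @export
#' @examples
#' normalize_dna(c("acgu", "ACGT"))
normalize_dna <- function(x, quiet = TRUE) {
  x <- toupper(x)
  had_u <- any(grepl("U", x, fixed = TRUE))
  x <- gsub("U", "T", x, fixed = TRUE)
  if (had_u && !quiet) message("RNA alphabet detected: U mapped to T")
  x
}

#' Display a DNA-notation sequence in RNA notation
#'
#' Purely a display transform (T -> U); all computation in the package
#' stays in DNA space.
#'
#' @param x Character vector of DNA-notation sequences.
#' @return Character vector with T replaced by U.
#' @export
dna_to_rna <- function(x) gsub("T", "U", toupper(x), fixed = TRUE)

.validate_triplet <- function(x, what = "anticodon") {
  x <- normalize_dna(x)
  bad_len <- nchar(x) != 3L
  if (any(bad_len)) {
    stop(sprintf("invalid %s '%s': length %d, expected 3",
                 what, x[bad_len][1L], nchar(x[bad_len][1L])), call. = FALSE)
  }
  chars <- strsplit(x, "", fixed = TRUE)
  for (i in seq_along(chars)) {
    hit <- which(!chars[[i]] %in% c("A", "C", "G", "T"))
    if (length(hit)) {
      stop(sprintf("invalid %s '%s': character '%s' at position %d not in {A,C,G,T}",
                   what, x[i], chars[[i]][hit[1L]], hit[1L]), call. = FALSE)
    }
  }
  x
}

#' Enumerate all 64 possible anticodons
#'
#' All 4^3 = 64 nucleotide triplets over the DNA alphabet, in
#' lexicographic order (AAA first, TTT last).
#'
#' @return Character vector of length 64.
#' @export
#' @examples
#' head(enumerate_anticodons())
enumerate_anticodons <- function() {
  nt <- c("A", "C", "G", "T")
  grid <- expand.grid(p3 = nt, p2 = nt, p1 = nt, stringsAsFactors = FALSE)
  sort(paste0(grid$p1, grid$p2, grid$p3))
}

#' Map an anticodon to the codon it decodes
#'
#' The decoded codon is the reverse complement of the anticodon (both
#' written 5'->3' in DNA notation). The map is an involution:
#' `anticodon_to_codon(anticodon_to_codon(x))` recovers `x`.
#'
#' @param anticodon Character vector of 3-letter anticodons (DNA or RNA
#'   notation; lowercase accepted).
#' @return Character vector of decoded codons.
#' @export
#' @examples
#' anticodon_to_codon("CAT")  # "ATG", the start codon
anticodon_to_codon <- function(anticodon) {
  ac <- .validate_triplet(anticodon)
  vapply(strsplit(ac, "", fixed = TRUE),
         function(ch) paste(rev(unname(.COMPLEMENT[ch])), collapse = ""),
         character(1))
}

#' Predict the tRNA isotype carried by an anticodon
#'
#' Decodes each anticodon to its codon (reverse complement) and looks
#' that codon up in the standard genetic code (NCBI translation
#' table 1). Anticodons whose decoded codon is one of the three standard
#' stop codons (anticodons TTA, CTA, TCA) are assigned the isotype
#' `"STOP"`. Non-standard codes are out of scope; annotated isotypes in
#' tRNAscan-SE files always take precedence over this prediction in the
#' census functions.
#'
#' @param anticodon Character vector of anticodons.
#' @return A tibble with columns `anticodon`, `decoded_codon`,
#'   `predicted_isotype`.
#' @export
#' @examples
#' predict_isotype(c("GCG", "TTA"))
predict_isotype <- function(anticodon) {
  ac <- .validate_triplet(anticodon)
  codon <- anticodon_to_codon(ac)
  tibble::tibble(
    anticodon = ac,
    decoded_codon = codon,
    predicted_isotype = unname(.CODON_TABLE[codon])
  )
}

#' Number of sense codons in the standard genetic code
#'
#' 64 codons minus the 3 standard stop codons.
#'
#' @return Integer, 61.
#' @export
count_sense_codons <- function() {
  64L - length(.STOP_CODONS)
}

#' The standard genetic code as a tidy table
#'
#' One row per codon with its reverse-complement anticodon and
#' amino-acid assignment under NCBI translation table 1.
#'
#' @return A tibble with columns `codon`, `anticodon`, `isotype`,
#'   `is_stop`.
#' @export
genetic_code_table <- function() {
  codons <- names(.CODON_TABLE)
  tibble::tibble(
    codon = codons,
    anticodon = anticodon_to_codon(codons),
    isotype = unname(.CODON_TABLE),
    is_stop = codons %in% .STOP_CODONS
  )
}

#' Anticodons complementary to stop codons
#'
#' @return Character vector of the three stop-complement anticodons.
#' @export
stop_complement_anticodons <- function() {
  sort(anticodon_to_codon(.STOP_CODONS))
}
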