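#' Build per-genome tRNA censuses
#'
#' Summarises a locus table into one row per genome: functional locus
#' count, pseudogene count, anticodon repertoire, per-anticodon and
#' per-isotype counts, intron content, and gene/mature length
#' summaries. Pseudogenes (loci without an assignable anticodon, or
#' flagged "pseudo") are counted separately and excluded from the
#' anticodon/isotype tallies and from length summaries; intron counts
#' cover all loci. The `combinations` column records the annotated
#' isotype (never the genetic-code prediction) paired with each
#' anticodon.
#'
#' @param loci Locus tibble from [read_trnascan()] (may span many
#'   genomes).
#' @return A tibble, one row per genome, with scalar columns
#'   `genome_id`, `total_trna`, `pseudogene_count`, `repertoire_size`,
#'   `n_loci`, `intron_locus_count`, `gene_length_mean`,
#'   `gene_length_median`, `mature_length_mean`, `mature_length_median`
#'   and list-columns `anticodon_counts`, `isotype_counts`,
#'   `intron_distribution` (named integer vectors) and `combinations`
#'   (tibble of isotype, anticodon, n).
#' @export
build_census <- function(loci) {
  if (!nrow(loci)) {
    return(tibble::tibble(
      genome_id = character(), total_trna = integer(),
      pseudogene_count = integer(), repertoire_size = integer(),
      n_loci = integer(), intron_locus_count = integer(),
      gene_length_mean = numeric(), gene_length_median = numeric(),
      mature_length_mean = numeric(), mature_length_median = numeric(),
      anticodon_counts = list(), isotype_counts = list(),
      intron_distribution = list(), combinations = list()
    ))
  }
  summarize_one <- function(d) {
    fun <- d[!d$is_pseudogene, ]
    ac_tab <- table(fun$anticodon)
    iso_tab <- table(fun$isotype)
    comb <- dplyr::count(fun, .data$isotype, .data$anticodon, name = "n")
    tibble::tibble(
      total_trna = nrow(fun),
      pseudogene_count = sum(d$is_pseudogene),
      repertoire_size = length(ac_tab),
      n_loci = nrow(d),
      intron_locus_count = sum(d$n_introns >= 1L),
      gene_length_mean = if (nrow(fun)) mean(fun$gene_length) else NA_real_,
      gene_length_median = if (nrow(fun)) stats::median(fun$gene_length) else NA_real_,
      mature_length_mean = if (nrow(fun)) mean(fun$mature_length) else NA_real_,
      mature_length_median = if (nrow(fun)) stats::median(fun$mature_length) else NA_real_,
      anticodon_counts = list(stats::setNames(as.integer(ac_tab), names(ac_tab))),
      isotype_counts = list(stats::setNames(as.integer(iso_tab), names(iso_tab))),
      intron_distribution = list({
        tab <- table(d$n_introns)
        stats::setNames(as.integer(tab), names(tab))
      }),
      combinations = list(comb)
    )
  }
  out <- loci |>
    dplyr::group_by(.data$genome_id) |>
    dplyr::group_modify(~ summarize_one(.x)) |>
    dplyr::ungroup()
  out
}

#' Apply the genome-level repertoire filter
#'
#' Removes genomes whose anticodon repertoire is too small to represent
#' a credible complete annotation. "Fewer than `min_isoacceptors`
#' isoacceptors" is read as fewer than that many *distinct anticodons*
#' (isoacceptor = anticodon identity); `on = "loci"` switches to a
#' total-locus-count reading for comparison.
#'
#' @param censuses Census tibble from [build_census()].
#' @param min_isoacceptors Minimum repertoire size to retain (default
#'   20); a genome with exactly this value is retained.
#' @param on Filter on `"isoacceptors"` (distinct anticodons, default)
#'   or `"loci"` (functional locus count).
#' @return A list with tibbles `retained` and `removed`; `removed`
#'   carries a `reason` column. The two partitions are disjoint and
#'   together equal the input.
#' @export
filter_genomes <- function(censuses, min_isoacceptors = 20L,
                           on = c("isoacceptors", "loci")) {
  on <- match.arg(on)
  value <- if (on == "isoacceptors") censuses$repertoire_size else censuses$total_trna
  keep <- value >= min_isoacceptors
  removed <- censuses[!keep, , drop = FALSE]
  if (nrow(removed)) {
    removed$reason <- sprintf("%s = %d < %d", on,
                              value[!keep], as.integer(min_isoacceptors))
  } else {
    removed$reason <- character(0)
  }
  list(retained = censuses[keep, , drop = FALSE], removed = removed)
}

# Annotated isotypes treated as consistent with a standard-code
# prediction: initiator Met variants decode ATG; Sec is inserted at the
# TCA (opal-complement) anticodon by the standard recoding machinery.
.isotype_matches <- function(annotated, predicted, anticodon) {
  annotated == predicted |
    (annotated %in% c("iMet", "fMet") & predicted == "Met") |
    (annotated == "Sec" & !is.na(anticodon) & anticodon == "TCA")
}

#' Find unusual anticodon-isotype combinations
#'
#' Returns observed (isotype, anticodon) combinations whose annotated
#' isotype differs from the standard-genetic-code prediction for that
#' anticodon. Initiator-Met variants (iMet/fMet with CAT) and Sec at
#' TCA are treated as standard; suppressor tRNAs (isotype `Sup`) always
#' count as unusual. Pseudogenes are excluded.
#'
#' @param censuses Census tibble from [build_census()].
#' @return Tibble with columns `genome_id`, `isotype`, `anticodon`,
#'   `predicted_isotype`, `n`.
#' @export
unusual_combinations <- function(censuses) {
  combs <- censuses |>
    dplyr::select("genome_id", "combinations") |>
    tidyr::unnest("combinations")
  if (!nrow(combs)) {
    return(tibble::tibble(genome_id = character(), isotype = character(),
                          anticodon = character(),
                          predicted_isotype = character(), n = integer()))
  }
  pred <- predict_isotype(combs$anticodon)
  combs$predicted_isotype <- pred$predicted_isotype
  unusual <- combs$isotype == "Sup" |
    !.isotype_matches(combs$isotype, combs$predicted_isotype, combs$anticodon)
  combs[unusual, c("genome_id", "isotype", "anticodon",
                   "predicted_isotype", "n")]
}
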