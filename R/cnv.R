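#' Intraspecific copy-number-variation summaries
#'
#' Groups genomes by the metadata species string (kept verbatim; strain
#' labels belong in a separate metadata column) and summarises the
#' spread of total tRNA copy number and anticodon repertoire across the
#' genomes of each species. `fold_range = cn_max / cn_min` is the
#' headline CNV statistic; it is reported missing (with a flag) when
#' `cn_min` is 0. Species represented by fewer than `min_genomes`
#' genomes are excluded and listed in the `excluded_species` attribute.
#'
#' @param censuses Census tibble.
#' @param metadata Metadata tibble.
#' @param min_genomes Minimum genomes per species (default 2).
#' @return Tibble, one row per qualifying species, with columns
#'   `species`, `n_genomes`, `cn_min`, `cn_max`, `cn_mean`, `cn_sd`,
#'   `fold_range`, `fold_range_defined`, `repertoire_min`,
#'   `repertoire_max`, `repertoire_varies`.
#' @export
species_cnv <- function(censuses, metadata, min_genomes = 2L) {
  joined <- join_metadata(censuses, metadata)
  tab <- joined |>
    dplyr::count(.data$species, name = "n_genomes")
  excluded <- tab$species[tab$n_genomes < min_genomes]
  keep <- tab$species[tab$n_genomes >= min_genomes]
  if (!length(keep)) {
    out <- tibble::tibble(
      species = character(), n_genomes = integer(), cn_min = integer(),
      cn_max = integer(), cn_mean = numeric(), cn_sd = numeric(),
      fold_range = numeric(), fold_range_defined = logical(),
      repertoire_min = integer(), repertoire_max = integer(),
      repertoire_varies = logical()
    )
    attr(out, "excluded_species") <- excluded
    return(out)
  }
  out <- joined |>
    dplyr::filter(.data$species %in% keep) |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(
      n_genomes = dplyr::n(),
      cn_min = min(.data$total_trna),
      cn_max = max(.data$total_trna),
      cn_mean = mean(.data$total_trna),
      cn_sd = stats::sd(.data$total_trna),
      repertoire_min = min(.data$repertoire_size),
      repertoire_max = max(.data$repertoire_size),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      fold_range_defined = .data$cn_min > 0L,
      fold_range = dplyr::if_else(.data$fold_range_defined,
                                  .data$cn_max / .data$cn_min, NA_real_),
      repertoire_varies = .data$repertoire_min < .data$repertoire_max
    ) |>
    dplyr::select("species", "n_genomes", "cn_min", "cn_max", "cn_mean",
                  "cn_sd", "fold_range", "fold_range_defined",
                  "repertoire_min", "repertoire_max", "repertoire_varies")
  attr(out, "excluded_species") <- excluded
  out
}

#' Genome-by-anticodon presence table within a species
#'
#' Boolean wide table over the genomes of one species: does each genome
#' carry at least one functional copy of each anticodon observed in the
#' species? Column sums give per-anticodon prevalence; non-constant
#' columns mark anticodons gained or lost between strains.
#'
#' @param censuses Census tibble restricted to one species (>= 2
#'   genomes).
#' @return Wide tibble: `genome_id` plus one logical column per
#'   anticodon observed in the species.
#' @export
anticodon_presence_matrix <- function(censuses) {
  if (nrow(censuses) < 2L) {
    stop("presence matrix needs at least 2 genomes", call. = FALSE)
  }
  long <- counts_long(censuses, "anticodon")
  wide <- long |>
    dplyr::mutate(present = .data$n >= 1L) |>
    dplyr::select("genome_id", "anticodon", "present") |>
    tidyr::pivot_wider(names_from = "anticodon", values_from = "present",
                       values_fill = FALSE)
  wide[order(wide$genome_id), c("genome_id", sort(setdiff(names(wide), "genome_id")))]
}
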