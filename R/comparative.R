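#' Join censuses to genome metadata
#'
#' Inner join on `genome_id`; genomes present in only one table are
#' dropped with a warning.
#'
#' @param censuses Census tibble.
#' @param metadata Metadata tibble.
#' @return Joined tibble.
#' @export
join_metadata <- function(censuses, metadata) {
  out <- dplyr::inner_join(censuses, metadata, by = "genome_id")
  n_lost <- nrow(censuses) - nrow(out)
  if (n_lost > 0) {
    warning(n_lost, " genome(s) without metadata dropped", call. = FALSE)
  }
  out
}

.summary_stats <- function(v) {
  v <- v[is.finite(v)]
  n <- length(v)
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  tibble::tibble(
    n = n,
    mean = mean(v),
    sd = if (n >= 2) stats::sd(v) else NA_real_,
    se = if (n >= 2) stats::sd(v) / sqrt(n) else NA_real_,
    median = q[2L],
    iqr = q[3L] - q[1L]
  )
}

#' Per-domain (or per-group) summary statistics
#'
#' Mean, SD, SE = SD/sqrt(n), median and IQR (Q3 - Q1, linear
#' interpolation quantiles) for numeric census variables, aggregated by
#' taxon. A single-genome stratum reports SD/SE as missing, not zero.
#'
#' @param censuses Census tibble.
#' @param metadata Metadata tibble.
#' @param vars Character vector of numeric census columns to summarise.
#' @param by Grouping column(s) in the metadata, default `"domain"`.
#' @return Long tibble with one row per stratum x variable.
#' @export
summarize_domain <- function(censuses, metadata,
                             vars = c("total_trna", "repertoire_size"),
                             by = "domain") {
  joined <- join_metadata(censuses, metadata)
  empty <- setdiff(unique(metadata[[by[1L]]]), unique(joined[[by[1L]]]))
  if (length(empty)) {
    warning("stratum with no genomes omitted: ",
            paste(empty, collapse = ", "), call. = FALSE)
  }
  joined |>
    dplyr::select(dplyr::all_of(c(by, vars))) |>
    tidyr::pivot_longer(dplyr::all_of(vars), names_to = "variable") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(by, "variable")))) |>
    dplyr::reframe(.summary_stats(.data$value)) |>
    dplyr::ungroup()
}

#' Per-genome anticodon (or isotype) counts in long form
#'
#' Expands the census list-columns into a long table, including
#' explicit zero rows for keys absent from a genome so that per-domain
#' means include zeros.
#'
#' @param censuses Census tibble.
#' @param what `"anticodon"` or `"isotype"`.
#' @return Tibble with columns `genome_id`, the key column, `n`.
#' @export
counts_long <- function(censuses, what = c("anticodon", "isotype")) {
  what <- match.arg(what)
  col <- paste0(what, "_counts")
  long <- censuses |>
    dplyr::select("genome_id", dplyr::all_of(col)) |>
    dplyr::mutate(.tab = purrr::map(.data[[col]], function(v) {
      tibble::tibble(key = names(v), n = unname(v))
    })) |>
    dplyr::select("genome_id", ".tab") |>
    tidyr::unnest(".tab")
  long <- tidyr::complete(long, .data$genome_id, .data$key,
                          fill = list(n = 0L))
  names(long)[names(long) == "key"] <- what
  long
}

#' Cross-domain pervasiveness of anticodon-isotype combinations
#'
#' For every (isotype, anticodon) combination observed in the cohort
#' and every domain, the fraction of that domain's genomes carrying at
#' least one functional copy, together with the mean copy number per
#' genome (zeros included for genomes lacking the combination).
#'
#' @param censuses Filtered census tibble.
#' @param metadata Metadata tibble.
#' @return A tibble of class `trna_pervasiveness` with columns
#'   `isotype`, `anticodon`, `domain`, `n_genomes`, `n_present`,
#'   `pervasiveness`, `mean_cn`.
#' @export
pervasiveness <- function(censuses, metadata) {
  joined <- join_metadata(censuses, metadata)
  denom <- joined |>
    dplyr::count(.data$domain, name = "n_genomes")
  zero <- setdiff(unique(metadata$domain), denom$domain)
  if (length(zero)) {
    stop("domain with zero genomes: ", paste(zero, collapse = ", "),
         call. = FALSE)
  }
  combs <- joined |>
    dplyr::select("genome_id", "domain", "combinations") |>
    tidyr::unnest("combinations")
  cells <- combs |>
    dplyr::group_by(.data$isotype, .data$anticodon, .data$domain) |>
    dplyr::summarise(n_present = dplyr::n_distinct(.data$genome_id),
                     total_cn = sum(.data$n), .groups = "drop") |>
    tidyr::complete(tidyr::nesting(!!rlang::sym("isotype"),
                                   !!rlang::sym("anticodon")),
                    domain = denom$domain,
                    fill = list(n_present = 0L, total_cn = 0L)) |>
    dplyr::left_join(denom, by = "domain") |>
    dplyr::mutate(pervasiveness = .data$n_present / .data$n_genomes,
                  mean_cn = .data$total_cn / .data$n_genomes) |>
    dplyr::select("isotype", "anticodon", "domain", "n_genomes",
                  "n_present", "pervasiveness", "mean_cn") |>
    dplyr::arrange(.data$isotype, .data$anticodon, .data$domain)
  class(cells) <- c("trna_pervasiveness", class(cells))
  cells
}

#' Pivot a pervasiveness table to one row per combination
#'
#' @param pm Result of [pervasiveness()].
#' @param value Which cell value to spread (`"pervasiveness"` or
#'   `"mean_cn"`).
#' @return Wide tibble with one column per domain; combinations absent
#'   from a domain get exactly 0.
#' @export
pervasiveness_wide <- function(pm, value = "pervasiveness") {
  tidyr::pivot_wider(
    dplyr::select(tibble::as_tibble(pm), "isotype", "anticodon", "domain",
                  dplyr::all_of(value)),
    names_from = "domain", values_from = dplyr::all_of(value),
    values_fill = 0
  )
}

.GROUP_LEVELS <- c("alpha", "beta", "gamma", "delta", "epsilon", "other")

#' Classify combinations into cross-domain universality groups
#'
#' Greek-letter universality classes from the three per-domain
#' pervasiveness cells: `alpha` combinations are present in more than
#' `high` of genomes in all three domains; `beta` are frequent in
#' eukaryotes and archaea but avoided (cell <= `low`) by bacteria;
#' `gamma` frequent in both prokaryote domains and avoided by
#' eukaryotes; `delta` frequent only in eukaryotes; `epsilon` rare or
#' absent everywhere. Combinations with mixed intermediate profiles
#' fall in `other`.
#'
#' @param pm Result of [pervasiveness()]; must contain all three
#'   domains.
#' @param high High-pervasiveness threshold (strict `>`, default 0.70).
#' @param low Avoidance threshold (`<=`, default 0.30).
#' @return Wide tibble with per-domain cells and a `group` factor.
#' @export
classify_groups <- function(pm, high = 0.70, low = 0.30) {
  if (high <= low) stop("configuration error: high must exceed low", call. = FALSE)
  wide <- pervasiveness_wide(pm)
  need <- c("Eukarya", "Archaea", "Bacteria")
  missing <- setdiff(need, names(wide))
  if (length(missing)) {
    stop("pervasiveness matrix lacks domain(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  euk <- wide$Eukarya; arc <- wide$Archaea; bac <- wide$Bacteria
  group <- dplyr::case_when(
    euk > high & arc > high & bac > high ~ "alpha",
    euk > high & arc > high & bac <= low ~ "beta",
    arc > high & bac > high & euk <= low ~ "gamma",
    euk > high & arc <= low & bac <= low ~ "delta",
    euk <= low & arc <= low & bac <= low ~ "epsilon",
    .default = "other"
  )
  wide$group <- factor(group, levels = .GROUP_LEVELS)
  wide
}

#' Venn-region counts of high-pervasiveness combinations
#'
#' For each domain, the set of combinations exceeding `threshold`
#' pervasiveness; counts of the seven Venn regions over the three sets.
#' Region counts sum to the size of the union.
#'
#' @param pm Result of [pervasiveness()].
#' @param threshold Strict pervasiveness cutoff (default 0.70).
#' @return Tibble with columns `region` (e.g. `"Eukarya"`,
#'   `"Eukarya+Bacteria"`, `"Eukarya+Archaea+Bacteria"`) and `count`,
#'   all seven regions always present.
#' @export
venn_high_pervasiveness <- function(pm, threshold = 0.70) {
  wide <- pervasiveness_wide(pm)
  doms <- c("Eukarya", "Archaea", "Bacteria")
  for (d in setdiff(doms, names(wide))) wide[[d]] <- 0
  memb <- cbind(E = wide$Eukarya > threshold,
                A = wide$Archaea > threshold,
                B = wide$Bacteria > threshold)
  memb <- memb[rowSums(memb) > 0L, , drop = FALSE]
  patterns <- list(
    "Eukarya" = c(TRUE, FALSE, FALSE),
    "Archaea" = c(FALSE, TRUE, FALSE),
    "Bacteria" = c(FALSE, FALSE, TRUE),
    "Eukarya+Archaea" = c(TRUE, TRUE, FALSE),
    "Eukarya+Bacteria" = c(TRUE, FALSE, TRUE),
    "Archaea+Bacteria" = c(FALSE, TRUE, TRUE),
    "Eukarya+Archaea+Bacteria" = c(TRUE, TRUE, TRUE)
  )
  counts <- vapply(patterns, function(p) {
    sum(memb[, 1L] == p[1L] & memb[, 2L] == p[2L] & memb[, 3L] == p[3L])
  }, integer(1))
  tibble::tibble(region = names(patterns), count = unname(counts))
}

#' Per-genome tRNA and protein-coding gene densities
#'
#' Loci per megabase of genome: `trna_density = total_trna /
#' genome_size_mb` and `protein_density = protein_coding_genes /
#' genome_size_mb`. Genomes without metadata are skipped with a
#' warning.
#'
#' @param censuses Census tibble.
#' @param metadata Metadata tibble.
#' @return Tibble with `genome_id`, `species`, `domain`,
#'   `genome_size_mb`, `total_trna`, `trna_density`, `protein_density`.
#' @export
gene_density <- function(censuses, metadata) {
  joined <- join_metadata(censuses, metadata)
  joined |>
    dplyr::transmute(
      .data$genome_id, .data$species, .data$domain, .data$genome_size_mb,
      .data$total_trna,
      trna_density = .data$total_trna / .data$genome_size_mb,
      protein_density = .data$protein_coding_genes / .data$genome_size_mb
    )
}
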