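make_cohort_censuses <- function(spec_list) {
  # spec_list: list of list(genome_id, domain, combos = tibble(isotype, anticodon, n))
  censuses <- dplyr::bind_rows(lapply(spec_list, function(s) {
    loci <- make_loci(s$genome_id,
                      rep(s$combos$isotype, s$combos$n),
                      rep(s$combos$anticodon, s$combos$n))
    build_census(loci)
  }))
  metadata <- tibble::tibble(
    genome_id = vapply(spec_list, `[[`, "", "genome_id"),
    species = paste("sp", seq_along(spec_list)),
    domain = vapply(spec_list, `[[`, "", "domain"),
    group = "grp",
    genome_size_mb = 5,
    protein_coding_genes = 1000L
  )
  list(censuses = censuses, metadata = metadata)
}

random_cohort <- function(seed, n_genomes = 8L) {
  set.seed(seed)
  pool <- predict_isotype(sample(enumerate_anticodons(), 12L))
  pool <- pool[pool$predicted_isotype != "STOP", ]
  specs <- lapply(seq_len(n_genomes), function(i) {
    k <- sample(2:nrow(pool), 1L)
    rows <- sample(nrow(pool), k)
    list(genome_id = sprintf("g%02d", i),
         domain = sample(c("Eukarya", "Archaea", "Bacteria"), 1L),
         combos = tibble::tibble(isotype = pool$predicted_isotype[rows],
                                 anticodon = pool$anticodon[rows],
                                 n = sample(1:5, k, replace = TRUE)))
  })
  # guarantee every domain is represented
  specs[[1L]]$domain <- "Eukarya"
  specs[[2L]]$domain <- "Archaea"
  specs[[3L]]$domain <- "Bacteria"
  make_cohort_censuses(specs)
}

test_that("summary statistics use SE = SD/sqrt(n) and interpolated quantiles", {
  x <- c(1, 2, 3)
  s <- trnaome:::.summary_stats(x)
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 1)
  expect_equal(s$se, 1 / sqrt(3))
  expect_equal(s$median, 2)
  expect_equal(s$iqr, 1)  # linear interpolation: Q3 = 2.5, Q1 = 1.5

  co <- random_cohort(1)
  sm <- summarize_domain(co$censuses, co$metadata)
  # cross-check one stratum against direct computation
  euk <- co$censuses$total_trna[
    co$censuses$genome_id %in% co$metadata$genome_id[co$metadata$domain == "Eukarya"]]
  row <- sm[sm$domain == "Eukarya" & sm$variable == "total_trna", ]
  expect_equal(row$mean, mean(euk))
  expect_equal(row$median, unname(stats::quantile(euk, 0.5)))
})

test_that("a single-genome stratum reports missing dispersion, not zero", {
  co <- make_cohort_censuses(list(
    list(genome_id = "g1", domain = "Eukarya",
         combos = tibble::tibble(isotype = "Met", anticodon = "CAT", n = 3L))
  ))
  sm <- summarize_domain(co$censuses, co$metadata)
  expect_true(all(is.na(sm$sd)))
  expect_true(all(is.na(sm$se)))
})

test_that("pervasiveness cells are genome fractions with zeros for absences", {
  specs <- lapply(1:4, function(i) {
    combos <- tibble::tibble(isotype = "Met", anticodon = "CAT", n = 2L)
    if (i <= 2) {
      combos <- dplyr::bind_rows(combos,
        tibble::tibble(isotype = "Leu", anticodon = "TAA", n = 1L))
    }
    list(genome_id = paste0("b", i), domain = "Bacteria", combos = combos)
  })
  co <- make_cohort_censuses(specs)
  pm <- pervasiveness(co$censuses, co$metadata)
  leu <- pm[pm$isotype == "Leu" & pm$anticodon == "TAA", ]
  expect_equal(leu$pervasiveness, 0.5)
  expect_equal(leu$mean_cn, 0.5)  # 2 copies over 4 genomes
  met <- pm[pm$isotype == "Met" & pm$anticodon == "CAT", ]
  expect_equal(met$pervasiveness, 1.0)
  expect_true(all(pm$pervasiveness >= 0 & pm$pervasiveness <= 1))
})

test_that("pervasiveness matches the brute-force tally and ignores genome order", {
  for (seed in 1:15) {
    co <- random_cohort(seed)
    pm <- pervasiveness(co$censuses, co$metadata)
    ref <- oracle_pervasiveness(co$censuses, co$metadata)
    merged <- merge(as.data.frame(pm), ref,
                    by = c("isotype", "anticodon", "domain"),
                    suffixes = c("", "_ref"))
    expect_identical(nrow(merged), nrow(pm))
    expect_equal(merged$pervasiveness, merged$pervasiveness_ref)
    expect_equal(merged$mean_cn, merged$mean_cn_ref)

    shuffled <- co$censuses[sample(nrow(co$censuses)), ]
    pm2 <- pervasiveness(shuffled, co$metadata)
    expect_equal(as.data.frame(pm2), as.data.frame(pm))
  }
})

test_that("pervasiveness errors on a domain with zero genomes", {
  co <- random_cohort(3)
  arc_ids <- co$metadata$genome_id[co$metadata$domain == "Archaea"]
  cen <- co$censuses[!co$censuses$genome_id %in% arc_ids, ]
  expect_error(pervasiveness(cen, co$metadata), "Archaea")
})

test_that("Greek-group classification applies the threshold rules", {
  cells <- tibble::tibble(
    isotype = c("A", "B", "C", "D", "E", "F"),
    anticodon = c("AAA", "AAC", "AAG", "AAT", "ACA", "ACC"),
    domain = "x"
  )
  pm <- tidyr::expand_grid(cells[, 1:2],
                           domain = c("Eukarya", "Archaea", "Bacteria"))
  vals <- rbind(
    c(0.90, 0.80, 0.75),  # alpha
    c(0.95, 0.85, 0.05),  # beta
    c(0.10, 0.88, 0.90),  # gamma
    c(0.85, 0.05, 0.30),  # delta (bac exactly at low)
    c(0.30, 0.30, 0.30),  # epsilon (boundary: <= low everywhere)
    c(0.85, 0.10, 0.85)   # other (mixed)
  )
  pm$pervasiveness <- as.vector(t(vals))
  pm$mean_cn <- 1
  class(pm) <- c("trna_pervasiveness", class(pm))
  got <- classify_groups(pm)
  got <- got[match(cells$isotype, got$isotype), ]
  expect_identical(as.character(got$group),
                   c("alpha", "beta", "gamma", "delta", "epsilon", "other"))
  expect_error(classify_groups(pm, high = 0.3, low = 0.3), "configuration")
})

test_that("group labels match an independent rule evaluator on random matrices", {
  set.seed(42)
  for (rep in 1:200) {
    cells <- round(runif(3), 2)
    pm <- tibble::tibble(
      isotype = "X", anticodon = "AAA",
      domain = c("Eukarya", "Archaea", "Bacteria"),
      n_genomes = 10L, n_present = 1L,
      pervasiveness = cells, mean_cn = 1
    )
    class(pm) <- c("trna_pervasiveness", class(pm))
    got <- as.character(classify_groups(pm)$group)
    expect_identical(got, oracle_group_label(cells[1L], cells[2L], cells[3L]))
  }
  # every combination gets exactly one label
  co <- random_cohort(7)
  pm <- pervasiveness(co$censuses, co$metadata)
  labels <- classify_groups(pm)
  expect_identical(nrow(labels),
                   nrow(unique(as.data.frame(pm)[, c("isotype", "anticodon")])))
  expect_false(anyNA(labels$group))
})

test_that("Venn regions match brute-force set algebra and sum to the union", {
  # three identical sets
  pm <- tidyr::expand_grid(
    tibble::tibble(isotype = "X", anticodon = enumerate_anticodons()[1:26]),
    domain = c("Eukarya", "Archaea", "Bacteria"))
  pm$pervasiveness <- 0.9; pm$mean_cn <- 1
  class(pm) <- c("trna_pervasiveness", class(pm))
  v <- venn_high_pervasiveness(pm)
  expect_identical(v$count[v$region == "Eukarya+Archaea+Bacteria"], 26L)
  expect_identical(sum(v$count), 26L)

  # randomized cohorts against the oracle
  for (seed in 1:15) {
    co <- random_cohort(seed + 100)
    pm <- pervasiveness(co$censuses, co$metadata)
    thr <- runif(1, 0.1, 0.9)
    v <- venn_high_pervasiveness(pm, threshold = thr)
    wide <- pervasiveness_wide(pm)
    key <- paste(wide$isotype, wide$anticodon)
    ref <- oracle_venn(key[wide$Eukarya > thr], key[wide$Archaea > thr],
                       key[wide$Bacteria > thr])
    expect_identical(setNames(v$count, v$region), ref)
    expect_true(all(v$count >= 0L))
    expect_identical(sum(v$count),
                     length(unique(c(key[wide$Eukarya > thr],
                                     key[wide$Archaea > thr],
                                     key[wide$Bacteria > thr]))))
  }
})

test_that("gene densities divide counts by genome size", {
  co <- random_cohort(5)
  co$metadata$genome_size_mb[1L] <- 1500
  cen1 <- co$censuses$genome_id[1L]
  co$censuses$total_trna[co$censuses$genome_id == cen1] <- 10471L
  d <- gene_density(co$censuses, co$metadata)
  expect_equal(d$trna_density[d$genome_id == cen1], 10471 / 1500,
               tolerance = 1e-12)
  expect_lt(abs(d$trna_density[d$genome_id == cen1] - 6.98), 0.01)
  # exact inverse identity for every genome
  expect_equal(d$trna_density * d$genome_size_mb, as.numeric(d$total_trna))
})
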