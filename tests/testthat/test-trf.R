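demo_models <- function() {
  set.seed(123)
  generate_trna_models(5L, seed = 123L)
}

test_that("fragments are typed by their position on the source tRNA", {
  models <- demo_models()
  m1 <- models$mature_seq[1L]
  t1 <- models$trailer_seq[1L]

  frag5 <- substr(m1, 1L, 18L)
  frag3 <- substr(m1, nchar(m1) - 21L, nchar(m1))
  frag1 <- substr(t1, 1L, 15L)
  rec <- classify_fragments(c(a = frag5, b = frag3, c = frag1), models)
  expect_identical(rec$trf_type, c("tRF-5", "tRF-3", "tRF-1"))
  expect_identical(rec$sources[[1L]], "tRNA001")
  expect_true(all(verify_fragments(rec, models)))
})

test_that("3' fragments spanning the post-transcriptional CCA are tagged", {
  models <- demo_models()
  m1 <- models$mature_seq[1L]
  frag <- paste0(substr(m1, nchar(m1) - 16L, nchar(m1)), "CCA")
  rec <- classify_fragments(frag, models)
  expect_identical(rec$trf_type, "tRF-3")
  expect_true(rec$cca_matched)
  expect_true(all(verify_fragments(rec, models)))
})

test_that("multi-copy genes accumulate sources; ambiguity follows the priority", {
  models <- demo_models()
  models$mature_seq[2L] <- models$mature_seq[1L]  # near-identical gene copies
  frag <- substr(models$mature_seq[1L], 1L, 16L)
  rec <- classify_fragments(frag, models)
  expect_identical(rec$n_sources, 2L)
  expect_identical(rec$trf_type, "tRF-5")

  # a fragment that is both a mature prefix and a trailer prefix
  models$trailer_seq[3L] <- paste0(substr(models$mature_seq[1L], 1L, 20L), "TTTT")
  rec2 <- classify_fragments(substr(models$mature_seq[1L], 1L, 14L), models)
  expect_identical(rec2$trf_type, "tRF-5")  # priority tRF-5 > tRF-1
  expect_true(rec2$ambiguous)
})

test_that("short fragments are rejected with a reason, misses are unclassified", {
  models <- demo_models()
  rec <- classify_fragments(c(x = "ACGTACGTACGT",            # 12 nt
                              y = strrep("ACGT", 5)), models)
  expect_true(is.na(rec$trf_type[1L]))
  expect_match(rec$reason[1L], "minimum 13")
  expect_identical(rec$trf_type[2L], "unclassified")
})

test_that("classification is order-independent over models", {
  models <- demo_models()
  pool <- generate_trf_pool(models, n_distinct = 40L, seed = 5L)
  a <- classify_fragments(setNames(pool$seq, pool$fragment_id), models)
  b <- classify_fragments(setNames(pool$seq, pool$fragment_id),
                          models[rev(seq_len(nrow(models))), ])
  expect_identical(a$trf_type, b$trf_type)
  expect_identical(lapply(a$sources, sort), lapply(b$sources, sort))
})

test_that("redundancy statistics count distinct sequences", {
  models <- demo_models()
  pool <- generate_trf_pool(models, n_distinct = 100L, duplication_factor = 1,
                            seed = 7L)
  rec <- classify_fragments(setNames(pool$seq, pool$fragment_id), models)
  rs <- redundancy_stats(rec)
  expect_identical(rs$total, nrow(pool))
  expect_equal(rs$unique_fraction, rs$unique / rs$total)

  # 100 copies of one sequence
  one <- classify_fragments(setNames(rep(substr(models$mature_seq[1L], 1L, 20L), 100),
                                     paste0("f", 1:100)), models)
  rs1 <- redundancy_stats(one)
  expect_identical(rs1$unique, 1L)
  expect_equal(rs1$unique_fraction, 0.01)

  # mixed pools against the set-based oracle
  for (seed in 1:10) {
    pool <- generate_trf_pool(models, n_distinct = 30L,
                              duplication_factor = 3, seed = seed)
    rec <- classify_fragments(setNames(pool$seq, pool$fragment_id), models)
    rs <- redundancy_stats(rec)
    ref <- oracle_redundancy(rec$seq[!is.na(rec$trf_type)])
    expect_identical(rs$total, ref$total)
    expect_identical(rs$unique, ref$unique)
    expect_equal(rs$unique_fraction, ref$unique_fraction)
    expect_true(rs$unique <= rs$total)
    expect_true(rs$unique_fraction > 0 && rs$unique_fraction <= 1)
    per_type <- rs$per_type_unique[[1L]]
    expect_identical(sum(per_type$unique),
                     nrow(unique(data.frame(t = rec$trf_type, s = rec$seq)[
                       !is.na(rec$trf_type), ])))
  }
})

test_that("tRF totals track copy number; unique pools need not", {
  # totals proportional to CN: perfect rank correlation
  df <- tibble::tibble(species = paste0("s", 1:6),
                       trna_cn = c(50, 100, 200, 400, 800, 1600),
                       total_trfs = trna_cn * 3,
                       unique_trfs = c(40, 45, 50, 42, 48, 44))
  res <- trf_census_correlation(df)
  expect_equal(res$spearman_rho[res$metric == "total_trfs"], 1)

  # independence: small correlation, p above 0.05 at n = 50
  set.seed(77)
  df2 <- tibble::tibble(species = paste0("s", 1:50),
                        trna_cn = exp(rnorm(50, 5, 1)),
                        total_trfs = trna_cn * runif(50, 2.5, 3.5),
                        unique_trfs = runif(50, 40, 60))
  res2 <- trf_census_correlation(df2)
  u <- res2[res2$metric == "unique_trfs", ]
  expect_lt(abs(u$spearman_rho), 0.3)
  expect_gt(u$p_value, 0.05)

  # constant totals: reported missing, not an error
  df3 <- df; df3$total_trfs <- 100
  expect_message(res3 <- trf_census_correlation(df3), "constant")
  expect_true(is.na(res3$spearman_rho[res3$metric == "total_trfs"]))

  expect_error(trf_census_correlation(df[1:2, ]), "3 species")
})

test_that("length spectra are computed on non-redundant sequences", {
  models <- demo_models()
  frag <- substr(models$mature_seq[1L], 1L, 22L)
  rec <- classify_fragments(setNames(c(frag, frag, frag), paste0("f", 1:3)),
                            models)
  sp <- length_spectrum(rec)
  expect_identical(nrow(sp), 1L)
  expect_identical(sp$length, 22L)
  expect_identical(sp$n, 1L)  # duplicates counted once
  expect_equal(attr(sp, "medians")$median_length, 22)

  for (seed in 1:5) {
    pool <- generate_trf_pool(models, n_distinct = 50L,
                              duplication_factor = 2, seed = seed)
    rec <- classify_fragments(setNames(pool$seq, pool$fragment_id), models)
    sp <- length_spectrum(rec)
    # brute-force tally over distinct (type, seq) pairs
    dd <- unique(data.frame(t = rec$trf_type, s = rec$seq,
                            l = rec$length)[!is.na(rec$trf_type) &
                                              rec$trf_type != "unclassified", ])
    ref <- as.data.frame(table(dd$t, dd$l), stringsAsFactors = FALSE)
    ref <- ref[ref$Freq > 0, ]
    for (k in seq_len(nrow(ref))) {
      expect_identical(
        sp$n[sp$trf_type == ref$Var1[k] & sp$length == as.integer(ref$Var2[k])],
        as.integer(ref$Freq[k]))
    }
    expect_true(all(sp$length >= 13L & sp$length <= 38L))
  }
})
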