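# In-code fixture builders: small locus tables and tRNAscan-SE text
# fixtures written at test time.

make_loci <- function(genome_id, isotype, anticodon,
                      n_introns = 0L, intron_length = 0L,
                      gene_length = 80L, score = 60,
                      note = "", seq_name = "chr1") {
  n <- max(length(isotype), length(anticodon))
  isotype <- rep_len(isotype, n)
  anticodon <- rep_len(anticodon, n)
  n_introns <- rep_len(as.integer(n_introns), n)
  intron_length <- ifelse(n_introns > 0L, rep_len(as.integer(intron_length), n), 0L)
  gene_length <- rep_len(as.integer(gene_length), n)
  begin <- cumsum(rep(1000L, n)) + seq_len(n)
  end <- begin + gene_length - 1L
  tibble::tibble(
    genome_id = genome_id, seq_name = rep_len(seq_name, n),
    trna_num = seq_len(n), begin = begin, end = end,
    strand = "+", isotype = isotype, anticodon = anticodon,
    introns = ifelse(n_introns > 0L,
                     paste0(begin + 30L, "-", begin + 30L + intron_length - 1L),
                     ""),
    n_introns = n_introns, intron_length = intron_length,
    score = rep_len(score, n), note = rep_len(note, n),
    is_pseudogene = is.na(anticodon) | grepl("pseudo", note),
    gene_length = gene_length,
    mature_length = gene_length - intron_length
  )
}

# random locus table: anticodons drawn from a pool, isotypes mostly
# standard with optional mismatches and pseudogenes
random_loci <- function(genome_id, n, seed, pool = NULL,
                        pseudo_rate = 0.1, mismatch_rate = 0) {
  set.seed(seed)
  if (is.null(pool)) pool <- sample(trnaome::enumerate_anticodons(), 30)
  ac <- sample(pool, n, replace = TRUE)
  iso <- trnaome::predict_isotype(ac)$predicted_isotype
  iso[iso == "STOP"] <- "Sup"
  mm <- runif(n) < mismatch_rate
  iso[mm] <- "Ala"
  pseudo <- runif(n) < pseudo_rate
  ac[pseudo] <- NA_character_
  iso[pseudo] <- "Undet"
  make_loci(genome_id, iso, ac,
            n_introns = rbinom(n, 1L, 0.2),
            intron_length = sample(10:20, n, replace = TRUE),
            gene_length = sample(70:90, n, replace = TRUE))
}

# a hand-written tRNAscan-SE fixture covering the dialect corners
write_trnascan_fixture <- function(path) {
  lines <- c(
    "Sequence\t\ttRNA\tBounds\ttRNA\tAnti\tIntron Bounds\tInf",
    "Name\ttRNA #\tBegin\tEnd\tType\tCodon\tBegin\tEnd\tScore\tNote",
    "--------\t------\t-----\t---\t----\t-----\t-----\t----\t-----\t----",
    "chr1\t1\t1000\t1084\tMet\tCAT\t0\t0\t75.5\t",
    "chr1\t2\t2084\t2000\tLeu\tTAA\t0\t0\t60.1\t",
    "chr1\t3\t3000\t3084\tUndet\tNNN\t0\t0\t30.2\tpseudo",
    "chr2\t1\t500\t584\tTyr\tGTA\t530\t542\t82.0\t",
    "chr2\t2\t9000\t9120\tSer\tAGA\t9040;9080\t9050;9092\t70.0\t"
  )
  writeLines(lines, path)
  path
}

metadata_fixture <- function() {
  tibble::tibble(
    genome_id = c("g1", "g2", "g3"),
    species = c("Alpha one", "Beta two", "Gamma three"),
    domain = c("Eukarya", "Bacteria", "Archaea"),
    group = c("Fungi", "Proteobacteria", "Euryarchaeota"),
    genome_size_mb = c(12.5, 4.2, 2.1),
    protein_coding_genes = c(6000L, 4100L, 2100L)
  )
}
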