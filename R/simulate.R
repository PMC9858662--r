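# Synthetic genome-annotation cohorts with the statistical structure
# the comparative analyses assume: domain-specific genome-size ranges,
# power-law CN-vs-size scaling, domain-skewed anticodon pervasiveness,
# domain-specific intron frequencies and gene-length distributions,
# pseudogene loci, and redundant tRF pools.

#' Default per-combination pervasiveness probabilities
#'
#' A deterministic synthetic profile assigning every sense
#' anticodon-isotype combination (plus iMet/CAT and Sup/TTA) an
#' inclusion probability per domain. Within each amino acid the
#' lexicographically first anticodon is near-universal in all domains,
#' later anticodons follow domain-skewed patterns (eukaryote+archaea,
#' prokaryote-only, eukaryote-only, rare everywhere, mixed), so the
#' full range of cross-domain universality classes is represented. The
#' probabilities are synthetic: the real per-combination frequencies
#' are database properties, not published parameters.
#'
#' @return Tibble with columns `isotype`, `anticodon`, `Eukarya`,
#'   `Archaea`, `Bacteria`.
#' @export
default_pervasiveness <- function() {
  code <- genetic_code_table()
  sense <- code[!code$is_stop, ]
  sense <- sense[order(sense$isotype, sense$anticodon), ]
  pat <- list(
    c(0.97, 0.97, 0.97),  # universal
    c(0.92, 0.90, 0.04),  # eukaryote + archaea
    c(0.05, 0.88, 0.90),  # prokaryote
    c(0.85, 0.05, 0.05),  # eukaryote only
    c(0.03, 0.03, 0.02),  # rare everywhere
    c(0.85, 0.10, 0.85)   # mixed (eukaryote + bacteria)
  )
  rows <- lapply(split(sense, sense$isotype), function(d) {
    k <- pmin(seq_len(nrow(d)), length(pat))
    m <- do.call(rbind, pat[k])
    tibble::tibble(isotype = d$isotype, anticodon = d$anticodon,
                   Eukarya = m[, 1L], Archaea = m[, 2L], Bacteria = m[, 3L])
  })
  extra <- tibble::tibble(
    isotype = c("iMet", "Sup"),
    anticodon = c("CAT", "TTA"),
    Eukarya = c(0.99, 0.02), Archaea = c(0.99, 0.00),
    Bacteria = c(0.99, 0.00)
  )
  out <- dplyr::bind_rows(c(rows, list(extra)))
  dplyr::arrange(out, .data$isotype, .data$anticodon)
}

#' Generator profile for one domain of life
#'
#' Bundles the sampling parameters the cohort generator uses for one
#' domain: genome-size range (sampled log-uniformly, Mb), power-law
#' copy-number scaling `CN = a * size_mb^b * lognormal(sdlog)`,
#' per-locus intron probability, gene-length and intron-length normal
#' distributions, pseudogene rate, a saturating protein-coding gene
#' model `P = cap * size / (k + size)`, and the per-combination
#' pervasiveness vector.
#'
#' Defaults: genome sizes span roughly 1-6 Mb (Archaea), 0.5-10 Mb
#' (Bacteria) and 10 Mb-100 Gb (Eukarya); intron probabilities are
#' 0.2230 (Eukarya), 0.1899 (Archaea) and 0.0011 (Bacteria); mean gene
#' lengths are 84.70, 83.10 and 77.60 bp respectively, bacteria being
#' the most uniform (sd 2.5 bp); the eukaryote protein-coding model
#' saturates at 35,000 genes.
#'
#' @param domain `"Eukarya"`, `"Archaea"` or `"Bacteria"`.
#' @return A list of class `domain_profile`.
#' @export
domain_profile <- function(domain = c("Eukarya", "Archaea", "Bacteria")) {
  domain <- match.arg(domain)
  base <- switch(domain,
    Eukarya = list(
      size_range_mb = c(10, 1e5),
      cn_scaling = list(a = 0.2, b = 1.0, sdlog = 0.5),
      intron_prob = 0.2230,
      gene_length = c(mean = 84.70, sd = 5),
      intron_length = c(mean = 18, sd = 4),
      pseudogene_rate = 0.05,
      protein_gene_model = list(cap = 35000, k = 500)
    ),
    Archaea = list(
      size_range_mb = c(1, 6),
      cn_scaling = list(a = 29, b = 0.5, sdlog = 0.05),
      intron_prob = 0.1899,
      gene_length = c(mean = 83.10, sd = 5),
      intron_length = c(mean = 30, sd = 8),
      pseudogene_rate = 0.01,
      protein_gene_model = list(cap = 6000, k = 4)
    ),
    Bacteria = list(
      size_range_mb = c(0.5, 10),
      cn_scaling = list(a = 37, b = 0.5, sdlog = 0.3),
      intron_prob = 0.0011,
      gene_length = c(mean = 77.60, sd = 2.5),
      intron_length = c(mean = 20, sd = 5),
      pseudogene_rate = 0.01,
      protein_gene_model = list(cap = 10000, k = 8)
    )
  )
  pv <- default_pervasiveness()
  base$domain <- domain
  base$pervasiveness <- stats::setNames(pv[[domain]],
                                        paste(pv$isotype, pv$anticodon, sep = "/"))
  base$combinations <- pv[, c("isotype", "anticodon")]
  structure(base, class = "domain_profile")
}

.GROUP_POOL <- list(
  Eukarya = c("vertebrates", "invertebrates", "Fungi", "land plants", "protists"),
  Archaea = c("Euryarchaeota", "Crenarchaeota", "Thaumarchaeota"),
  Bacteria = c("Proteobacteria", "Firmicutes", "Actinobacteria", "Bacteroidetes")
)

# independent per-genome RNG substream (kept below 2^31)
.genome_seed <- function(seed, idx) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(idx) * 16807) %% 2147483647)
}

.draw_loci <- function(profile, cn, included) {
  comb <- profile$combinations[included, , drop = FALSE]
  n_comb <- nrow(comb)
  # one guaranteed copy per included combination, remainder multinomial
  # with weights skewed toward high-pervasiveness combinations
  w <- profile$pervasiveness[included]^2 + 0.01
  extra <- cn - n_comb
  counts <- rep(1L, n_comb)
  if (extra > 0L) {
    counts <- counts + as.integer(stats::rmultinom(1L, extra, w / sum(w)))
  }
  isotype <- rep(comb$isotype, counts)
  anticodon <- rep(comb$anticodon, counts)
  n_fun <- length(isotype)
  n_pseudo <- stats::rbinom(1L, n_fun, profile$pseudogene_rate)
  n_tot <- n_fun + n_pseudo
  isotype <- c(isotype, rep("Undet", n_pseudo))
  anticodon <- c(anticodon, rep(NA_character_, n_pseudo))
  note <- c(rep("", n_fun), rep("pseudo", n_pseudo))
  ord <- sample.int(n_tot)
  isotype <- isotype[ord]; anticodon <- anticodon[ord]; note <- note[ord]

  gl <- profile$gene_length
  gene_length <- pmax(60L, as.integer(round(stats::rnorm(n_tot, gl["mean"], gl["sd"]))))
  has_intron <- stats::rbinom(n_tot, 1L, profile$intron_prob) == 1L
  il <- profile$intron_length
  ilen <- integer(n_tot)
  if (any(has_intron)) {
    raw <- as.integer(round(stats::rnorm(sum(has_intron), il["mean"], il["sd"])))
    ilen[has_intron] <- pmax(4L, pmin(raw, gene_length[has_intron] - 40L))
  }

  # non-overlapping placement on synthetic contigs, ~50 loci each
  contig <- paste0("chr", (seq_len(n_tot) - 1L) %/% 50L + 1L)
  gap <- sample(200:2000, n_tot, replace = TRUE)
  offset <- stats::ave(gene_length + gap, contig,
                       FUN = function(v) cumsum(c(0L, v[-length(v)])))
  begin <- as.integer(offset + gap)
  end <- begin + gene_length - 1L
  intron_begin <- ifelse(has_intron, begin + 37L, 0L)
  intron_end <- ifelse(has_intron, intron_begin + ilen - 1L, 0L)
  strand <- sample(c("+", "-"), n_tot, replace = TRUE)
  score <- round(ifelse(note == "pseudo", stats::runif(n_tot, 20, 40),
                        stats::runif(n_tot, 45, 110)), 1)

  tibble::tibble(
    seq_name = contig,
    trna_num = seq_len(n_tot),
    begin = begin, end = end, strand = strand,
    isotype = isotype, anticodon = anticodon,
    introns = ifelse(has_intron, paste0(intron_begin, "-", intron_end), ""),
    n_introns = as.integer(has_intron),
    intron_length = ilen,
    score = score, note = note,
    is_pseudogene = note == "pseudo",
    gene_length = gene_length,
    mature_length = gene_length - ilen
  )
}

#' Simulate the tRNA annotation of one genome
#'
#' Samples a genome size, draws the functional copy number from the
#' profile's power-law scaling model (floored at 20 loci and at one
#' copy per included combination, so no sampled combination is ever
#' silently dropped), selects the anticodon repertoire from the
#' per-combination pervasiveness probabilities, and emits a normalized
#' locus table with introns, pseudogenes and non-overlapping synthetic
#' coordinates.
#'
#' @param profile A [domain_profile()].
#' @param genome_id Genome identifier.
#' @param seed Integer seed for this genome's RNG stream.
#' @return List with elements `loci` (locus tibble), `metadata`
#'   (one-row metadata tibble) and `params` (sampled size/CN
#'   bookkeeping).
#' @export
simulate_genome <- function(profile, genome_id, seed) {
  set.seed(seed)
  sr <- profile$size_range_mb
  size_mb <- exp(stats::runif(1, log(sr[1L]), log(sr[2L])))
  sc <- profile$cn_scaling
  cn_target <- sc$a * size_mb^sc$b * stats::rlnorm(1, 0, sc$sdlog)
  included <- which(stats::rbinom(length(profile$pervasiveness), 1L,
                                  profile$pervasiveness) == 1L)
  if (!length(included)) {  # pathological all-zero draw: force one combination
    included <- which.max(profile$pervasiveness)
  }
  cn <- max(20L, length(included), as.integer(round(cn_target)))
  loci <- .draw_loci(profile, cn, included)
  loci <- dplyr::mutate(loci, genome_id = genome_id, .before = 1L)
  pg <- profile$protein_gene_model
  protein <- as.integer(round(pg$cap * size_mb / (pg$k + size_mb) *
                                stats::runif(1, 0.9, 1.1)))
  meta <- tibble::tibble(
    genome_id = genome_id,
    species = paste("Synthetic", tolower(profile$domain), genome_id),
    domain = profile$domain,
    group = sample(.GROUP_POOL[[profile$domain]], 1L),
    genome_size_mb = round(size_mb, 4),
    protein_coding_genes = protein
  )
  list(loci = loci, metadata = meta,
       params = tibble::tibble(genome_id = genome_id, seed = seed,
                               size_mb = size_mb, cn_target = cn_target,
                               cn = cn, n_combinations = length(included),
                               cn_floored = cn > round(cn_target)))
}

#' Generate a synthetic multi-domain cohort on disk
#'
#' Writes one tRNAscan-SE-format `.out` file per genome, a metadata
#' TSV (`metadata.tsv`) and a JSON manifest (`manifest.json`) recording
#' the master seed and every sampled per-genome parameter. Each genome
#' uses its own RNG stream derived from `(seed, genome index)`, so a
#' fixed seed reproduces the cohort byte for byte.
#'
#' @param out_dir Output directory (created if needed).
#' @param n_euk,n_arc,n_bac Genomes per domain.
#' @param seed Master integer seed.
#' @param profiles Named list of [domain_profile()]s to draw from.
#' @return Invisibly, a list with `metadata`, `manifest` (per-genome
#'   parameter tibble) and `out_dir`.
#' @export
generate_cohort <- function(out_dir, n_euk = 0L, n_arc = 0L, n_bac = 0L,
                            seed = 1L,
                            profiles = list(Eukarya = domain_profile("Eukarya"),
                                            Archaea = domain_profile("Archaea"),
                                            Bacteria = domain_profile("Bacteria"))) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  plan <- tibble::tibble(
    domain = rep(c("Eukarya", "Archaea", "Bacteria"), c(n_euk, n_arc, n_bac)),
    idx = seq_len(n_euk + n_arc + n_bac)
  )
  prefix <- c(Eukarya = "EUK", Archaea = "ARC", Bacteria = "BAC")
  plan$genome_id <- sprintf("%s%04d", prefix[plan$domain],
                            as.integer(stats::ave(plan$idx, plan$domain,
                                                  FUN = seq_along)))
  metas <- vector("list", nrow(plan))
  params <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    g <- simulate_genome(profiles[[plan$domain[i]]], plan$genome_id[i],
                         .genome_seed(seed, plan$idx[i]))
    write_trnascan(g$loci, file.path(out_dir, paste0(plan$genome_id[i], ".out")))
    metas[[i]] <- g$metadata
    params[[i]] <- g$params
  }
  metadata <- dplyr::bind_rows(metas)
  manifest <- dplyr::bind_rows(params)
  write_metadata(metadata, file.path(out_dir, "metadata.tsv"))
  jsonlite::write_json(
    list(seed = seed, n_euk = n_euk, n_arc = n_arc, n_bac = n_bac,
         genomes = manifest),
    file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = 10
  )
  invisible(list(metadata = metadata, manifest = manifest, out_dir = out_dir))
}

#' Generate strains of one species with intraspecific CNV
#'
#' Simulates a base genome, then jitters its total copy number across
#' `n_strains` strains (`CN_s = round(base_cn * lognormal(cnv_sd))`);
#' all strains share the base genome's anticodon repertoire and species
#' label. With probability `repertoire_loss_prob` a strain loses all
#' copies of one random anticodon; `force_loss_strain` deterministically
#' drops one anticodon from the given strain indices instead.
#'
#' @param out_dir Output directory, or `NULL` to skip writing files.
#' @param domain Domain profile to base the species on.
#' @param n_strains Number of strains (>= 2).
#' @param cnv_sd Lognormal sd of the per-strain CN jitter.
#' @param repertoire_loss_prob Per-strain probability of losing one
#'   anticodon.
#' @param force_loss_strain Integer indices of strains forced to lose
#'   one anticodon (overrides the random rule for those strains).
#' @param species Species label shared by all strains.
#' @param seed Master seed.
#' @return List with `loci` (all strains), `metadata`, and `out_dir`.
#' @export
generate_species_cohort <- function(out_dir = NULL, domain = "Eukarya",
                                    n_strains = 5L, cnv_sd = 0.1,
                                    repertoire_loss_prob = 0,
                                    force_loss_strain = integer(),
                                    species = "Synthetic species",
                                    seed = 1L) {
  stopifnot(n_strains >= 2L)
  profile <- domain_profile(domain)
  set.seed(.genome_seed(seed, 0L))
  sr <- profile$size_range_mb
  size_mb <- exp(stats::runif(1, log(sr[1L]), log(sr[2L])))
  sc <- profile$cn_scaling
  included <- which(stats::rbinom(length(profile$pervasiveness), 1L,
                                  profile$pervasiveness) == 1L)
  base_cn <- max(20L, length(included),
                 as.integer(round(sc$a * size_mb^sc$b)))
  pg <- profile$protein_gene_model
  protein <- as.integer(round(pg$cap * size_mb / (pg$k + size_mb)))

  loci_all <- vector("list", n_strains)
  metas <- vector("list", n_strains)
  for (s in seq_len(n_strains)) {
    set.seed(.genome_seed(seed, s))
    gid <- sprintf("STR%03d", s)
    cn_s <- max(20L, as.integer(round(base_cn * stats::rlnorm(1, 0, cnv_sd))))
    incl_s <- included
    lose <- s %in% force_loss_strain ||
      (repertoire_loss_prob > 0 && stats::runif(1) < repertoire_loss_prob)
    if (lose && length(incl_s) > 1L) {
      incl_s <- incl_s[-sample.int(length(incl_s), 1L)]
    }
    cn_s <- max(cn_s, length(incl_s))
    loci <- .draw_loci(profile, cn_s, incl_s)
    loci <- dplyr::mutate(loci, genome_id = gid, .before = 1L)
    loci_all[[s]] <- loci
    metas[[s]] <- tibble::tibble(
      genome_id = gid, species = species, domain = profile$domain,
      group = .GROUP_POOL[[profile$domain]][1L],
      genome_size_mb = round(size_mb, 4), protein_coding_genes = protein
    )
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write_trnascan(loci, file.path(out_dir, paste0(gid, ".out")))
    }
  }
  metadata <- dplyr::bind_rows(metas)
  if (!is.null(out_dir)) {
    write_metadata(metadata, file.path(out_dir, "metadata.tsv"))
  }
  list(loci = dplyr::bind_rows(loci_all), metadata = metadata,
       out_dir = out_dir)
}

.random_seq <- function(n_seqs, len) {
  vapply(len, function(l) {
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
  }, character(1))
}

#' Generate random mature-tRNA models with trailers
#'
#' Random-sequence stand-ins for mature tRNAs (optionally
#' CCA-terminated) plus 3' trailer sequences; sequence content is
#' synthetic (no cloverleaf structure), only the lengths are realistic.
#'
#' @param n Number of models.
#' @param seed Integer seed.
#' @param mature_len_range,trailer_len_range Length ranges (nt).
#' @param cca_terminated Append CCA to the mature sequences?
#' @return Model tibble (`trna_id`, `mature_seq`, `trailer_seq`).
#' @export
generate_trna_models <- function(n, seed = 1L,
                                 mature_len_range = c(70L, 90L),
                                 trailer_len_range = c(20L, 50L),
                                 cca_terminated = FALSE) {
  set.seed(seed)
  ml <- sample(mature_len_range[1L]:mature_len_range[2L], n, replace = TRUE)
  tl <- sample(trailer_len_range[1L]:trailer_len_range[2L], n, replace = TRUE)
  mature <- .random_seq(n, ml)
  if (cca_terminated) mature <- paste0(mature, "CCA")
  tibble::tibble(
    trna_id = sprintf("tRNA%03d", seq_len(n)),
    mature_seq = mature,
    trailer_seq = .random_seq(n, tl)
  )
}

#' Generate a redundant tRF pool with ground-truth labels
#'
#' Cuts fragments from the 5' ends, 3' ends and trailers of the given
#' models with lengths uniform on `len_range`, then replicates each
#' distinct fragment a geometric number of times (mean
#' `duplication_factor`) to emulate a redundant sequencing-derived
#' pool. Truth labels record the cut type and source model.
#'
#' @param models Model tibble.
#' @param n_distinct Number of distinct fragments to cut.
#' @param type_weights Sampling weights for `c(tRF-5, tRF-3, tRF-1)`.
#' @param len_range Fragment length range, default 13-38 nt.
#' @param duplication_factor Mean copies per distinct fragment (1 =
#'   fully non-redundant pool).
#' @param seed Integer seed.
#' @param out_fasta,out_truth Optional paths: fragment FASTA and truth
#'   TSV sidecar.
#' @return Tibble with one row per fragment copy: `fragment_id`, `seq`,
#'   `true_type`, `source_id`.
#' @export
generate_trf_pool <- function(models, n_distinct = 100L,
                              type_weights = c(0.4, 0.4, 0.2),
                              len_range = c(13L, 38L),
                              duplication_factor = 1,
                              seed = 1L,
                              out_fasta = NULL, out_truth = NULL) {
  set.seed(seed)
  models <- validate_models(models)
  types <- sample(c("tRF-5", "tRF-3", "tRF-1"), n_distinct, replace = TRUE,
                  prob = type_weights)
  src <- sample.int(nrow(models), n_distinct, replace = TRUE)
  len <- sample(len_range[1L]:len_range[2L], n_distinct, replace = TRUE)
  seqs <- character(n_distinct)
  for (i in seq_len(n_distinct)) {
    m <- models$mature_seq[src[i]]
    tr <- models$trailer_seq[src[i]]
    l <- switch(types[i],
                `tRF-5` = ,
                `tRF-3` = min(len[i], nchar(m)),
                `tRF-1` = min(len[i], nchar(tr)))
    seqs[i] <- switch(types[i],
                      `tRF-5` = substr(m, 1L, l),
                      `tRF-3` = substr(m, nchar(m) - l + 1L, nchar(m)),
                      `tRF-1` = substr(tr, 1L, l))
  }
  copies <- if (duplication_factor > 1) {
    1L + stats::rgeom(n_distinct, 1 / duplication_factor)
  } else {
    rep(1L, n_distinct)
  }
  pool <- tibble::tibble(
    seq = rep(seqs, copies),
    true_type = rep(types, copies),
    source_id = rep(models$trna_id[src], copies)
  )
  pool <- pool[sample.int(nrow(pool)), ]
  pool$fragment_id <- sprintf("trf%05d", seq_len(nrow(pool)))
  pool <- pool[, c("fragment_id", "seq", "true_type", "source_id")]
  if (!is.null(out_fasta)) {
    write_fasta(tibble::tibble(id = pool$fragment_id, seq = pool$seq), out_fasta)
  }
  if (!is.null(out_truth)) {
    utils::write.table(pool, out_truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  pool
}
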