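# Independent brute-force oracles: plain loops and closed forms, no
# shared code with the package internals they check.

# per-genome recount of a locus table
oracle_census_tally <- function(loci_one_genome) {
  d <- loci_one_genome
  fun_rows <- which(!d$is_pseudogene)
  ac <- d$anticodon[fun_rows]
  list(
    total_trna = length(fun_rows),
    pseudogene_count = nrow(d) - length(fun_rows),
    repertoire_size = length(unique(ac)),
    intron_locus_count = sum(d$n_introns >= 1),
    anticodon_counts = {
      out <- integer(0)
      for (a in sort(unique(ac))) out[a] <- sum(ac == a)
      out
    }
  )
}

# per-combination, per-domain presence fraction and mean copy number
oracle_pervasiveness <- function(censuses, metadata) {
  dom <- setNames(metadata$domain, metadata$genome_id)
  combos <- list()
  for (i in seq_len(nrow(censuses))) {
    cb <- censuses$combinations[[i]]
    for (j in seq_len(nrow(cb))) {
      combos[[paste(cb$isotype[j], cb$anticodon[j], sep = "/")]] <- TRUE
    }
  }
  out <- list()
  for (key in sort(names(combos))) {
    parts <- strsplit(key, "/", fixed = TRUE)[[1]]
    for (d in unique(metadata$domain)) {
      gids <- censuses$genome_id[dom[censuses$genome_id] == d]
      n_present <- 0L; total_cn <- 0L
      for (g in gids) {
        cb <- censuses$combinations[[which(censuses$genome_id == g)]]
        hit <- cb$isotype == parts[1] & cb$anticodon == parts[2]
        if (any(hit)) {
          n_present <- n_present + 1L
          total_cn <- total_cn + sum(cb$n[hit])
        }
      }
      out[[length(out) + 1L]] <- data.frame(
        isotype = parts[1], anticodon = parts[2], domain = d,
        pervasiveness = n_present / length(gids),
        mean_cn = total_cn / length(gids),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

# independently coded Greek-group rule evaluator
oracle_group_label <- function(euk, arc, bac, high = 0.70, low = 0.30) {
  if (euk > high && arc > high && bac > high) return("alpha")
  if (euk > high && arc > high && bac <= low) return("beta")
  if (arc > high && bac > high && euk <= low) return("gamma")
  if (euk > high && arc <= low && bac <= low) return("delta")
  if (euk <= low && arc <= low && bac <= low) return("epsilon")
  "other"
}

# brute-force set algebra over three sets
oracle_venn <- function(E, A, B) {
  u <- union(union(E, A), B)
  counts <- c("Eukarya" = 0L, "Archaea" = 0L, "Bacteria" = 0L,
              "Eukarya+Archaea" = 0L, "Eukarya+Bacteria" = 0L,
              "Archaea+Bacteria" = 0L, "Eukarya+Archaea+Bacteria" = 0L)
  for (x in u) {
    inE <- x %in% E; inA <- x %in% A; inB <- x %in% B
    key <- if (inE && inA && inB) "Eukarya+Archaea+Bacteria"
      else if (inE && inA) "Eukarya+Archaea"
      else if (inE && inB) "Eukarya+Bacteria"
      else if (inA && inB) "Archaea+Bacteria"
      else if (inE) "Eukarya" else if (inA) "Archaea" else "Bacteria"
    counts[key] <- counts[key] + 1L
  }
  counts
}

# per-species CNV summary by explicit looping
oracle_species_cnv <- function(cn_by_species, rep_by_species) {
  out <- list()
  for (sp in names(cn_by_species)) {
    cn <- cn_by_species[[sp]]; rp <- rep_by_species[[sp]]
    out[[sp]] <- list(
      cn_min = min(cn), cn_max = max(cn), cn_mean = mean(cn),
      fold_range = if (min(cn) > 0) max(cn) / min(cn) else NA_real_,
      repertoire_varies = min(rp) < max(rp)
    )
  }
  out
}

# set-based redundancy recount
oracle_redundancy <- function(seqs) {
  seen <- character(0)
  uniq <- 0L
  for (s in seqs) {
    if (!(s %in% seen)) { seen <- c(seen, s); uniq <- uniq + 1L }
  }
  list(total = length(seqs), unique = uniq,
       unique_fraction = uniq / length(seqs))
}

# Welch t-test closed form with Satterthwaite degrees of freedom
oracle_welch <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1)
  vy <- sum((y - mean(y))^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# Mann-Whitney U by direct pair counting (midrank convention for ties)
oracle_u_stat <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) {
    u <- u + (xi > yj) + 0.5 * (xi == yj)
  }
  u
}

# exact two-sided p by full enumeration of group assignments
oracle_u_exact_p <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  idx <- utils::combn(length(pooled), nx)
  us <- apply(idx, 2, function(ii) {
    oracle_u_stat(pooled[ii], pooled[-ii])
  })
  u_obs <- oracle_u_stat(x, y)
  pl <- mean(us <= u_obs + 1e-9)
  pu <- mean(us >= u_obs - 1e-9)
  min(1, 2 * min(pl, pu))
}

# large-sample normal approximation with tie correction and
# continuity correction
oracle_u_approx_p <- function(x, y) {
  nx <- length(x); ny <- length(y); N <- nx + ny
  u <- oracle_u_stat(x, y)
  ties <- table(c(x, y))
  sigma2 <- (nx * ny / 12) * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  z <- u - nx * ny / 2
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  min(1, 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE)))
}
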