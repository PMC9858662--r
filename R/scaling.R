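.SCALING_VARS <- c("genome_size_mb", "total_trna", "protein_coding_genes",
                   "repertoire_size", "pseudogene_count")

.scaling_pair <- function(d, xv, yv, domain_label) {
  x <- d[[xv]]; y <- d[[yv]]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) {
    warning(sprintf("scaling pair %s ~ %s in %s skipped: %d point(s)",
                    yv, xv, domain_label, n), call. = FALSE)
    return(NULL)
  }
  # Spearman; a constant margin has no defined rank correlation and is
  # reported as 0 (ties handled), p missing
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    rho <- 0; rho_p <- NA_real_
  } else {
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    rho <- unname(ct$estimate); rho_p <- ct$p.value
  }
  # log10-log10 OLS on strictly positive values
  pos <- x > 0 & y > 0
  if (sum(pos) >= 3L) {
    fit <- stats::lm(log10(y[pos]) ~ log10(x[pos]))
    slope <- unname(stats::coef(fit)[2L])
    intercept <- unname(stats::coef(fit)[1L])
    r2 <- suppressWarnings(summary(fit)$r.squared)
    n_log <- sum(pos)
  } else {
    slope <- NA_real_; intercept <- NA_real_; r2 <- NA_real_
    n_log <- sum(pos)
  }
  tibble::tibble(domain = domain_label, x = xv, y = yv, n = n,
                 spearman_rho = rho, spearman_p = rho_p,
                 n_log = n_log, slope = slope, intercept = intercept,
                 r_squared = r2)
}

#' Genome-size scaling of tRNA gene content
#'
#' Spearman rank correlations and log10-log10 least-squares slopes for
#' every pair among genome size, functional tRNA copy number,
#' protein-coding gene count, anticodon repertoire size and pseudogene
#' count, computed overall and (optionally) per domain. Log-log fits
#' use strictly positive values only; pairs with fewer than 3 points
#' are skipped with a warning. A constant margin yields Spearman rho 0
#' with a missing p-value; the log-log slope of a constant response is
#' exactly 0.
#'
#' @param censuses Filtered census tibble.
#' @param metadata Metadata tibble.
#' @param vars Variables to correlate pairwise (default all five).
#' @param by_domain Also compute per-domain rows?
#' @return Tibble of class `trna_scaling`: one row per (domain, x, y).
#' @export
scaling_analysis <- function(censuses, metadata, vars = .SCALING_VARS,
                             by_domain = TRUE) {
  joined <- join_metadata(censuses, metadata)
  pairs <- utils::combn(vars, 2L, simplify = FALSE)
  strata <- list(all = joined)
  if (by_domain) {
    for (d in unique(joined$domain)) {
      strata[[d]] <- joined[joined$domain == d, , drop = FALSE]
    }
  }
  rows <- list()
  for (lab in names(strata)) {
    for (p in pairs) {
      rows[[length(rows) + 1L]] <- .scaling_pair(strata[[lab]], p[1L], p[2L], lab)
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("trna_scaling", class(out))
  out
}
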