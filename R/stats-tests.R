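#' Two-group comparison: Welch t and Mann-Whitney U
#'
#' Runs both tests the comparative analyses use for contrasting two
#' sets of genomes: Welch's two-sample t-test (unequal variances,
#' Satterthwaite degrees of freedom) and the Wilcoxon-Mann-Whitney U
#' test. The U test uses exact enumeration when both samples have at
#' most 20 observations and no ties, and the normal approximation with
#' tie and continuity correction otherwise. Two-sided p-values
#' throughout; the conventional significance threshold is 0.05.
#'
#' @param x,y Numeric samples; Welch requires n >= 2 per sample and at
#'   least one sample with non-zero variance.
#' @param exact_max Largest per-sample size for exact U enumeration
#'   (default 20).
#' @return An object of class `trna_group_comparison`; use
#'   [generics::tidy()] for a per-test tibble and [generics::glance()]
#'   for a one-row summary.
#' @export
#' @examples
#' cmp <- compare_groups(rnorm(10), rnorm(10, 1))
#' tidy(cmp)
compare_groups <- function(x, y, exact_max = 20L) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2L || length(y) < 2L) {
    stop("Welch t-test needs at least 2 observations per sample", call. = FALSE)
  }
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    stop("both samples have zero variance: Welch t statistic undefined",
         call. = FALSE)
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  has_ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- length(x) <= exact_max && length(y) <= exact_max && !has_ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = use_exact,
                                            correct = TRUE))
  structure(
    list(
      welch = list(statistic = unname(tt$statistic), df = unname(tt$parameter),
                   p_value = tt$p.value),
      mann_whitney = list(U = unname(wt$statistic), p_value = wt$p.value,
                          exact = use_exact),
      n_x = length(x), n_y = length(y),
      mean_x = mean(x), mean_y = mean(y)
    ),
    class = "trna_group_comparison"
  )
}

#' @export
print.trna_group_comparison <- function(x, ...) {
  cat(sprintf("Two-group comparison (n = %d vs %d)\n", x$n_x, x$n_y))
  cat(sprintf("  Welch t = %.4g, df = %.2f, p = %.4g\n",
              x$welch$statistic, x$welch$df, x$welch$p_value))
  cat(sprintf("  Mann-Whitney U = %g, p = %.4g (%s)\n",
              x$mann_whitney$U, x$mann_whitney$p_value,
              if (x$mann_whitney$exact) "exact" else "normal approximation"))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a two-group comparison
#'
#' @param x A `trna_group_comparison` object.
#' @param ... Unused.
#' @return Tibble with one row per test: `method`, `statistic`, `df`,
#'   `p_value`.
#' @method tidy trna_group_comparison
#' @export
tidy.trna_group_comparison <- function(x, ...) {
  tibble::tibble(
    method = c("welch_t", "mann_whitney_u"),
    statistic = c(x$welch$statistic, x$mann_whitney$U),
    df = c(x$welch$df, NA_real_),
    p_value = c(x$welch$p_value, x$mann_whitney$p_value)
  )
}

#' One-row summary of a two-group comparison
#'
#' @param x A `trna_group_comparison` object.
#' @param ... Unused.
#' @return One-row tibble with sample sizes, means, and both test
#'   results.
#' @method glance trna_group_comparison
#' @export
glance.trna_group_comparison <- function(x, ...) {
  tibble::tibble(
    n_x = x$n_x, n_y = x$n_y, mean_x = x$mean_x, mean_y = x$mean_y,
    welch_t = x$welch$statistic, welch_df = x$welch$df,
    welch_p = x$welch$p_value,
    mw_u = x$mann_whitney$U, mw_p = x$mann_whitney$p_value
  )
}
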