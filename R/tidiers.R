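#' Tidy a cohort result
#'
#' One row per evaluated region: the across-cell CF summary joined with the
#' comparison against the reference region (the reference row has `NA`
#' comparison columns).
#'
#' @param x a [run_cohort()] result.
#' @param ... unused.
#' @return A tibble with columns `region`, `mean_cf`, `sem`, `n`,
#'   `n_excluded`, `p_value`, `p_adj`, `reject`.
#' @method tidy cohort_result
#' @export
tidy.cohort_result <- function(x, ...) {
  cmp <- x$anova$comparisons[, c("region", "p_value", "p_adj", "reject")]
  dplyr::left_join(x$summary, cmp, by = "region")
}

#' Glance at a cohort result
#'
#' @inheritParams tidy.cohort_result
#' @return A one-row tibble: `n_cells`, `n_regions`, `statistic` and
#'   `p_value` (omnibus ANOVA), `reference`, `scaffold`,
#'   `scaffold_significant`, `convention`.
#' @method glance cohort_result
#' @export
glance.cohort_result <- function(x, ...) {
  tibble(n_cells = x$n_cells,
         n_regions = nrow(x$summary),
         statistic = x$anova$anova$statistic,
         p_value = x$anova$anova$p_value,
         reference = x$reference,
         scaffold = if (!is.null(x$scaffold)) x$scaffold$scaffold
                    else NA_character_,
         scaffold_significant = if (!is.null(x$scaffold))
           x$scaffold$significant else NA,
         convention = x$convention)
}

#' Tidy a region ANOVA
#'
#' @param x a [anova_vs_reference()] result.
#' @param ... unused.
#' @return The comparisons tibble (one row per non-reference region).
#' @method tidy cf_anova
#' @export
tidy.cf_anova <- function(x, ...) x$comparisons

#' @rdname tidy.cf_anova
#' @method glance cf_anova
#' @export
glance.cf_anova <- function(x, ...) x$anova
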