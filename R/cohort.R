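check_cf_records <- function(cf_records) {
  need <- c("cell_id", "region", "cf", "defined")
  missing <- setdiff(need, names(cf_records))
  if (length(missing) > 0)
    abort(sprintf("CF records lack column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "venncf_parameter_error")
  cells <- unique(cf_records$cell_id)
  if (length(cells) < 2)
    abort("need >= 2 cells (the SEM over cells is undefined otherwise)",
          class = "venncf_parameter_error")
  base <- sort(unique(cf_records$region[cf_records$cell_id == cells[1]]))
  for (cid in cells[-1]) {
    regs <- sort(unique(cf_records$region[cf_records$cell_id == cid]))
    if (!identical(regs, base)) {
      diffset <- c(setdiff(base, regs), setdiff(regs, base))
      abort(sprintf("region sets differ across cells (cell '%s'): %s",
                    cid, paste(diffset, collapse = "; ")),
            class = "venncf_parameter_error")
    }
  }
  invisible(cf_records)
}

#' Aggregate per-cell CF records across a cohort
#'
#' Cells are the biological replicate unit. Undefined CFs (0/0 regions,
#' flagged `defined = FALSE`) are excluded from the statistics and counted in
#' `n_excluded`.
#'
#' @param cf_records a tibble of CF records (rows of
#'   [colocalization_factor()] / [cf_table()] over >= 2 cells with matching
#'   region sets).
#' @return A tibble with one row per region: `region`, `mean_cf`, `sem`
#'   (standard error of the mean over cells), `n` (cells with a defined CF),
#'   `n_excluded`.
#' @examples
#' recs <- tibble::tibble(
#'   cell_id = rep(as.character(1:5), each = 1),
#'   region = "A & B & C", cf = c(5, 6, 7, 8, 9), defined = TRUE)
#' aggregate_cells(recs)  # mean 7, SEM ~ 0.707
#' @export
aggregate_cells <- function(cf_records) {
  check_cf_records(cf_records)
  cf_records |>
    group_by(.data$region) |>
    summarise(
      mean_cf = mean(.data$cf[.data$defined]),
      sem = sd(.data$cf[.data$defined]) / sqrt(sum(.data$defined)),
      n = sum(.data$defined),
      n_excluded = sum(!.data$defined),
      .groups = "drop")
}

# Welch two-sample t-test that tolerates constant groups: when both groups
# are constant the test is degenerate and we report p = 0 (means differ) or
# p = 1 (means equal) with an infinite/zero statistic.
welch_p <- function(x, y) {
  if (sd(x) == 0 && sd(y) == 0) {
    if (mean(x) == mean(y))
      return(list(statistic = 0, df = NA_real_, p = 1))
    return(list(statistic = Inf, df = NA_real_, p = 0))
  }
  tt <- t.test(x, y)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' One-way ANOVA of region CFs against a reference region
#'
#' Across-region one-way ANOVA with cells as replicates, plus pairwise
#' Welch-type comparisons of each non-reference region against the reference
#' with Holm familywise correction ("one-way ANOVA against" the reference).
#' Undefined CFs are dropped. With zero residual variance but differing group
#' means the F statistic is infinite and p is reported as 0; if every CF in
#' every group is identical the data are degenerate and an error is raised.
#'
#' @inheritParams aggregate_cells
#' @param reference the reference region: a [region_spec()] or its label.
#' @param regions optional character vector of region labels to include
#'   (default: all regions present).
#' @param alpha familywise significance level for the `reject` flag.
#' @return An object of class `cf_anova`: list with `anova` (one-row tibble:
#'   `statistic`, `df_between`, `df_within`, `p_value`, `method`),
#'   `comparisons` (tibble per non-reference region: `region`, `reference`,
#'   `mean_diff`, `statistic`, `df`, `p_value`, `p_adj`, `reject`),
#'   `reference`, `alpha`, and the correction method used.
#' @export
anova_vs_reference <- function(cf_records, reference, regions = NULL,
                               alpha = 0.05) {
  check_cf_records(cf_records)
  ref_label <- if (inherits(reference, "region_spec")) format(reference)
               else as.character(reference)
  d <- cf_records[cf_records$defined & is.finite(cf_records$cf), ]
  if (!is.null(regions)) d <- d[d$region %in% regions, ]
  if (!ref_label %in% d$region)
    abort(sprintf("reference region '%s' not among the evaluated regions (%s)",
                  ref_label, paste(unique(d$region), collapse = "; ")),
          class = "venncf_parameter_error")
  if (var(d$cf) == 0)
    abort("degenerate data: every CF is identical; ANOVA is undefined",
          class = "venncf_degenerate_data")

  groups <- split(d$cf, d$region)
  k <- length(groups)
  ns <- lengths(groups)
  grand <- mean(d$cf)
  ss_b <- sum(ns * (vapply(groups, mean, 0) - grand)^2)
  ss_w <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  df_b <- k - 1
  df_w <- sum(ns) - k
  if (ss_w == 0) {
    f_stat <- Inf
    p_val <- 0
  } else {
    f_stat <- (ss_b / df_b) / (ss_w / df_w)
    p_val <- pf(f_stat, df_b, df_w, lower.tail = FALSE)
  }

  others <- setdiff(names(groups), ref_label)
  cmp <- lapply(others, function(rg) {
    w <- welch_p(groups[[rg]], groups[[ref_label]])
    tibble(region = rg, reference = ref_label,
           mean_diff = mean(groups[[rg]]) - mean(groups[[ref_label]]),
           statistic = w$statistic, df = w$df, p_value = w$p)
  })
  cmp <- bind_rows(cmp)
  cmp$p_adj <- p.adjust(cmp$p_value, method = "holm")
  cmp$reject <- cmp$p_adj < alpha

  structure(list(
    anova = tibble(statistic = f_stat, df_between = df_b, df_within = df_w,
                   p_value = p_val, method = "one-way ANOVA"),
    comparisons = cmp,
    reference = ref_label,
    alpha = alpha,
    comparison_method = "Welch t-test, Holm familywise correction"
  ), class = "cf_anova")
}

#' @export
print.cf_anova <- function(x, ...) {
  a <- x$anova
  cat(sprintf("One-way ANOVA across regions: F(%d, %d) = %.4g, p = %.4g\n",
              a$df_between, a$df_within, a$statistic, a$p_value))
  cat(sprintf("Comparisons vs '%s' (%s, alpha = %g):\n", x$reference,
              x$comparison_method, x$alpha))
  print(as.data.frame(x$comparisons))
  invisible(x)
}

pair_regions_3ch <- function(cf_records) {
  d <- unique(cf_records[, c("region", "include", "exclude")])
  inc_n <- lengths(strsplit(d$include, ","))
  exc_n <- ifelse(nzchar(d$exclude), lengths(strsplit(d$exclude, ",")), 0L)
  pairs <- d[inc_n == 2 & exc_n == 1, ]
  if (nrow(pairs) != 3)
    abort(paste("scaffold inference needs exactly the three exclusive-pair",
                "regions of a 3-channel analysis; found",
                nrow(pairs)), class = "venncf_parameter_error")
  pairs
}

#' Infer the scaffold channel from exclusive-pair CFs
#'
#' In a three-protein system the scaffold is the protein that bridges the
#' other two: both exclusive-pair regions containing it are CF-enriched while
#' the pair region excluding it is not. The candidate scaffold is therefore
#' the channel excluded from the pair region with the minimum mean CF; the
#' call is significant only if both other pair regions reject against that
#' minimum region (Welch t-tests, Holm correction over the two comparisons)
#' at `alpha`. Without joint significance, or when the minimum is tied,
#' `scaffold` is `NA` and the CF ordering is still reported.
#'
#' @inheritParams aggregate_cells
#' @param alpha significance level for the two comparisons.
#' @param tie_tol relative tolerance below which the two smallest mean CFs
#'   count as tied (no call is made on a tie).
#' @return An object of class `scaffold_call`: list with `scaffold` (channel
#'   name or `NA`), `candidate`, `significant`, `tie`, `ordering` (tibble:
#'   `region`, `excluded_channel`, `mean_cf`, sorted decreasing),
#'   `comparisons` (the two tests vs the minimum region), `alpha`.
#' @export
call_scaffold <- function(cf_records, alpha = 0.05, tie_tol = 1e-9) {
  check_cf_records(cf_records)
  pairs <- pair_regions_3ch(cf_records)
  d <- cf_records[cf_records$region %in% pairs$region &
                    cf_records$defined & is.finite(cf_records$cf), ]
  means <- vapply(split(d$cf, d$region), mean, 0)
  means <- means[pairs$region]
  ord <- order(means, decreasing = TRUE)
  ordering <- tibble(region = pairs$region[ord],
                     excluded_channel = pairs$exclude[ord],
                     mean_cf = unname(means[ord]))

  lo <- sort(means)
  tie <- (lo[2] - lo[1]) <= tie_tol * max(abs(lo[1]), abs(lo[2]), 1e-300)
  min_region <- pairs$region[which.min(means)]
  candidate <- pairs$exclude[pairs$region == min_region]

  cmp <- NULL
  significant <- FALSE
  if (!tie) {
    av <- anova_vs_reference(cf_records, reference = min_region,
                             regions = pairs$region, alpha = alpha)
    cmp <- av$comparisons
    significant <- all(cmp$reject)
  }
  structure(list(
    scaffold = if (!tie && significant) candidate else NA_character_,
    candidate = if (!tie) candidate else NA_character_,
    significant = significant,
    tie = tie,
    ordering = ordering,
    comparisons = cmp,
    alpha = alpha
  ), class = "scaffold_call")
}

#' @export
print.scaffold_call <- function(x, ...) {
  if (x$tie) {
    cat("Scaffold call: none (minimum pair-region CFs tied)\n")
  } else if (is.na(x$scaffold)) {
    cat(sprintf(
      "Scaffold call: none (candidate %s not significant at alpha = %g)\n",
      x$candidate, x$alpha))
  } else {
    cat(sprintf("Scaffold call: %s (both pair regions containing it exceed",
                x$scaffold),
        sprintf("the %s region at alpha = %g)\n",
                x$ordering$region[3], x$alpha))
  }
  print(as.data.frame(x$ordering))
  invisible(x)
}
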