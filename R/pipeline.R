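#' Configuration for an end-to-end colocalization run
#'
#' Bundles either image inputs (per-cell TIFF paths, channel names, optional
#' ROI paths) or a simulation (`sim_config` + `n_cells`), with the threshold
#' method, expectation convention, regions, reference region and alpha.
#' Exactly one of the two input modes must be present, and the reference
#' region must be among the evaluated regions.
#'
#' @param simulation a [sim_config()], or `NULL` when analysing images.
#' @param n_cells number of cells to simulate (simulation mode).
#' @param images list of per-cell inputs, each `list(path =, roi = NULL,
#'   cell_id = NULL)` (image mode).
#' @param channel_names channel names for image mode (page order).
#' @param threshold_method,threshold_params passed to [binarize()].
#' @param convention expectation convention, see [expected_fraction()].
#' @param regions list of [region_spec()]s; `NULL` = [default_regions()].
#' @param reference reference region for the ANOVA ([region_spec()] or
#'   label); `NULL` = the exclusive-pair region excluding the last channel
#'   (for channels ACC1, COP1, KIF12: "ACC1 & COP1 w/o KIF12").
#' @param alpha significance level.
#' @param out_dir directory for CSV/JSON outputs, or `NULL` to skip writing.
#' @param seed cohort seed (simulation mode).
#' @return An object of class `run_config`.
#' @export
run_config <- function(simulation = NULL, n_cells = NULL, images = NULL,
                       channel_names = NULL,
                       threshold_method = "otsu", threshold_params = NULL,
                       convention = c("exclusion_aware", "paper_literal"),
                       regions = NULL, reference = NULL, alpha = 0.05,
                       out_dir = NULL, seed = 1L) {
  convention <- arg_match(convention)
  sim_mode <- !is.null(simulation)
  img_mode <- !is.null(images)
  if (sim_mode == img_mode)
    abort("exactly one of `simulation` or `images` must be given",
          class = "venncf_parameter_error")
  if (sim_mode) {
    stopifnot(inherits(simulation, "sim_config"))
    if (is.null(n_cells))
      abort("simulation mode requires `n_cells`",
            class = "venncf_parameter_error")
    channel_names <- simulation$channels
  } else {
    if (is.null(channel_names))
      abort("image mode requires `channel_names`",
            class = "venncf_parameter_error")
  }
  if (is.null(regions)) regions <- default_regions(channel_names)
  labels <- map_chr(regions, format)
  if (is.null(reference)) {
    k <- length(channel_names)
    if (k < 3)
      abort("no default reference region for < 3 channels; supply `reference`",
            class = "venncf_parameter_error")
    reference <- region_spec(channel_names[-k], channel_names[k])
  }
  ref_label <- if (inherits(reference, "region_spec")) format(reference)
               else as.character(reference)
  if (!ref_label %in% labels)
    abort(sprintf("reference region '%s' is not among the evaluated regions",
                  ref_label), class = "venncf_parameter_error")
  structure(list(simulation = simulation, n_cells = n_cells, images = images,
                 channel_names = channel_names,
                 threshold_method = threshold_method,
                 threshold_params = threshold_params,
                 convention = convention, regions = regions,
                 reference = ref_label, alpha = alpha, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Analyse one cell: binarize, partition, Colocalization Factors
#'
#' The per-cell pipeline: binary masks per channel, exact Venn partition
#' within the ROI, and a CF record per requested region. Thresholds and areas
#' are retained for audit.
#'
#' @param config a [run_config()].
#' @param cell the cell input: a [channel_stack()], a `simulate_cell()`
#'   result, or (image mode) an entry of `config$images`.
#' @param cell_id label for this cell.
#' @return An object of class `cell_result`: list with `cell_id`, `cf`
#'   (tibble of CF records), `venn` ([venn_summary()] tibble), `thresholds`
#'   (tibble from [binarize()]), `partition`.
#' @export
run_cell <- function(config, cell, cell_id = "cell1") {
  stopifnot(inherits(config, "run_config"))
  stack <- if (inherits(cell, "channel_stack")) cell
    else if (is.list(cell) && inherits(cell$stack, "channel_stack")) cell$stack
    else if (is.list(cell) && !is.null(cell$path))
      load_stack(cell$path, config$channel_names, roi_path = cell$roi)
    else abort("unrecognized cell input", class = "venncf_parameter_error")

  masks <- tryCatch(
    binarize(stack, method = config$threshold_method,
             params = config$threshold_params),
    error = function(e)
      abort(sprintf("[binarize, cell %s] %s", cell_id, conditionMessage(e)),
            class = setdiff(class(e), c("error", "condition"))[1]))
  pa <- partition_areas(masks)
  cf <- cf_table(pa, regions = config$regions,
                 convention = config$convention, cell_id = cell_id)
  structure(list(cell_id = cell_id, cf = cf, venn = venn_summary(pa),
                 thresholds = masks$info, partition = pa),
            class = "cell_result")
}

#' @export
print.cell_result <- function(x, ...) {
  cat(sprintf("<cell_result> %s\n", x$cell_id))
  print(as.data.frame(x$cf[, c("region", "actual_fraction",
                               "expected_fraction", "cf")]))
  invisible(x)
}

cohort_inputs <- function(config) {
  if (!is.null(config$simulation)) {
    cells <- simulate_cohort(config$simulation, config$n_cells, config$seed)
    ids <- sprintf("cell%03d", seq_along(cells))
    list(cells = cells, ids = ids)
  } else {
    ids <- map_chr(seq_along(config$images), function(i)
      config$images[[i]]$cell_id %||% sprintf("cell%03d", i))
    list(cells = config$images, ids = ids)
  }
}

#' Run the full cohort pipeline
#'
#' Analyses every cell ([run_cell()]), aggregates CFs across cells, runs the
#' one-way ANOVA with comparisons against the reference region, and makes the
#' scaffold call. When `config$out_dir` is set, writes `cf_records.csv` (one
#' row per cell x region, full double precision), `venn_summary.csv` (per
#' cell x exclusive pattern) and `cohort.json` (summaries, ANOVA,
#' comparisons, scaffold call).
#'
#' @param config a [run_config()] with >= 2 cells.
#' @return An object of class `cohort_result`: list with `cells` (all CF
#'   records), `venn` (per-cell Venn summaries), `thresholds`, `summary`
#'   (per-region mean/SEM/n), `anova` (a `cf_anova`), `scaffold` (a
#'   `scaffold_call`, 3-channel runs only), `reference`, `convention`,
#'   `alpha`, `n_cells`.
#' @examples
#' cfg <- run_config(simulation = sim_config(droplets_per_channel = 60),
#'                   n_cells = 3, seed = 11)
#' res <- run_cohort(cfg)
#' tidy(res)
#' @export
run_cohort <- function(config) {
  stopifnot(inherits(config, "run_config"))
  inp <- cohort_inputs(config)
  if (length(inp$cells) < 2)
    abort("cohort analysis needs >= 2 cells", class = "venncf_parameter_error")
  results <- vector("list", length(inp$cells))
  for (i in seq_along(inp$cells)) {
    results[[i]] <- tryCatch(
      run_cell(config, inp$cells[[i]], cell_id = inp$ids[i]),
      error = function(e)
        abort(sprintf("cell %s failed: %s", inp$ids[i], conditionMessage(e)),
              class = "venncf_cell_error"))
  }
  cf <- bind_rows(lapply(results, `[[`, "cf"))
  venn <- bind_rows(lapply(results, function(r)
    mutate(r$venn, cell_id = r$cell_id)))
  thr <- bind_rows(lapply(results, function(r)
    mutate(r$thresholds, cell_id = r$cell_id)))
  summary <- aggregate_cells(cf)
  anova <- anova_vs_reference(cf, reference = config$reference,
                              alpha = config$alpha)
  scaffold <- if (length(config$channel_names) == 3)
    call_scaffold(cf, alpha = config$alpha) else NULL

  out <- structure(list(cells = cf, venn = venn, thresholds = thr,
                        summary = summary, anova = anova,
                        scaffold = scaffold, reference = config$reference,
                        convention = config$convention, alpha = config$alpha,
                        n_cells = length(inp$cells)),
                   class = "cohort_result")
  if (!is.null(config$out_dir)) write_cohort(out, config$out_dir)
  out
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("<cohort_result> %d cells, convention '%s'\n", x$n_cells,
              x$convention))
  print(as.data.frame(x$summary))
  print(x$anova)
  if (!is.null(x$scaffold)) print(x$scaffold)
  invisible(x)
}

#' Write cohort outputs as CSV and JSON
#'
#' @param result a [run_cohort()] result.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(result, out_dir) {
  stopifnot(inherits(result, "cohort_result"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(result$cells, file.path(out_dir, "cf_records.csv"),
            row.names = FALSE)
  write.csv(result$venn, file.path(out_dir, "venn_summary.csv"),
            row.names = FALSE)
  report <- list(
    n_cells = result$n_cells,
    convention = result$convention,
    reference = result$reference,
    summary = result$summary,
    anova = result$anova$anova,
    comparisons = result$anova$comparisons,
    comparison_method = result$anova$comparison_method,
    scaffold_call = if (!is.null(result$scaffold)) list(
      scaffold = result$scaffold$scaffold,
      candidate = result$scaffold$candidate,
      significant = result$scaffold$significant,
      tie = result$scaffold$tie,
      ordering = result$scaffold$ordering,
      alpha = result$scaffold$alpha))
  jsonlite::write_json(report, file.path(out_dir, "cohort.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(out_dir)
}

#' Independence-null calibration of the Colocalization Factor
#'
#' Simulates a cohort with fully independent channels (`tether_fraction = 0`,
#' no scaffold), runs the standard pipeline, and summarises CFs per region
#' and overall. Under the random-placement null the mean CF of every Venn
#' region converges to 1 (the control level); this is the package's built-in
#' control experiment.
#'
#' @param n_cells number of independent cells to simulate.
#' @param seed cohort seed.
#' @param config base [sim_config()]; its scaffold/tether settings are
#'   overridden to the null.
#' @param convention expectation convention, see [expected_fraction()].
#' @return A list with `per_region` (tibble: region, mean_cf, sem, n,
#'   n_excluded), `overall_mean_cf` (mean CF over all defined records of the
#'   triple and exclusive-pair regions), `n_cells`, `n_records`.
#' @export
null_calibrate <- function(n_cells = 200, seed = 1L, config = sim_config(),
                           convention = "exclusion_aware") {
  null_cfg <- config
  null_cfg$scaffold_channel <- NULL
  null_cfg$tether_fraction[] <- 0
  rc <- run_config(simulation = null_cfg, n_cells = n_cells,
                   convention = convention, seed = seed)
  res <- run_cohort(rc)
  defined <- res$cells[res$cells$defined & is.finite(res$cells$cf), ]
  list(per_region = res$summary,
       overall_mean_cf = mean(defined$cf),
       n_cells = res$n_cells,
       n_records = nrow(defined))
}
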