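#' Specify a Venn region by included and excluded channels
#'
#' A region is the set of pixels belonging to every channel in `include` and
#' to none in `exclude`; channels mentioned in neither are unconstrained.
#' E.g. `region_spec(c("KIF12", "ACC1"), "COP1")` is "KIF12–ACC1
#' colocalization without COP1". Channel names are stored sorted so that
#' region labels are canonical across cells.
#'
#' @param include channels the region must contain (non-empty).
#' @param exclude channels the region must not contain (disjoint from
#'   `include`).
#' @return An object of class `region_spec`.
#' @export
region_spec <- function(include, exclude = character()) {
  include <- sort(unique(as.character(include)))
  exclude <- sort(unique(as.character(exclude)))
  if (length(include) == 0)
    abort("`include` must name at least one channel",
          class = "venncf_parameter_error")
  if (length(intersect(include, exclude)) > 0)
    abort("`include` and `exclude` must be disjoint",
          class = "venncf_parameter_error")
  structure(list(include = include, exclude = exclude),
            class = "region_spec")
}

#' @export
format.region_spec <- function(x, ...) region_label(x$include, x$exclude)

#' @export
print.region_spec <- function(x, ...) {
  cat("<region_spec>", format(x), "\n")
  invisible(x)
}

region_label <- function(include, exclude) {
  lab <- paste(sort(include), collapse = " & ")
  if (length(exclude) > 0)
    lab <- paste(lab, "w/o", paste(sort(exclude), collapse = " & "))
  lab
}

#' Default regions of interest for a channel set
#'
#' The all-channels overlap region plus, for k >= 3 channels, each exclusive
#' (k-1)-wise region (for three channels: the triple region and the three
#' exclusive pairs, the regions used to diagnose a scaffold).
#'
#' @param channels character vector of channel names.
#' @return A named list of [region_spec()]s, named by their labels.
#' @export
default_regions <- function(channels) {
  regs <- list(region_spec(channels))
  if (length(channels) >= 3)
    regs <- c(regs, lapply(channels, function(ch)
      region_spec(setdiff(channels, ch), ch)))
  setNames(regs, map_chr(regs, format))
}

check_region_channels <- function(region, channels) {
  unknown <- setdiff(c(region$include, region$exclude), channels)
  if (length(unknown) > 0)
    abort(sprintf("region mentions unknown channel(s): %s",
                  paste(unknown, collapse = ", ")),
          class = "venncf_parameter_error")
}

#' Exact Venn partition of binary masks
#'
#' Partitions the ROI into the 2^k - 1 non-empty membership patterns of the k
#' channel masks and counts pixels in each, in exact integer arithmetic, plus
#' each channel's total area fraction p_i of the ROI ("percentage of each
#' color area"). The exclusive-region areas sum exactly to the union area and
#' reconstruct each channel's marginal area exactly.
#'
#' @param masks a `mask_set` from [binarize()], or a named list of logical
#'   matrices of one shape (>= 2 channels).
#' @param roi optional logical matrix restricting the partition; defaults to
#'   the mask set's ROI or the whole frame. Mask pixels outside it are
#'   ignored.
#' @return An object of class `venn_partition`: list with `channels`,
#'   `roi_area` (pixel count), `areas` (integer vector indexed by membership
#'   code 1..2^k-1, bit i set = in channel i) and `p` (named per-channel area
#'   fractions).
#' @examples
#' a <- matrix(FALSE, 8, 8); a[1:4, 1:4] <- TRUE
#' b <- matrix(FALSE, 8, 8); b[3:6, 3:6] <- TRUE
#' partition_areas(list(A = a, B = b))
#' @export
partition_areas <- function(masks, roi = NULL) {
  if (inherits(masks, "mask_set")) {
    if (is.null(roi)) roi <- masks$roi
    masks <- masks$masks
  }
  if (!is.list(masks) || length(masks) < 2 || is.null(names(masks)))
    abort("need a named list of >= 2 binary masks",
          class = "venncf_parameter_error")
  channels <- names(masks)
  shp <- dim(masks[[1]])
  for (ch in channels) {
    if (!identical(dim(masks[[ch]]), shp))
      abort(sprintf("mask '%s' has shape %s, expected %s", ch,
                    paste(dim(masks[[ch]]), collapse = "x"),
                    paste(shp, collapse = "x")),
            class = "venncf_shape_error")
  }
  if (is.null(roi)) roi <- matrix(TRUE, shp[1], shp[2])
  if (!identical(dim(roi), shp))
    abort("ROI shape does not match mask shape", class = "venncf_shape_error")

  k <- length(channels)
  code <- integer(sum(roi))
  for (i in seq_len(k))
    code <- code + bitwShiftL(1L, i - 1L) * as.integer(masks[[channels[i]]][roi])
  areas <- tabulate(code, nbins = 2L^k - 1L)
  roi_area <- sum(roi)
  p <- map_dbl(channels, function(ch) sum(masks[[ch]] & roi) / roi_area)
  structure(list(channels = channels, roi_area = roi_area,
                 areas = as.integer(areas), p = setNames(p, channels)),
            class = "venn_partition")
}

# membership matrix (2^k-1 patterns x k channels) for a partition
pattern_membership <- function(partition) {
  k <- length(partition$channels)
  codes <- seq_len(2L^k - 1L)
  m <- sapply(seq_len(k), function(i) bitwAnd(codes, bitwShiftL(1L, i - 1L)) > 0L)
  m <- matrix(m, ncol = k)
  colnames(m) <- partition$channels
  m
}

#' @export
print.venn_partition <- function(x, ...) {
  cat(sprintf("<venn_partition> %d channels, ROI %d px, union %d px\n",
              length(x$channels), x$roi_area, sum(x$areas)))
  print(as.data.frame(venn_summary(x)))
  invisible(x)
}

#' Pixel area of a Venn region
#'
#' Sums the exclusive-pattern areas over all membership patterns containing
#' every `include` channel and no `exclude` channel. A region with a single
#' included channel and nothing excluded returns that channel's total mask
#' area.
#'
#' @param partition a [partition_areas()] result.
#' @param region a [region_spec()].
#' @return Integer pixel count.
#' @export
region_area <- function(partition, region) {
  stopifnot(inherits(partition, "venn_partition"),
            inherits(region, "region_spec"))
  check_region_channels(region, partition$channels)
  m <- pattern_membership(partition)
  keep <- rep(TRUE, nrow(m))
  for (ch in region$include) keep <- keep & m[, ch]
  for (ch in region$exclude) keep <- keep & !m[, ch]
  sum(partition$areas[keep])
}

#' Expected region fraction under the random-placement null
#'
#' Under the null that every channel's pixels are placed independently at
#' random, the chance a pixel lies in every included channel and no excluded
#' channel factorizes over channels. Two conventions are provided:
#' `"exclusion_aware"` (default) multiplies `p_i` for included channels and
#' `1 - p_j` for excluded ones — the exact independence null for an exclusive
#' region; `"paper_literal"` multiplies included fractions only ("multiplying
#' the percentages of each color area"). The two coincide whenever `exclude`
#' is empty, e.g. for the triple-overlap region.
#'
#' @param p named per-channel area fractions in \[0, 1\] (field `p` of a
#'   [partition_areas()] result).
#' @param region a [region_spec()].
#' @param convention `"exclusion_aware"` or `"paper_literal"`.
#' @return Expected fraction of ROI area in \[0, 1\].
#' @examples
#' p <- c(A = 0.5, B = 0.5, C = 0.5)
#' expected_fraction(p, region_spec(c("A", "B", "C")))          # 0.125
#' expected_fraction(p, region_spec(c("A", "B"), "C"))          # 0.125
#' expected_fraction(p, region_spec(c("A", "B"), "C"), "paper_literal") # 0.25
#' @export
expected_fraction <- function(p, region,
                              convention = c("exclusion_aware",
                                             "paper_literal")) {
  convention <- arg_match(convention)
  stopifnot(inherits(region, "region_spec"))
  check_region_channels(region, names(p))
  if (any(p < 0 | p > 1))
    abort("channel fractions must lie in [0, 1]",
          class = "venncf_parameter_error")
  e <- prod(p[region$include])
  if (convention == "exclusion_aware" && length(region$exclude) > 0)
    e <- e * prod(1 - p[region$exclude])
  unname(e)
}

#' Colocalization Factor of one region
#'
#' CF = (observed region area / ROI area) / expected fraction under the
#' random-placement null. CF = 1 indicates no association beyond chance
#' (the control level); CF > 1 indicates enrichment. When both the observed
#' and expected fractions are 0 the CF is undefined and returned as `NaN`
#' with `defined = FALSE` (cohort statistics drop such records and report the
#' exclusion); an observed area over a zero expectation is impossible for
#' included-channel products and raises an internal error.
#'
#' @inheritParams region_area
#' @inheritParams expected_fraction
#' @param cell_id label identifying the cell this partition came from.
#' @return A one-row tibble (a CF record) with columns `cell_id`, `region`,
#'   `include`, `exclude`, `actual_area`, `roi_area`, `actual_fraction`,
#'   `expected_fraction`, `cf`, `convention`, `defined`.
#' @examples
#' m <- matrix(FALSE, 10, 10); m[1:2, 1:10] <- TRUE   # p = 0.2
#' pa <- partition_areas(list(A = m, B = m, C = m))
#' colocalization_factor(pa, region_spec(c("A", "B", "C")))$cf  # 0.2^-2 = 25
#' @export
colocalization_factor <- function(partition, region,
                                  convention = c("exclusion_aware",
                                                 "paper_literal"),
                                  cell_id = NA_character_) {
  convention <- arg_match(convention)
  actual <- region_area(partition, region) / partition$roi_area
  expected <- expected_fraction(partition$p, region, convention)
  if (expected == 0 && actual > 0) {
    if (prod(partition$p[region$include]) == 0)
      abort(paste("internal inconsistency: observed area positive while an",
                  "included channel fraction is 0"))
    # expected 0 via an excluded channel covering the whole ROI: then no
    # pixel can be outside it, so actual must be 0 as well
    abort("internal inconsistency: observed area positive with expected 0")
  }
  defined <- expected > 0
  lab <- region_label(region$include, region$exclude)
  inc <- paste(region$include, collapse = ",")
  exc <- paste(region$exclude, collapse = ",")
  area <- region_area(partition, region)
  tibble(cell_id = as.character(cell_id),
         region = lab,
         include = inc,
         exclude = exc,
         actual_area = area,
         roi_area = partition$roi_area,
         actual_fraction = actual,
         expected_fraction = expected,
         cf = if (defined) actual / expected else NaN,
         convention = convention,
         defined = defined)
}

#' CF records for a set of regions
#'
#' Convenience wrapper applying [colocalization_factor()] to each region;
#' defaults to the triple region and the three exclusive pairs for a
#' three-channel partition.
#'
#' @inheritParams colocalization_factor
#' @param regions list of [region_spec()]s; default [default_regions()].
#' @return A tibble with one CF record per region.
#' @export
cf_table <- function(partition, regions = default_regions(partition$channels),
                     convention = c("exclusion_aware", "paper_literal"),
                     cell_id = NA_character_) {
  convention <- arg_match(convention)
  bind_rows(lapply(regions, function(r)
    colocalization_factor(partition, r, convention, cell_id)))
}

#' Venn-diagram summary of exclusive regions
#'
#' One row per non-empty membership pattern (2^k - 1 rows) with its pixel
#' area and percentage of the ROI; the percentages sum to the union's
#' percentage of the ROI.
#'
#' @inheritParams region_area
#' @return A tibble with columns `region` (exclusive-pattern label), one
#'   logical column per channel, `area` (px) and `percent` (of ROI).
#' @export
venn_summary <- function(partition) {
  stopifnot(inherits(partition, "venn_partition"))
  m <- pattern_membership(partition)
  labels <- apply(m, 1, function(row) {
    inc <- partition$channels[row]
    exc <- partition$channels[!row]
    if (length(exc) == 0) paste(inc, collapse = " & ")
    else if (length(inc) == 1 && length(exc) == length(partition$channels) - 1)
      paste(inc, "only")
    else region_label(inc, exc)
  })
  out <- as_tibble(as.data.frame(m))
  out <- dplyr::bind_cols(tibble(region = labels), out)
  out$area <- partition$areas
  out$percent <- 100 * partition$areas / partition$roi_area
  out
}

#' Monte-Carlo expected region fractions by toroidal randomization
#'
#' Estimates each region's expected area fraction under spatial independence
#' by repeatedly translating every channel's mask by an independent uniform
#' toroidal shift (preserving each channel's internal spatial structure while
#' destroying cross-channel association) and averaging the observed region
#' fraction over shifts. This is the model-free oracle against which the
#' analytic [expected_fraction()] can be checked.
#'
#' @param masks a `mask_set` or named list of logical matrices.
#' @param regions list of [region_spec()]s.
#' @param n_shifts number of random toroidal shifts.
#' @param seed RNG seed.
#' @param roi optional ROI (fractions are measured inside it; masks wrap over
#'   the full frame).
#' @return A tibble with one row per region: `region`, `mc_expected` (mean
#'   fraction over shifts), `mc_se` (standard error over shifts), `n_shifts`.
#' @export
toroidal_null_fraction <- function(masks, regions, n_shifts = 500,
                                   seed = 1L, roi = NULL) {
  if (inherits(masks, "mask_set")) {
    if (is.null(roi)) roi <- masks$roi
    masks <- masks$masks
  }
  channels <- names(masks)
  shp <- dim(masks[[1]])
  if (is.null(roi)) roi <- matrix(TRUE, shp[1], shp[2])
  roi_area <- sum(roi)
  for (r in regions) check_region_channels(r, channels)

  set.seed(as.integer(seed))
  fr <- matrix(NA_real_, n_shifts, length(regions))
  rows <- seq_len(shp[1]); cols <- seq_len(shp[2])
  for (s in seq_len(n_shifts)) {
    shifted <- lapply(masks, function(m) {
      dr <- sample.int(shp[1], 1L) - 1L
      dc <- sample.int(shp[2], 1L) - 1L
      m[((rows - 1L - dr) %% shp[1]) + 1L, ((cols - 1L - dc) %% shp[2]) + 1L]
    })
    for (j in seq_along(regions)) {
      reg <- regions[[j]]
      pix <- roi
      for (ch in reg$include) pix <- pix & shifted[[ch]]
      for (ch in reg$exclude) pix <- pix & !shifted[[ch]]
      fr[s, j] <- sum(pix) / roi_area
    }
  }
  tibble(region = map_chr(regions, format),
         mc_expected = colMeans(fr),
         mc_se = apply(fr, 2, sd) / sqrt(n_shifts),
         n_shifts = n_shifts)
}
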