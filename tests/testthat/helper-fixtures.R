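# random logical masks of one shape, one per channel name
rand_masks <- function(channels = c("A", "B", "C"), nr = 8, nc = 8,
                       p = 0.3, seed = 1) {
  set.seed(seed)
  setNames(lapply(channels, function(ch)
    matrix(runif(nr * nc) < p, nr, nc)), channels)
}

# small, fast simulation for unit tests (64x64, 40 droplets)
tiny_sim_config <- function(...) {
  sim_config(image_shape = c(64L, 64L), droplets_per_channel = 40L,
             seed = 99L, ...)
}

# independent oracle: per-pixel loop enumerating membership patterns.
# Deliberately naive; no shared code with partition_areas().
pixel_loop_areas <- function(masks, roi = NULL) {
  channels <- names(masks)
  nr <- nrow(masks[[1]]); nc <- ncol(masks[[1]])
  if (is.null(roi)) roi <- matrix(TRUE, nr, nc)
  counts <- integer(2^length(channels) - 1)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!roi[i, j]) next
    code <- 0L
    for (ci in seq_along(channels))
      if (masks[[channels[ci]]][i, j]) code <- code + 2L^(ci - 1L)
    if (code > 0L) counts[code] <- counts[code] + 1L
  }
  counts
}

# independent oracle: pixel count of (all include) & (no exclude)
pixel_loop_region_area <- function(masks, include, exclude = character(),
                                   roi = NULL) {
  nr <- nrow(masks[[1]]); nc <- ncol(masks[[1]])
  if (is.null(roi)) roi <- matrix(TRUE, nr, nc)
  total <- 0L
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!roi[i, j]) next
    ok <- TRUE
    for (ch in include) if (!masks[[ch]][i, j]) { ok <- FALSE; break }
    if (ok) for (ch in exclude) if (masks[[ch]][i, j]) { ok <- FALSE; break }
    if (ok) total <- total + 1L
  }
  total
}

# per-cell CF records for synthetic cohort tests, bypassing imaging:
# one row per region per cell with given cf values
fake_cf_records <- function(cf_by_region, cell_ids = NULL) {
  n <- length(cf_by_region[[1]])
  if (is.null(cell_ids)) cell_ids <- sprintf("c%d", seq_len(n))
  regions <- names(cf_by_region)
  dplyr::bind_rows(lapply(regions, function(rg) {
    spec <- attr(cf_by_region, "specs")[[rg]]
    tibble::tibble(cell_id = cell_ids, region = rg,
                   include = spec$include, exclude = spec$exclude,
                   cf = cf_by_region[[rg]], defined = TRUE)
  }))
}

# the three exclusive-pair regions (plus triple) of channels A, B, C with
# labels matching region_spec()'s canonical labels
pair_cf_records <- function(ab, ac, bc, triple = NULL,
                            channels = c("A", "B", "C")) {
  x <- list()
  specs <- list()
  lab <- function(inc, exc) {
    r <- region_spec(inc, exc)
    format(r)
  }
  add <- function(inc, exc, vals) {
    l <- lab(inc, exc)
    x[[l]] <<- vals
    specs[[l]] <<- list(include = paste(sort(inc), collapse = ","),
                        exclude = paste(sort(exc), collapse = ","))
  }
  add(channels[c(1, 2)], channels[3], ab)
  add(channels[c(1, 3)], channels[2], ac)
  add(channels[c(2, 3)], channels[1], bc)
  if (!is.null(triple)) add(channels, character(), triple)
  attr(x, "specs") <- specs
  x
}
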