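#' Otsu threshold of an intensity sample
#'
#' Histogram-based Otsu threshold: intensities are binned (`levels` bins over
#' their range), the cut maximizing between-class variance is found, and the
#' threshold is the bin edge at that cut; when several cuts tie (e.g. an
#' exactly bimodal two-delta histogram) the median tied cut is used, placing
#' the threshold strictly between the two populations. Operates on a plain
#' intensity vector so that it can be restricted to ROI pixels.
#'
#' @param v numeric vector of intensities (e.g. the ROI pixels of one plane).
#' @param levels number of histogram bins.
#' @return A single threshold; pixels with intensity `>= threshold` are
#'   foreground.
#' @export
otsu_threshold <- function(v, levels = 256L) {
  v <- v[is.finite(v)]
  r <- range(v)
  if (r[1] == r[2])
    abort(paste("constant-intensity plane: Otsu threshold is degenerate;",
                "use method = 'fixed' with an explicit threshold"),
          class = "venncf_degenerate_threshold")
  bin <- pmin(levels, 1L + floor((v - r[1]) / (r[2] - r[1]) * levels))
  h <- as.numeric(tabulate(bin, nbins = levels))
  w1 <- cumsum(h)
  m1 <- cumsum(h * seq_len(levels))
  tot <- w1[levels]; mtot <- m1[levels]
  w2 <- tot - w1
  bcv <- (mtot * w1 - m1 * tot)^2 / (w1 * w2)  # between-class variance (scaled)
  bcv[!is.finite(bcv)] <- -Inf
  bcv[levels] <- -Inf
  ties <- which(bcv >= max(bcv) - 1e-9 * abs(max(bcv)))
  k <- ties[ceiling(length(ties) / 2)]
  r[1] + k / levels * (r[2] - r[1])
}

#' Binarize each channel of a stack
#'
#' Converts every grayscale plane to a boolean mask. Thresholds are computed
#' from ROI pixels only, and pixels outside the ROI are always `FALSE`. The
#' foreground rule is `intensity >= threshold` for all methods.
#'
#' Methods:
#' * `"otsu"` (default): per-channel Otsu threshold ([otsu_threshold()]).
#' * `"fixed"`: explicit threshold(s) via `params` (single value or named per
#'   channel).
#' * `"quantile"`: threshold at the given intensity quantile of ROI pixels
#'   (`params` a probability, single or named per channel).
#'
#' @param stack a [channel_stack()].
#' @param method `"otsu"`, `"fixed"` or `"quantile"`.
#' @param params per-channel parameter for `"fixed"` (threshold) or
#'   `"quantile"` (probability); a single value is recycled to all channels.
#' @return An object of class `mask_set`: list with `masks` (named list of
#'   logical matrices), `info` (tibble with `channel`, `method`,
#'   `threshold` actually used, for audit) and `roi`.
#' @examples
#' cell <- simulate_cell(sim_config(droplets_per_channel = 40, seed = 2))
#' bm <- binarize(cell$stack)
#' bm$info
#' @export
binarize <- function(stack, method = c("otsu", "fixed", "quantile"),
                     params = NULL) {
  stopifnot(inherits(stack, "channel_stack"))
  method <- arg_match(method)
  roi <- roi_or_full(stack)
  if (sum(roi) < 2)
    abort("ROI contains fewer than 2 pixels", class = "venncf_parameter_error")
  ch_names <- names(stack$channels)

  get_param <- function(ch) {
    if (is.null(params))
      abort(sprintf("method '%s' requires `params`", method),
            class = "venncf_parameter_error")
    p <- if (is.null(names(params))) params[[1]]
         else if (ch %in% names(params)) params[[ch]]
    if (is.null(p) || is.na(p))
      abort(sprintf("no '%s' parameter supplied for channel '%s'",
                    method, ch), class = "venncf_parameter_error")
    p
  }

  masks <- list()
  info <- vector("list", length(ch_names))
  for (i in seq_along(ch_names)) {
    ch <- ch_names[i]
    plane <- stack$channels[[ch]]
    vals <- plane[roi]
    thr <- switch(method,
      otsu = otsu_threshold(vals),
      fixed = get_param(ch),
      quantile = {
        pr <- get_param(ch)
        if (pr < 0 || pr > 1)
          abort(sprintf("quantile probability for '%s' must be in [0, 1]", ch),
                class = "venncf_parameter_error")
        unname(quantile(vals, pr))
      })
    masks[[ch]] <- (plane >= thr) & roi
    info[[i]] <- tibble(channel = ch, method = method, threshold = thr)
  }
  structure(list(masks = masks, info = bind_rows(info), roi = roi),
            class = "mask_set")
}

#' @export
print.mask_set <- function(x, ...) {
  cat(sprintf("<mask_set> %d channel(s), ROI %d px\n", length(x$masks),
              sum(x$roi)))
  df <- x$info
  df$fraction <- map_dbl(x$masks, ~ sum(.x) / sum(x$roi))[df$channel]
  print(as.data.frame(df))
  invisible(x)
}

#' Export binary masks as 8-bit TIFF (0/255)
#'
#' @param masks a `mask_set` from [binarize()].
#' @param path output TIFF path (one page per channel, in channel order).
#' @return `path`, invisibly.
#' @export
write_masks <- function(masks, path) {
  stopifnot(inherits(masks, "mask_set"))
  pages <- lapply(masks$masks, function(m)
    matrix(as.numeric(m), nrow(m)))
  tiff::writeTIFF(unname(pages), path, bits.per.sample = 8L)
  invisible(path)
}
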