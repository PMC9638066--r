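#' VARI raster
#'
#' Visible atmospherically resistant index,
#' `(green - red) / (green + red - blue)`, used here to separate green
#' canopy (VARI well above 0) from bare soil (VARI near or below 0).
#' Pixels whose denominator magnitude falls below `eps` become `NA`.
#'
#' @param stack a reflectance [band_stack()].
#' @param eps denominator tolerance in reflectance units (default 1e-6).
#' @return Numeric matrix of per-pixel VARI.
#' @export
vari_raster <- function(stack, eps = 1e-6) {
  stopifnot(inherits(stack, "band_stack"))
  if (stack$units != "reflectance") {
    stop("VARI requires reflectance units", call. = FALSE)
  }
  g <- bslice(stack, "green")
  r <- bslice(stack, "red")
  b <- bslice(stack, "blue")
  den <- g + r - b
  out <- (g - r) / den
  out[abs(den) < eps] <- NA_real_
  out
}

#' Otsu threshold
#'
#' Histogram split maximizing between-class variance, over `n_bins` equal
#' bins spanning the observed data range. When several candidate splits are
#' equally optimal (e.g. an empty gap between two well-separated modes), the
#' midpoint of the optimal plateau is returned, so cleanly separated classes
#' are split through the middle of the gap. Deterministic.
#'
#' @param values numeric vector (`NA` dropped); needs at least two distinct
#'   finite values.
#' @param n_bins histogram resolution (default 256).
#' @return Threshold value; classify canopy as `value > threshold`.
#' @export
otsu_threshold <- function(values, n_bins = 256) {
  v <- values[is.finite(values)]
  if (length(unique(v)) < 2) {
    stop("Otsu threshold undefined for constant input", call. = FALSE)
  }
  rng <- range(v)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  counts <- tabulate(
    pmin(pmax(findInterval(v, breaks, rightmost.closed = TRUE), 1L), n_bins),
    nbins = n_bins
  )
  p <- counts / sum(counts)
  mids <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  w0 <- cumsum(p)                       # class 0: bins 1..t
  mu_t <- cumsum(p * mids)
  mu <- mu_t[n_bins]
  ## between-class variance for split after bin t (t = 1..n_bins-1)
  w0 <- w0[-n_bins]; mu_t <- mu_t[-n_bins]
  valid <- w0 > 0 & w0 < 1
  sigma_b <- rep(-Inf, n_bins - 1)
  sigma_b[valid] <- (mu * w0[valid] - mu_t[valid])^2 /
    (w0[valid] * (1 - w0[valid]))
  best <- which(sigma_b >= max(sigma_b) - 1e-12)
  ## split after bin t means thresholding at the upper edge of bin t
  mean(breaks[range(best) + 1L])
}

#' Canopy mask container
#' @keywords internal
new_canopy_mask <- function(mask, transform, threshold, method) {
  structure(
    list(mask = mask, transform = transform, threshold = threshold,
         method = method,
         fraction_retained = mean(mask, na.rm = TRUE)),
    class = "canopy_mask"
  )
}

#' @export
print.canopy_mask <- function(x, ...) {
  cat(sprintf("<canopy_mask> %d x %d px, method %s, threshold %.4f, %.1f%% retained\n",
              nrow(x$mask), ncol(x$mask), x$method, x$threshold,
              100 * x$fraction_retained))
  invisible(x)
}

#' Segment soil background from a VARI raster
#'
#' Canopy = pixels with `VARI > threshold`; `NA` (degenerate-denominator)
#' pixels are excluded from the canopy. `threshold = "auto"` applies
#' [otsu_threshold()] to the valid VARI values; a numeric threshold is used
#' as-is (with a warning when it falls outside the observed VARI range,
#' which yields an empty or full mask).
#'
#' @param vari VARI matrix from [vari_raster()].
#' @param threshold `"auto"` (Otsu) or a numeric VARI cutoff.
#' @param transform raster transform carried onto the mask (optional).
#' @return A `canopy_mask`: logical matrix plus threshold, method and the
#'   fraction of pixels retained.
#' @export
segment_soil <- function(vari, threshold = "auto", transform = NULL) {
  if (identical(threshold, "auto")) {
    thr <- otsu_threshold(vari)
    method <- "otsu"
  } else {
    thr <- as.numeric(threshold)
    method <- "fixed"
    rng <- range(vari, na.rm = TRUE)
    if (thr < rng[1] || thr > rng[2]) {
      warning("threshold ", format(thr), " lies outside the observed VARI range [",
              format(rng[1]), ", ", format(rng[2]), "]; mask is empty or full",
              call. = FALSE)
    }
  }
  mask <- !is.na(vari) & vari > thr
  new_canopy_mask(mask, transform, thr, method)
}

#' Confusion-matrix accuracy of a canopy mask
#'
#' Compares a predicted mask against a reference (e.g. the generator's true
#' canopy mask), treating canopy as the positive class.
#'
#' @param mask predicted `canopy_mask` or logical matrix.
#' @param truth reference `canopy_mask` or logical matrix, same shape.
#' @return Tibble: `accuracy`, `iou`, `precision`, `recall`, plus the
#'   confusion counts `tp`, `fp`, `fn`, `tn`.
#' @export
mask_accuracy <- function(mask, truth) {
  m <- if (inherits(mask, "canopy_mask")) mask$mask else mask
  t <- if (inherits(truth, "canopy_mask")) truth$mask else truth
  if (!all(dim(m) == dim(t))) {
    stop("mask and truth grids are not aligned", call. = FALSE)
  }
  ok <- !is.na(m) & !is.na(t)
  m <- m[ok]; t <- t[ok]
  tp <- sum(m & t); fp <- sum(m & !t); fn <- sum(!m & t); tn <- sum(!m & !t)
  tibble::tibble(
    accuracy = (tp + tn) / (tp + fp + fn + tn),
    iou = if (tp + fp + fn == 0) 1 else tp / (tp + fp + fn),
    precision = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
    recall = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
    tp = tp, fp = fp, fn = fn, tn = tn
  )
}
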