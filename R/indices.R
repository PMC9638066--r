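#' Vegetation index formulas
#'
#' The nine indices computed by the pipeline, as functions of the five band
#' reflectances. `repRVI = red / NIR` is the reciprocal of the classic ratio
#' vegetation index (`RVI = NIR / red`); with the red band in the numerator
#' it tracks the rising red reflectance of ripening canopies that RVI,
#' dominated by its NIR numerator, smooths over.
#'
#' @return Character vector of supported index names.
#' @export
index_names <- function() {
  c("VARI", "NGBDI", "NDVI", "NDRE", "GNDVI",
    "CIrededge", "MTCI", "mNDblue", "repRVI")
}

## each: function(b, g, r, re, n) -> list(num, den) or value; den checked vs eps
index_formula <- function(name) {
  switch(
    name,
    VARI      = function(b, g, r, re, n) list(g - r, g + r - b),
    NGBDI     = function(b, g, r, re, n) list(g - b, g + b),
    NDVI      = function(b, g, r, re, n) list(n - r, n + r),
    NDRE      = function(b, g, r, re, n) list(n - re, n + re),
    GNDVI     = function(b, g, r, re, n) list(n - g, n + g),
    CIrededge = function(b, g, r, re, n) list(n - re, re),   # n/re - 1
    MTCI      = function(b, g, r, re, n) list(n - re, re - r),
    mNDblue   = function(b, g, r, re, n) list(b - re, n + b),
    repRVI    = function(b, g, r, re, n) list(r, n),
    stop("unknown vegetation index: ", name, call. = FALSE)
  )
}

#' Compute a vegetation index raster
#'
#' Applies the index formula per pixel; pixels whose denominator magnitude
#' falls below `eps` are set to `NA`, and `NA` reflectance propagates.
#'
#' @param stack a reflectance [band_stack()].
#' @param name one of [index_names()].
#' @param eps denominator tolerance (default 1e-6).
#' @return Numeric matrix of per-pixel index values.
#' @export
compute_index <- function(stack, name, eps = 1e-6) {
  stopifnot(inherits(stack, "band_stack"))
  if (stack$units != "reflectance") {
    stop("vegetation indices require reflectance units", call. = FALSE)
  }
  f <- index_formula(name)
  parts <- f(bslice(stack, "blue"), bslice(stack, "green"),
             bslice(stack, "red"), bslice(stack, "rededge"),
             bslice(stack, "nir"))
  out <- parts[[1]] / parts[[2]]
  out[abs(parts[[2]]) < eps] <- NA_real_
  out
}

#' Masked zonal mean over a plot polygon
#'
#' Mean of raster values over pixels whose centres fall inside the plot
#' polygon shrunk inward by `edge_buffer` (avoiding plot-boundary spectral
#' mixing), that are flagged canopy in the mask, and are not `NA`.
#'
#' @param raster numeric matrix (e.g. an index raster).
#' @param poly plot polygon (axis-aligned rectangle ring, world metres).
#' @param mask `canopy_mask` or logical matrix aligned with `raster`
#'   (`NULL` = no masking).
#' @param transform raster transform (see [band_stack()]).
#' @param edge_buffer inward buffer, m (default 0.25).
#' @return List: `value` (mean), `n_pixels` (count used).
#' @export
zonal_mean <- function(raster, poly, mask = NULL, transform, edge_buffer = 0.25) {
  m <- if (inherits(mask, "canopy_mask")) mask$mask else mask
  if (!is.null(m) && !all(dim(m) == dim(raster))) {
    stop("raster and mask grids are not aligned", call. = FALSE)
  }
  inner <- if (edge_buffer > 0) buffer_rectangle_inward(poly, edge_buffer) else poly
  sel <- polygon_pixel_mask(transform, nrow(raster), ncol(raster), inner)
  if (!is.null(m)) sel <- sel & m
  vals <- raster[sel]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) {
    stop("empty zone: no qualifying pixels in plot polygon", call. = FALSE)
  }
  list(value = mean(vals), n_pixels = length(vals))
}

#' Per-plot vegetation index table
#'
#' Computes each requested index raster per stage and extracts its masked
#' zonal mean for every plot, yielding the long table that drives screening
#' and modeling. Plot aggregation is the mean of per-pixel index values
#' (mean-of-index, not index-of-mean-reflectance). Plots with no qualifying
#' pixels at some stage are dropped from the table, recorded in the
#' `"empty_zones"` attribute, and reported in a warning; other plots are
#' unaffected.
#'
#' @param stacks named list of reflectance [band_stack()]s, one per stage.
#' @param layout plot-layout tibble from [build_design()].
#' @param masks named list of `canopy_mask`es aligned with `stacks`
#'   (`NULL` = no masking).
#' @param indices character vector of index names, or `"all"`.
#' @param edge_buffer inward plot buffer, m.
#' @return Tibble: `plot_id`, `stage`, `index`, `value`, `n_pixels`; one row
#'   per combination, `(plot_id, stage, index)` unique.
#' @export
build_vi_table <- function(stacks, layout, masks = NULL,
                           indices = "all", edge_buffer = 0.25) {
  if (identical(indices, "all")) indices <- index_names()
  stages <- names(stacks)
  if (is.null(stages) || any(!nzchar(stages))) {
    stop("`stacks` must be a named list keyed by stage", call. = FALSE)
  }
  if (!is.null(masks) && !all(stages %in% names(masks))) {
    stop("missing canopy mask for at least one stage", call. = FALSE)
  }
  empty <- tibble::tibble(plot_id = character(), stage = character())
  rows <- purrr::map_dfr(stages, function(st) {
    stack <- stacks[[st]]
    mask <- if (is.null(masks)) NULL else masks[[st]]
    purrr::map_dfr(indices, function(ix) {
      rast <- compute_index(stack, ix)
      purrr::map_dfr(seq_len(nrow(layout)), function(i) {
        zm <- tryCatch(
          zonal_mean(rast, layout$geometry[[i]], mask, stack$transform,
                     edge_buffer),
          error = function(e) NULL
        )
        if (is.null(zm)) {
          empty <<- dplyr::bind_rows(
            empty, tibble::tibble(plot_id = layout$plot_id[i], stage = st))
          return(NULL)
        }
        tibble::tibble(plot_id = layout$plot_id[i], stage = st, index = ix,
                       value = zm$value, n_pixels = zm$n_pixels)
      })
    })
  })
  empty <- dplyr::distinct(empty)
  if (nrow(empty) > 0) {
    warning(nrow(empty), " (plot, stage) zones had no qualifying pixels; ",
            "see attr(, \"empty_zones\")", call. = FALSE)
  }
  attr(rows, "empty_zones") <- empty
  rows
}
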