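#' Five-band raster stack
#'
#' In-memory container for co-registered multispectral imagery. Bands are
#' stored as a numeric array of dimension `nrow x ncol x 5` in the fixed
#' order blue, green, red, red-edge, NIR (the band set of the consumer
#' multispectral cameras this pipeline targets: 450/560/650/730/840 nm).
#' Pixels are squares of side `transform$px` metres; the world coordinate of
#' the centre of pixel `(row, col)` is
#' `x = x0 + (col - 0.5) * px`, `y = y0 - (row - 0.5) * px`
#' with `(x0, y0)` the top-left corner of the grid ("pixel-is-area").
#' Missing data is `NA`.
#'
#' @param values numeric array `nrow x ncol x 5`, band order
#'   blue/green/red/red-edge/NIR.
#' @param units `"DN"` (raw digital numbers) or `"reflectance"`.
#' @param transform list with `x0`, `y0` (world metres, top-left corner) and
#'   `px` (pixel size in metres).
#' @return An object of class `band_stack`.
#' @export
band_stack <- function(values, units = c("DN", "reflectance"),
                       transform = list(x0 = 0, y0 = 0, px = 1)) {
  units <- match.arg(units)
  if (length(dim(values)) != 3L || dim(values)[3] != 5L) {
    stop("`values` must be a nrow x ncol x 5 array", call. = FALSE)
  }
  if (!is.numeric(transform$px) || transform$px <= 0) {
    stop("pixel size must be positive", call. = FALSE)
  }
  dimnames(values)[[3]] <- band_names()
  structure(
    list(
      values = values,
      units = units,
      band_meta = band_meta(),
      transform = transform
    ),
    class = "band_stack"
  )
}

band_names <- function() c("blue", "green", "red", "rededge", "nir")

band_meta <- function() {
  tibble::tibble(
    band = band_names(),
    center_nm = c(450, 560, 650, 730, 840),
    bandwidth_nm = c(32, 32, 32, 32, 52)
  )
}

#' @export
print.band_stack <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<band_stack> %d x %d px, 5 bands (%s), units: %s, px = %g m\n",
    d[1], d[2], paste(band_names(), collapse = "/"), x$units, x$transform$px
  ))
  invisible(x)
}

#' @export
dim.band_stack <- function(x) dim(x$values)

#' Extract one band as a matrix
#' @param stack a [band_stack()].
#' @param band band name (`"blue"`, `"green"`, `"red"`, `"rededge"`, `"nir"`).
#' @return numeric matrix.
#' @export
get_band <- function(stack, band) {
  stopifnot(inherits(stack, "band_stack"))
  band <- match.arg(band, band_names())
  bslice(stack, band)
}

## band slice that never drops the matrix dimensions
bslice <- function(stack, band) {
  d <- dim(stack$values)
  matrix(stack$values[, , band], d[1], d[2])
}

## ---- world <-> pixel geometry -------------------------------------------

pixel_centers_x <- function(transform, ncol) {
  transform$x0 + (seq_len(ncol) - 0.5) * transform$px
}

pixel_centers_y <- function(transform, nrow) {
  transform$y0 - (seq_len(nrow) - 0.5) * transform$px
}

#' Test which points fall inside a polygon (ray casting)
#'
#' Even-odd rule on a closed or open ring; points exactly on a horizontal
#' edge follow the half-open convention (lower vertex included), which makes
#' adjacent polygons partition the plane.
#'
#' @param x,y point coordinates (equal length).
#' @param poly two-column matrix of vertex coordinates (ring; closure
#'   optional).
#' @return logical vector.
#' @export
points_in_polygon <- function(x, y, poly) {
  px <- poly[, 1]; py <- poly[, 2]
  n <- length(px)
  if (px[1] == px[n] && py[1] == py[n]) { # drop duplicated closing vertex
    px <- px[-n]; py <- py[-n]; n <- n - 1L
  }
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((py[i] > y) != (py[j] > y)) &
      (x < (px[j] - px[i]) * (y - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Shrink an axis-aligned rectangle inward
#'
#' Plot polygons in this pipeline are axis-aligned rectangles; the inward
#' edge buffer used by zonal extraction is therefore a simple bound
#' contraction. Non-rectangular rings are rejected rather than approximated.
#'
#' @param poly two-column vertex matrix of an axis-aligned rectangle.
#' @param buffer inward distance in metres (non-negative).
#' @return vertex matrix of the shrunken rectangle.
#' @export
buffer_rectangle_inward <- function(poly, buffer) {
  stopifnot(buffer >= 0)
  xs <- unique(round(poly[, 1], 9)); ys <- unique(round(poly[, 2], 9))
  if (length(xs) != 2L || length(ys) != 2L) {
    stop("inward buffering supports axis-aligned rectangles only", call. = FALSE)
  }
  x1 <- min(xs) + buffer; x2 <- max(xs) - buffer
  y1 <- min(ys) + buffer; y2 <- max(ys) - buffer
  if (x1 >= x2 || y1 >= y2) {
    stop("buffer collapses the rectangle to an empty region", call. = FALSE)
  }
  cbind(c(x1, x2, x2, x1, x1), c(y1, y1, y2, y2, y1))
}

#' Logical pixel selector for a polygon on a raster grid
#'
#' Inclusion is by pixel centre in polygon, in world coordinates.
#'
#' @param transform raster transform (see [band_stack()]).
#' @param nr,nc raster dimensions.
#' @param poly two-column vertex matrix.
#' @return logical matrix `nr x nc`.
#' @export
polygon_pixel_mask <- function(transform, nr, nc, poly) {
  xs <- pixel_centers_x(transform, nc)
  ys <- pixel_centers_y(transform, nr)
  ## bounding-box prefilter keeps the ray cast cheap
  cols <- which(xs >= min(poly[, 1]) & xs <= max(poly[, 1]))
  rows <- which(ys >= min(poly[, 2]) & ys <= max(poly[, 2]))
  out <- matrix(FALSE, nr, nc)
  if (!length(cols) || !length(rows)) return(out)
  grid <- expand.grid(row = rows, col = cols)
  inside <- points_in_polygon(xs[grid$col], ys[grid$row], poly)
  out[cbind(grid$row, grid$col)] <- inside
  out
}

rectangle_ring <- function(x1, y1, x2, y2) {
  cbind(c(x1, x2, x2, x1, x1), c(y1, y1, y2, y2, y1))
}

## ---- file I/O ------------------------------------------------------------

#' Write a DN band stack to a multi-page 16-bit TIFF
#'
#' One TIFF directory per band in blue/green/red/red-edge/NIR order, 16-bit
#' unsigned. The world transform and units are written to a JSON sidecar
#' (`<path>.json`) since baseline TIFF carries no georeferencing tags.
#'
#' @param stack a [band_stack()] in DN units (integer-valued, 0..65535).
#' @param path output file path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "band_stack"))
  if (stack$units != "DN") stop("write_stack_tiff expects DN units", call. = FALSE)
  pages <- lapply(band_names(), function(b) {
    m <- stack$values[, , b]
    m[is.na(m)] <- 0
    m / 65535
  })
  ok <- tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  if (!isTRUE(ok == length(pages))) stop("failed to write ", path, call. = FALSE)
  jsonlite::write_json(
    list(units = stack$units, transform = stack$transform),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a band stack written by [write_stack_tiff()]
#' @param path TIFF path; the `<path>.json` sidecar must be present.
#' @return a [band_stack()] in DN units.
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  vals <- array(NA_real_, c(dim(pages[[1]]), length(pages)))
  for (i in seq_along(pages)) vals[, , i] <- round(pages[[i]] * 65535)
  band_stack(vals, units = meta$units,
             transform = as.list(meta$transform))
}

write_mask_tiff <- function(mask_matrix, transform, path) {
  m <- mask_matrix * 1
  m[is.na(m)] <- 0
  ok <- tiff::writeTIFF(m, path, bits.per.sample = 8L, compression = "none")
  if (!isTRUE(ok == 1L)) stop("failed to write ", path, call. = FALSE)
  jsonlite::write_json(list(transform = transform), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_mask_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  round(m * 255) > 0
}
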