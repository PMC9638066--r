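#' Plot-layout and panel GeoJSON I/O
#'
#' A plot layout is a tibble with one row per plot: `plot_id`, `n_level`
#' (kg N/ha), `variety`, `replicate`, and a `geometry` list-column of
#' two-column vertex matrices (closed rings, world metres). Panel sets carry
#' `panel_id`, `geometry` and a `reflectance` list-column of per-band known
#' reflectances.
#'
#' @param layout plot-layout tibble.
#' @param path output `.geojson` path.
#' @return `path`, invisibly.
#' @name layout_io
NULL

polygon_to_geojson <- function(poly) {
  ring <- poly
  n <- nrow(ring)
  if (ring[1, 1] != ring[n, 1] || ring[1, 2] != ring[n, 2]) {
    ring <- rbind(ring, ring[1, ])
  }
  list(
    type = "Polygon",
    coordinates = list(lapply(seq_len(nrow(ring)), function(i) c(ring[i, 1], ring[i, 2])))
  )
}

geojson_to_polygon <- function(geom) {
  ring <- geom$coordinates[[1]]
  do.call(rbind, lapply(ring, function(p) c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
}

#' @rdname layout_io
#' @export
write_layout_geojson <- function(layout, path) {
  features <- purrr::pmap(layout, function(plot_id, n_level, variety, replicate, geometry, ...) {
    list(
      type = "Feature",
      properties = list(plot_id = plot_id, n_level = n_level,
                        variety = variety, replicate = replicate),
      geometry = polygon_to_geojson(geometry)
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname layout_io
#' @export
read_layout_geojson <- function(path) {
  fc <- jsonlite::read_json(path, simplifyVector = FALSE)
  purrr::map_dfr(fc$features, function(f) {
    tibble::tibble(
      plot_id = f$properties$plot_id,
      n_level = as.numeric(f$properties$n_level),
      variety = f$properties$variety,
      replicate = as.integer(f$properties$replicate),
      geometry = list(geojson_to_polygon(f$geometry))
    )
  })
}

#' @rdname layout_io
#' @param panels panel-set tibble (`panel_id`, `geometry`, `reflectance`).
#' @export
write_panels_geojson <- function(panels, path) {
  features <- purrr::pmap(panels, function(panel_id, geometry, reflectance, ...) {
    list(
      type = "Feature",
      properties = c(list(panel_id = panel_id), as.list(reflectance)),
      geometry = polygon_to_geojson(geometry)
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname layout_io
#' @export
read_panels_geojson <- function(path) {
  fc <- jsonlite::read_json(path, simplifyVector = FALSE)
  purrr::map_dfr(fc$features, function(f) {
    refl <- unlist(f$properties[band_names()])
    tibble::tibble(
      panel_id = f$properties$panel_id,
      geometry = list(geojson_to_polygon(f$geometry)),
      reflectance = list(refl)
    )
  })
}

#' Panel known reflectances as a tidy table
#' @param panels panel-set tibble.
#' @return tibble with `panel_id`, `band`, `reflectance`.
#' @export
panel_reflectance_table <- function(panels) {
  purrr::map_dfr(seq_len(nrow(panels)), function(i) {
    tibble::tibble(
      panel_id = panels$panel_id[i],
      band = band_names(),
      reflectance = as.numeric(panels$reflectance[[i]][band_names()])
    )
  })
}
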