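#' Configuration for a synthetic wheat trial scene
#'
#' Describes a split-plot nitrogen-rate trial imaged by a five-band UAV
#' camera: 4 N levels x 3 varieties x 3 replicates = 36 plots of 2 m x 8 m
#' at 1.5 cm ground sample distance, flown at six growth stages (jointing
#' through late grain-filling), with four grey reference panels in view.
#' Canopy radiometry follows a linear soil/canopy mixture: each plot has a
#' latent "vigor" that increases (saturating) with N rate, drives fractional
#' canopy cover per stage, shifts the canopy spectrum (red/blue down,
#' red-edge/NIR up), and determines yield linearly. Digital numbers invert
#' the empirical line: DN = reflectance / a_i + noise.
#'
#' @param n_levels N fertilizer rates, kg N/ha.
#' @param n_varieties,n_replicates design counts.
#' @param plot_width,plot_length plot dimensions, m.
#' @param plot_spacing gap between plots, m.
#' @param gsd ground sample distance, m/pixel.
#' @param stages ordered growth-stage labels.
#' @param soil_spectrum per-band reflectance of bare soil, `[0,1]`.
#' @param canopy_base,canopy_slope per-band canopy reflectance at vigor 1 and
#'   its change per unit vigor (red/blue negative, red-edge/NIR positive).
#' @param cover_stage_base per-stage intercept of the logistic cover model.
#' @param cover_vigor_slope,cover_vigor_center logistic cover model:
#'   cover = plogis(base_stage + slope * (vigor - center)).
#' @param cover_noise_sd per-pixel fractional-cover noise sd.
#' @param vigor_max_gain,vigor_half_sat vigor = 1 + gain * N / (N + half_sat).
#' @param variety_effects additive vigor offsets, one per variety (small:
#'   the N treatment dominates the variance structure).
#' @param vigor_noise_sd per-plot vigor noise sd.
#' @param yield_intercept,yield_slope,yield_noise_sd yield model, kg/ha:
#'   yield = intercept + slope * vigor + N(0, sd).
#' @param elm_true_slopes true per-band DN-to-reflectance slopes a_i
#'   (strictly positive).
#' @param dn_noise_sd additive DN noise sd (before integer rounding).
#' @param dn_round round DN to integers (16-bit sensor convention, the
#'   default). `FALSE` keeps continuous DN, making empirical-line inversion
#'   exact — the configuration used when validating calibration recovery,
#'   where quantization would otherwise dominate the error.
#' @param refl_noise_sd per-pixel reflectance noise sd (sub-pixel mixing).
#' @param panel_reflectances per-panel nominal reflectance (flat spectra).
#' @param panel_size panel side length, m.
#' @param margin bare-soil margin around the trial, m.
#' @param seed integer seed fixing the whole scene.
#' @return A `scene_config` list.
#' @export
scene_config <- function(n_levels = c(0, 100, 200, 300),
                         n_varieties = 3,
                         n_replicates = 3,
                         plot_width = 2,
                         plot_length = 8,
                         plot_spacing = 0.5,
                         gsd = 0.015,
                         stages = c("J", "B", "H", "LF", "IGF", "LGF"),
                         soil_spectrum = c(blue = 0.10, green = 0.18, red = 0.22,
                                           rededge = 0.26, nir = 0.30),
                         canopy_base = c(blue = 0.040, green = 0.140, red = 0.050,
                                         rededge = 0.220, nir = 0.350),
                         canopy_slope = c(blue = -0.008, green = -0.010, red = -0.012,
                                          rededge = 0.040, nir = 0.100),
                         cover_stage_base = c(J = -0.8, B = 0.6, H = 1.4,
                                              LF = 1.8, IGF = 1.8, LGF = 1.5),
                         cover_vigor_slope = 1.2,
                         cover_vigor_center = 1.6,
                         cover_noise_sd = 0.04,
                         vigor_max_gain = 2,
                         vigor_half_sat = 150,
                         variety_effects = c(0.15, 0, -0.15),
                         vigor_noise_sd = 0.08,
                         yield_intercept = 1500,
                         yield_slope = 2200,
                         yield_noise_sd = 250,
                         elm_true_slopes = c(blue = 2.2e-05, green = 2.4e-05,
                                             red = 2.5e-05, rededge = 2.6e-05,
                                             nir = 2.8e-05),
                         dn_noise_sd = 20,
                         dn_round = TRUE,
                         refl_noise_sd = 0.004,
                         panel_reflectances = c(0.05, 0.20, 0.40, 0.60),
                         panel_size = 0.6,
                         margin = 1,
                         seed = 1L) {
  cfg <- as.list(environment())
  validate_scene_config(cfg)
  structure(cfg, class = "scene_config")
}

validate_scene_config <- function(cfg) {
  with(cfg, {
    if (plot_width <= 0 || plot_length <= 0 || gsd <= 0 || plot_spacing < 0 ||
        n_varieties < 1 || n_replicates < 1 || length(n_levels) < 1) {
      stop("invalid scene configuration: non-positive dimension or count",
           call. = FALSE)
    }
    refl <- c(soil_spectrum, panel_reflectances)
    if (any(refl < 0 | refl > 1)) {
      stop("reflectances must lie in [0, 1]", call. = FALSE)
    }
    if (any(elm_true_slopes <= 0) || any(!is.finite(elm_true_slopes))) {
      stop("elm_true_slopes must be strictly positive", call. = FALSE)
    }
    sds <- c(cover_noise_sd, vigor_noise_sd, yield_noise_sd, dn_noise_sd,
             refl_noise_sd)
    if (any(sds < 0)) stop("noise sd must be non-negative", call. = FALSE)
    if (length(variety_effects) != n_varieties) {
      stop("variety_effects must have one entry per variety", call. = FALSE)
    }
    if (!all(stages %in% names(cover_stage_base))) {
      stop("every stage needs a cover_stage_base entry", call. = FALSE)
    }
  })
  invisible(cfg)
}

## trial geometry: replicates are rows, N x variety combinations are columns,
## panels sit in a strip above the top replicate
scene_geometry <- function(cfg) {
  n_cols <- length(cfg$n_levels) * cfg$n_varieties
  n_panels <- length(cfg$panel_reflectances)
  width <- max(
    2 * cfg$margin + n_cols * cfg$plot_width + (n_cols - 1) * cfg$plot_spacing,
    2 * cfg$margin + n_panels * cfg$panel_size + (n_panels - 1) * 0.5
  )
  plots_top <- cfg$margin + cfg$n_replicates * cfg$plot_length +
    (cfg$n_replicates - 1) * cfg$plot_spacing
  panel_y1 <- plots_top + cfg$plot_spacing
  height <- panel_y1 + cfg$panel_size + cfg$margin
  list(n_cols = n_cols, width = width, height = height, panel_y1 = panel_y1,
       transform = list(x0 = 0, y0 = height, px = cfg$gsd),
       nrow = as.integer(ceiling(height / cfg$gsd)),
       ncol = as.integer(ceiling(width / cfg$gsd)))
}

#' Lay out the trial's plot polygons
#'
#' Places the `|n_levels| * varieties * replicates` rectangular plots on a
#' regular grid (replicates as rows; N level varying slowest across columns,
#' variety fastest) with the configured inter-plot spacing. Deterministic
#' given the configuration.
#'
#' @param config a [scene_config()].
#' @return Plot-layout tibble: `plot_id`, `n_level`, `variety`, `replicate`,
#'   `geometry` (list of rectangle rings, world metres).
#' @export
build_design <- function(config) {
  validate_scene_config(config)
  geo <- scene_geometry(config)
  grid <- tidyr::expand_grid(
    replicate = seq_len(config$n_replicates),
    n_level = config$n_levels,
    variety_idx = seq_len(config$n_varieties)
  )
  grid <- dplyr::mutate(
    grid,
    col = (match(.data$n_level, config$n_levels) - 1L) * config$n_varieties +
      .data$variety_idx,
    x1 = config$margin + (.data$col - 1) * (config$plot_width + config$plot_spacing),
    y1 = config$margin + (.data$replicate - 1) *
      (config$plot_length + config$plot_spacing),
    variety = paste0("V", .data$variety_idx),
    plot_id = sprintf("P%02d", dplyr::row_number())
  )
  tibble::tibble(
    plot_id = grid$plot_id,
    n_level = grid$n_level,
    variety = grid$variety,
    replicate = grid$replicate,
    geometry = purrr::map2(
      grid$x1, grid$y1,
      ~rectangle_ring(.x, .y, .x + config$plot_width, .y + config$plot_length)
    )
  )
}

#' Reference panels for a scene
#'
#' Panels are squares in a strip above the plots, with flat (band-constant)
#' known reflectances spanning the configured grey levels.
#'
#' @param config a [scene_config()].
#' @return Panel tibble: `panel_id`, `geometry`, `reflectance` (named
#'   per-band vector).
#' @export
build_panels <- function(config) {
  geo <- scene_geometry(config)
  purrr::map_dfr(seq_along(config$panel_reflectances), function(k) {
    x1 <- config$margin + (k - 1) * (config$panel_size + 0.5)
    tibble::tibble(
      panel_id = sprintf("panel%d", k),
      geometry = list(rectangle_ring(x1, geo$panel_y1,
                                     x1 + config$panel_size,
                                     geo$panel_y1 + config$panel_size)),
      reflectance = list(stats::setNames(
        rep(config$panel_reflectances[k], 5), band_names()
      ))
    )
  })
}

#' Simulate per-plot ground truth
#'
#' Draws the latent plot vigor (saturating in N rate, plus a small variety
#' offset and Gaussian noise), the resulting yield, per-stage true fractional
#' canopy cover, and the per-band canopy reflectance of each plot.
#'
#' @param layout output of [build_design()].
#' @param config a [scene_config()].
#' @param seed integer seed.
#' @return A `ground_truth` list: `plots` (tibble with `vigor`,
#'   `yield_kg_ha`), `cover` (plot x stage), `canopy_reflectance`
#'   (plot x band), `elm_true_slopes`, `layout`, `config`.
#' @export
simulate_ground_truth <- function(layout, config, seed = config$seed) {
  validate_scene_config(config)
  n <- nrow(layout)
  withr::with_seed(seed, {
    vidx <- as.integer(sub("^V", "", layout$variety))
    vigor <- 1 + config$vigor_max_gain * layout$n_level /
      (layout$n_level + config$vigor_half_sat) +
      config$variety_effects[vidx] +
      stats::rnorm(n, 0, config$vigor_noise_sd)
    yield <- pmax(0, config$yield_intercept + config$yield_slope * vigor +
                    stats::rnorm(n, 0, config$yield_noise_sd))
  })
  plots <- dplyr::mutate(
    dplyr::select(layout, -"geometry"),
    vigor = vigor, yield_kg_ha = yield
  )
  cover <- tidyr::expand_grid(plot_id = layout$plot_id, stage = config$stages)
  cover <- dplyr::left_join(cover, plots[, c("plot_id", "vigor")], by = "plot_id")
  cover$cover <- stats::plogis(
    config$cover_stage_base[cover$stage] +
      config$cover_vigor_slope * (cover$vigor - config$cover_vigor_center)
  )
  cover$vigor <- NULL
  canopy <- tidyr::expand_grid(plot_id = layout$plot_id, band = band_names())
  canopy <- dplyr::left_join(canopy, plots[, c("plot_id", "vigor")], by = "plot_id")
  canopy$reflectance <- pmin(0.95, pmax(0.01,
    config$canopy_base[canopy$band] +
      config$canopy_slope[canopy$band] * (canopy$vigor - 1)
  ))
  canopy$vigor <- NULL
  structure(
    list(plots = plots, cover = cover, canopy_reflectance = canopy,
         elm_true_slopes = config$elm_true_slopes,
         layout = layout, config = config),
    class = "ground_truth"
  )
}

## fill a rectangle's pixel block (pixel-centre rule) with values
rect_pixel_range <- function(poly, transform, nr, nc) {
  xs <- range(poly[, 1]); ys <- range(poly[, 2])
  cols <- which(pixel_centers_x(transform, nc) > xs[1] &
                  pixel_centers_x(transform, nc) < xs[2])
  rows <- which(pixel_centers_y(transform, nr) > ys[1] &
                  pixel_centers_y(transform, nr) < ys[2])
  list(rows = rows, cols = cols)
}

#' Render one growth stage as a DN image
#'
#' Per-pixel reflectance is the cover-weighted linear mixture of the plot's
#' canopy spectrum and the soil spectrum, plus Gaussian sub-pixel noise,
#' clipped to `[0,1]`; panels are uniform patches at their known reflectance.
#' DN inverts the empirical line per band (`DN = R / a_i + noise`), rounded
#' to integers in `[0, 65535]`. The true canopy mask marks pixels whose
#' realized canopy fraction exceeds 0.5 (panels excluded).
#'
#' @param truth output of [simulate_ground_truth()].
#' @param stage stage label (must be in `config$stages`).
#' @param config a [scene_config()].
#' @param seed integer seed.
#' @return List: `stack` (DN [band_stack()]), `true_mask` (logical matrix),
#'   `panels` (panel tibble), `stage`.
#' @export
render_scene <- function(truth, stage, config = truth$config, seed = config$seed) {
  if (!stage %in% config$stages) {
    stop("unknown stage label: ", stage, call. = FALSE)
  }
  geo <- scene_geometry(config)
  nr <- geo$nrow; nc <- geo$ncol
  layout <- truth$layout
  panels <- build_panels(config)
  stage_cover <- dplyr::filter(truth$cover, .data$stage == !!stage)
  canopy_wide <- tidyr::pivot_wider(truth$canopy_reflectance,
                                    names_from = "band",
                                    values_from = "reflectance")

  withr::with_seed(seed, {
    cover_px <- matrix(0, nr, nc)
    canopy_px <- lapply(band_names(), function(b) matrix(NA_real_, nr, nc))
    names(canopy_px) <- band_names()
    for (i in seq_len(nrow(layout))) {
      rng <- rect_pixel_range(layout$geometry[[i]], geo$transform, nr, nc)
      npx <- length(rng$rows) * length(rng$cols)
      if (npx == 0) next
      mu <- stage_cover$cover[stage_cover$plot_id == layout$plot_id[i]]
      cover_px[rng$rows, rng$cols] <- pmin(1, pmax(0,
        mu + stats::rnorm(npx, 0, config$cover_noise_sd)))
      crow <- canopy_wide[canopy_wide$plot_id == layout$plot_id[i], ]
      for (b in band_names()) canopy_px[[b]][rng$rows, rng$cols] <- crow[[b]]
    }

    vals <- array(NA_real_, c(nr, nc, 5))
    for (k in seq_along(band_names())) {
      b <- band_names()[k]
      cb <- canopy_px[[b]]
      cb[is.na(cb)] <- 0   # no canopy outside plots
      refl <- cover_px * cb + (1 - cover_px) * config$soil_spectrum[b]
      if (config$refl_noise_sd > 0) {
        refl <- refl + stats::rnorm(length(refl), 0, config$refl_noise_sd)
      }
      vals[, , k] <- pmin(1, pmax(0, refl))
    }

    panel_px <- matrix(FALSE, nr, nc)
    for (i in seq_len(nrow(panels))) {
      rng <- rect_pixel_range(panels$geometry[[i]], geo$transform, nr, nc)
      panel_px[rng$rows, rng$cols] <- TRUE
      for (k in seq_along(band_names())) {
        b <- band_names()[k]
        sl <- vals[, , k]
        sl[rng$rows, rng$cols] <- panels$reflectance[[i]][b]
        vals[, , k] <- sl
      }
    }

    for (k in seq_along(band_names())) {
      a <- config$elm_true_slopes[band_names()[k]]
      dn <- vals[, , k] / a
      if (config$dn_noise_sd > 0) {
        dn <- dn + stats::rnorm(length(dn), 0, config$dn_noise_sd)
      }
      if (config$dn_round) dn <- round(dn)
      vals[, , k] <- pmin(65535, pmax(0, dn))
    }
    true_mask <- cover_px > 0.5 & !panel_px
  })

  list(
    stack = band_stack(vals, units = "DN", transform = geo$transform),
    true_mask = true_mask,
    panels = panels,
    stage = stage
  )
}

#' Simulate a complete multi-stage trial scene
#'
#' Convenience wrapper: design, ground truth, and one rendered DN image per
#' stage, each stage with a seed derived from the scene seed.
#'
#' @param config a [scene_config()].
#' @return List: `config`, `layout`, `panels`, `truth`, `stages` (named list
#'   of [render_scene()] outputs).
#' @export
simulate_scene <- function(config = scene_config()) {
  layout <- build_design(config)
  truth <- simulate_ground_truth(layout, config, seed = config$seed)
  stages <- lapply(seq_along(config$stages), function(k) {
    render_scene(truth, config$stages[k], config, seed = config$seed + 100L + k)
  })
  names(stages) <- config$stages
  list(config = config, layout = layout, panels = build_panels(config),
       truth = truth, stages = stages)
}

#' Write / read a simulated scene on disk
#'
#' Persists per-stage 16-bit DN TIFFs and true-mask TIFFs, the plot layout
#' and panel GeoJSONs, a tidy panel-reflectance CSV, and ground-truth CSVs.
#' `read_scene()` round-trips the rasters bit-identically.
#'
#' @param scene output of [simulate_scene()].
#' @param dir output directory (created if absent).
#' @return `dir` invisibly (`write_scene`); a scene-like list (`read_scene`).
#' @export
write_scene <- function(scene, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory ", dir, call. = FALSE)
  }
  for (st in names(scene$stages)) {
    write_stack_tiff(scene$stages[[st]]$stack,
                     file.path(dir, paste0("stage_", st, "_dn.tif")))
    write_mask_tiff(scene$stages[[st]]$true_mask,
                    scene$stages[[st]]$stack$transform,
                    file.path(dir, paste0("stage_", st, "_truemask.tif")))
  }
  write_layout_geojson(scene$layout, file.path(dir, "layout.geojson"))
  write_panels_geojson(scene$panels, file.path(dir, "panels.geojson"))
  utils::write.csv(panel_reflectance_table(scene$panels),
                   file.path(dir, "panel_reflectance.csv"), row.names = FALSE)
  utils::write.csv(scene$truth$plots, file.path(dir, "truth_plots.csv"),
                   row.names = FALSE)
  utils::write.csv(scene$truth$cover, file.path(dir, "truth_cover.csv"),
                   row.names = FALSE)
  utils::write.csv(scene$truth$canopy_reflectance,
                   file.path(dir, "truth_canopy_reflectance.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(stages = names(scene$stages),
         elm_true_slopes = as.list(scene$config$elm_true_slopes)),
    file.path(dir, "scene_meta.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' @rdname write_scene
#' @export
read_scene <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "scene_meta.json"),
                              simplifyVector = TRUE)
  stages <- lapply(meta$stages, function(st) {
    list(
      stack = read_stack_tiff(file.path(dir, paste0("stage_", st, "_dn.tif"))),
      true_mask = read_mask_tiff(file.path(dir, paste0("stage_", st, "_truemask.tif"))),
      stage = st
    )
  })
  names(stages) <- meta$stages
  list(
    layout = read_layout_geojson(file.path(dir, "layout.geojson")),
    panels = read_panels_geojson(file.path(dir, "panels.geojson")),
    truth = list(
      plots = tibble::as_tibble(
        utils::read.csv(file.path(dir, "truth_plots.csv"))),
      cover = tibble::as_tibble(
        utils::read.csv(file.path(dir, "truth_cover.csv"))),
      canopy_reflectance = tibble::as_tibble(
        utils::read.csv(file.path(dir, "truth_canopy_reflectance.csv"))),
      elm_true_slopes = unlist(meta$elm_true_slopes)
    ),
    stages = stages
  )
}
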