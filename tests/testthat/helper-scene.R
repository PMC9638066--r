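# Shared fixtures. Desk-scale scenes use a coarser ground sample distance
# than the 1.5 cm default; every protocol count (36 plots, 1944 VI records,
# 24/12 splits) is GSD-invariant.

coarse_config <- function(seed = 1L, gsd = 0.06, ...) {
  scene_config(gsd = gsd, seed = seed, ...)
}

# one-plot config rendering a single stage: cheap scenes for Monte-Carlo
# loops over the panel calibration
panel_only_config <- function(seed = 1L, ...) {
  scene_config(
    n_levels = 100, n_varieties = 1, n_replicates = 1,
    variety_effects = 0, stages = "LF", gsd = 0.05, seed = seed, ...
  )
}

band_cols <- c("blue", "green", "red", "rededge", "nir")

panel_refl_matrix <- function(panels) {
  do.call(rbind, lapply(panels$reflectance, function(r) r[band_cols]))
}

calibrate_stage <- function(scene, stage) {
  rend <- scene$stages[[stage]]
  coeffs <- fit_elm(extract_panel_dn(rend$stack, scene$panels)[, band_cols],
                    panel_refl_matrix(scene$panels))
  apply_elm(rend$stack, coeffs)
}

# memoised default coarse scene plus its calibrated stacks and Otsu masks,
# shared across test files
.shared <- new.env(parent = emptyenv())

shared_scene <- function() {
  if (is.null(.shared$scene)) {
    .shared$scene <- simulate_scene(coarse_config(seed = 42L))
  }
  .shared$scene
}

shared_calibrated <- function() {
  if (is.null(.shared$calibrated)) {
    scene <- shared_scene()
    stacks <- lapply(names(scene$stages), function(st) calibrate_stage(scene, st))
    names(stacks) <- names(scene$stages)
    masks <- lapply(stacks, function(s) {
      segment_soil(vari_raster(s), transform = s$transform)
    })
    .shared$calibrated <- list(stacks = stacks, masks = masks)
  }
  .shared$calibrated
}

shared_vi_table <- function() {
  if (is.null(.shared$vi)) {
    cal <- shared_calibrated()
    .shared$vi <- build_vi_table(cal$stacks, shared_scene()$layout, cal$masks)
  }
  .shared$vi
}

shared_traits <- function() {
  if (is.null(.shared$traits)) {
    scene <- shared_scene()
    .shared$traits <- build_trait_table(
      scene$truth$plots[, c("plot_id", "yield_kg_ha")], scene$layout
    )
  }
  .shared$traits
}

# uniform small stack helper for algebraic unit tests: constant reflectance
# per band over an nr x nc grid
flat_stack <- function(refl, nr = 4, nc = 4, units = "reflectance", px = 0.1) {
  vals <- array(0, c(nr, nc, 5))
  for (k in 1:5) vals[, , k] <- refl[k]
  band_stack(vals, units = units, transform = list(x0 = 0, y0 = nr * px, px = px))
}
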