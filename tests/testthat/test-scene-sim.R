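test_that("trial design has the right plot count, areas and grouping", {
  layout <- build_design(scene_config())
  expect_equal(nrow(layout), 36)
  areas <- vapply(layout$geometry, function(p) {
    diff(range(p[, 1])) * diff(range(p[, 2]))
  }, numeric(1))
  expect_equal(areas, rep(16, 36))

  # degenerate single-plot grid
  one <- build_design(scene_config(n_levels = 0, n_varieties = 1,
                                   n_replicates = 1, variety_effects = 0))
  expect_equal(nrow(one), 1)

  # 2 levels x 3 varieties x 3 reps
  l2 <- build_design(scene_config(n_levels = c(0, 200)))
  expect_equal(nrow(l2), 18)
  expect_equal(as.integer(table(l2$n_level)), c(9L, 9L))
  expect_error(scene_config(plot_width = -1), "non-positive")
})

test_that("plot polygons are pairwise disjoint rectangles on a grid", {
  layout <- build_design(scene_config())
  boxes <- t(vapply(layout$geometry, function(p) {
    c(range(p[, 1]), range(p[, 2]))
  }, numeric(4)))
  for (i in 1:(nrow(boxes) - 1)) {
    for (j in (i + 1):nrow(boxes)) {
      overlap_x <- boxes[i, 1] < boxes[j, 2] && boxes[j, 1] < boxes[i, 2]
      overlap_y <- boxes[i, 3] < boxes[j, 4] && boxes[j, 3] < boxes[i, 4]
      if (overlap_x && overlap_y) fail(sprintf("plots %d and %d overlap", i, j))
    }
  }
  succeed()
})

test_that("ground truth follows the vigor model and is reproducible", {
  cfg <- scene_config(yield_noise_sd = 0)
  layout <- build_design(cfg)
  truth <- simulate_ground_truth(layout, cfg, seed = 5)
  # zero-noise limit: yield exactly linear in vigor
  expect_equal(truth$plots$yield_kg_ha,
               pmax(0, cfg$yield_intercept + cfg$yield_slope * truth$plots$vigor))

  # determinism
  truth2 <- simulate_ground_truth(layout, cfg, seed = 5)
  expect_identical(truth, truth2)

  expect_error(scene_config(yield_noise_sd = -1), "non-negative")
  expect_true(all(truth$plots$yield_kg_ha >= 0))
})

test_that("mean yield increases from N0 to the top N rate", {
  cfg <- scene_config()
  layout <- build_design(cfg)
  draws <- vapply(1:40, function(s) {
    tr <- simulate_ground_truth(layout, cfg, seed = s)$plots
    mean(tr$yield_kg_ha[tr$n_level == 300]) -
      mean(tr$yield_kg_ha[tr$n_level == 0])
  }, numeric(1))
  expect_gt(mean(draws), 0)
  expect_gt(mean(draws > 0), 0.95)
})

test_that("rendering follows the linear soil/canopy mixture and ELM inversion", {
  # mixture endpoint: zero cover everywhere -> soil spectrum (no noise)
  cfg <- panel_only_config(
    seed = 2, cover_stage_base = c(LF = -50), cover_noise_sd = 0,
    refl_noise_sd = 0, dn_noise_sd = 0, dn_round = FALSE
  )
  sc <- simulate_scene(cfg)
  stack <- sc$stages$LF$stack
  refl_red <- get_band(stack, "red") * cfg$elm_true_slopes["red"]
  plot_px <- polygon_pixel_mask(stack$transform, nrow(refl_red),
                                ncol(refl_red), sc$layout$geometry[[1]])
  expect_equal(unname(refl_red[plot_px]),
               rep(unname(cfg$soil_spectrum["red"]), sum(plot_px)),
               tolerance = 1e-12)
  expect_false(any(sc$stages$LF$true_mask))

  # hand-checked mixture weight at cover 0.4: 0.4*0.05 + 0.6*0.30 = 0.20
  expect_equal(0.4 * 0.05 + 0.6 * 0.30, 0.20)
  cfg2 <- panel_only_config(
    seed = 2, cover_noise_sd = 0, refl_noise_sd = 0, dn_noise_sd = 0,
    dn_round = FALSE,
    # logistic cover hits exactly 0.4 at this plot's expected vigor when
    # base = logit(0.4) - slope * (vigor - center)
    vigor_noise_sd = 0,
    soil_spectrum = c(blue = 0.10, green = 0.18, red = 0.30,
                      rededge = 0.26, nir = 0.30),
    canopy_base = c(blue = 0.04, green = 0.14, red = 0.05,
                    rededge = 0.22, nir = 0.35),
    canopy_slope = c(blue = 0, green = 0, red = 0, rededge = 0, nir = 0)
  )
  vig <- 1 + cfg2$vigor_max_gain * 100 / (100 + cfg2$vigor_half_sat)
  cfg2$cover_stage_base["LF"] <-
    stats::qlogis(0.4) - cfg2$cover_vigor_slope * (vig - cfg2$cover_vigor_center)
  sc2 <- simulate_scene(cfg2)
  red2 <- get_band(sc2$stages$LF$stack, "red") * cfg2$elm_true_slopes["red"]
  px2 <- polygon_pixel_mask(sc2$stages$LF$stack$transform, nrow(red2),
                            ncol(red2), sc2$layout$geometry[[1]])
  expect_equal(mean(red2[px2]), 0.20, tolerance = 1e-9)
})

test_that("panels render at known reflectance with exact DN inversion", {
  cfg <- panel_only_config(seed = 3, dn_noise_sd = 0, refl_noise_sd = 0,
                           dn_round = FALSE,
                           elm_true_slopes = c(blue = 2.5e-4, green = 2.5e-4,
                                               red = 2.5e-4, rededge = 2.5e-4,
                                               nir = 2.5e-4),
                           panel_reflectances = 0.5)
  sc <- simulate_scene(cfg)
  stack <- sc$stages$LF$stack
  sel <- polygon_pixel_mask(stack$transform, dim(stack)[1], dim(stack)[2],
                            sc$panels$geometry[[1]])
  # reflectance 0.5 with a = 0.00025 -> DN 2000
  expect_equal(unname(get_band(stack, "nir")[sel]), rep(2000, sum(sel)))
  expect_error(render_scene(sc$truth, "nosuch", cfg), "unknown stage")
})

test_that("rendered values stay in physical range and seeds reproduce bits", {
  scene <- shared_scene()
  for (st in c("J", "LGF")) {
    dn <- scene$stages[[st]]$stack$values
    expect_true(all(dn >= 0 & dn <= 65535))
    expect_true(all(dn == round(dn)))
  }
  cfg <- scene$config
  r1 <- render_scene(scene$truth, "H", cfg, seed = 77)
  r2 <- render_scene(scene$truth, "H", cfg, seed = 77)
  expect_identical(r1$stack$values, r2$stack$values)
  expect_identical(r1$true_mask, r2$true_mask)
})

test_that("scene files round-trip losslessly", {
  dir <- withr::local_tempdir()
  cfg <- coarse_config(seed = 9, gsd = 0.1, stages = c("J", "LF"),
                       cover_stage_base = c(J = -0.8, LF = 1.8))
  scene <- simulate_scene(cfg)
  write_scene(scene, dir)
  back <- read_scene(dir)

  expect_identical(back$stages$LF$stack$values, scene$stages$LF$stack$values)
  expect_identical(back$stages$J$true_mask, scene$stages$J$true_mask)
  expect_equal(nrow(back$layout), 36)
  expect_named(back$layout, c("plot_id", "n_level", "variety", "replicate",
                              "geometry"))
  expect_equal(back$layout$n_level, scene$layout$n_level)

  ptab <- panel_reflectance_table(back$panels)
  expect_equal(nrow(ptab), 4 * 5)
  expect_equal(sort(unique(ptab$reflectance)), c(0.05, 0.20, 0.40, 0.60))
})

test_that("plot-mean NIR reflectance tracks yield across seeded scenes", {
  rs <- vapply(1:20, function(s) {
    sc <- simulate_scene(coarse_config(seed = s, gsd = 0.1))
    refl <- calibrate_stage(sc, "LF")
    nir <- get_band(refl, "nir")
    means <- vapply(seq_len(nrow(sc$layout)), function(i) {
      zonal_mean(nir, sc$layout$geometry[[i]], NULL, refl$transform)$value
    }, numeric(1))
    stats::cor(means, sc$truth$plots$yield_kg_ha)
  }, numeric(1))
  expect_true(all(rs > 0.5))
})
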