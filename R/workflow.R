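#' Configuration of an end-to-end pipeline run
#'
#' @param scene a [scene_config()] (its seed is overridden by `seed`), or a
#'   directory path containing a scene written by [write_scene()].
#' @param mask_threshold `"auto"` (Otsu) or a fixed VARI cutoff.
#' @param indices index names or `"all"`.
#' @param edge_buffer inward plot buffer for zonal extraction, m.
#' @param pairing zero-N pairing rule for [build_trait_table()].
#' @param screening_traits traits to screen.
#' @param model_specs list of [model_spec()]s (may be empty, in which case
#'   the run stops after screening).
#' @param n_repeats evaluation repeats per model.
#' @param seed global seed; fixes the scene, every split and every CV fold.
#' @param out_dir optional directory to persist all intermediate artifacts.
#' @return A `run_config` list.
#' @export
run_config <- function(scene = scene_config(),
                       mask_threshold = "auto",
                       indices = "all",
                       edge_buffer = 0.25,
                       pairing = "replicate",
                       screening_traits = c("yield_kg_ha", "npfp", "anue"),
                       model_specs = list(),
                       n_repeats = 20L,
                       seed = 1L,
                       out_dir = NULL) {
  structure(as.list(environment()), class = "run_config")
}

content_hash <- function(x) {
  if (requireNamespace("digest", quietly = TRUE)) {
    digest::digest(x, algo = "md5")
  } else {
    NA_character_
  }
}

#' Run the full phenotyping pipeline
#'
#' Simulate (or load) the trial scene, then for every growth stage:
#' calibrate DN to reflectance with the empirical line fitted on the
#' scene's reference panels, segment soil by VARI thresholding, and extract
#' masked per-plot vegetation indices. Derive the trait table, screen every
#' (index, stage) cell against each requested trait with a
#' stage-generality ranking, and evaluate every model specification with
#' repeated stratified splits. All stochastic stages derive from the single
#' run seed, so re-running a config reproduces the report.
#'
#' @param config a [run_config()].
#' @return A `run_report` list: `vi_table`, `trait_table`, `elm` (per-stage
#'   coefficients), `masks`, `screens`, `generality`, `evaluations`,
#'   `manifest` (seeds + content hashes of every table).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }

  if (is.character(config$scene)) {
    scene <- read_scene(config$scene)
    scene_seed <- NA_integer_
  } else {
    scfg <- config$scene
    scfg$seed <- config$seed
    scene <- simulate_scene(scfg)
    scene_seed <- config$seed
    if (!is.null(out_dir)) write_scene(scene, file.path(out_dir, "scene"))
  }

  layout <- scene$layout
  panels <- scene$panels
  panel_refl <- do.call(rbind, lapply(panels$reflectance, function(r) r[band_names()]))

  stacks <- list(); masks <- list(); elm <- list()
  for (st in names(scene$stages)) {
    dn_stack <- scene$stages[[st]]$stack
    dn_means <- extract_panel_dn(dn_stack, panels)
    coeffs <- fit_elm(dn_means[, band_names()], panel_refl)
    refl <- apply_elm(dn_stack, coeffs)
    vari <- vari_raster(refl)
    masks[[st]] <- segment_soil(vari, config$mask_threshold,
                                transform = refl$transform)
    stacks[[st]] <- refl
    elm[[st]] <- coeffs
  }

  vi_table <- build_vi_table(stacks, layout, masks,
                             indices = config$indices,
                             edge_buffer = config$edge_buffer)

  trait_table <- build_trait_table(
    dplyr::select(scene$truth$plots, "plot_id", "yield_kg_ha"),
    layout, pairing = config$pairing
  )

  screens <- list(); generality <- list()
  for (tr in config$screening_traits) {
    screens[[tr]] <- correlation_screen(vi_table, trait_table, tr)
    generality[[tr]] <- generality_score(screens[[tr]])
  }

  evaluations <- lapply(config$model_specs, function(sp) {
    repeated_evaluation(sp, vi_table, trait_table,
                        n_repeats = config$n_repeats,
                        base_seed = config$seed + 1000L)
  })

  manifest <- list(
    seed = config$seed,
    scene_seed = scene_seed,
    model_base_seed = config$seed + 1000L,
    hashes = list(
      vi_table = content_hash(vi_table),
      trait_table = content_hash(trait_table),
      screens = content_hash(lapply(screens, tibble::as_tibble)),
      evaluations = content_hash(lapply(evaluations, function(e) e$per_repeat))
    )
  )

  if (!is.null(out_dir)) {
    utils::write.csv(vi_table, file.path(out_dir, "vi_table.csv"),
                     row.names = FALSE)
    utils::write.csv(trait_table, file.path(out_dir, "trait_table.csv"),
                     row.names = FALSE)
    for (tr in names(screens)) {
      utils::write.csv(tibble::as_tibble(unclass(screens[[tr]])),
                       file.path(out_dir, paste0("screen_", tr, ".csv")),
                       row.names = FALSE)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  structure(
    list(vi_table = vi_table, trait_table = trait_table, elm = elm,
         masks = masks, screens = screens, generality = generality,
         evaluations = evaluations, manifest = manifest,
         layout = layout),
    class = "run_report"
  )
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat("  plots:", nrow(x$layout), " VI records:", nrow(x$vi_table), "\n")
  cat("  screened traits:", paste(names(x$screens), collapse = ", "), "\n")
  cat("  models evaluated:", length(x$evaluations), "\n")
  invisible(x)
}
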