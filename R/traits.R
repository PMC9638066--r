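#' Convert a sampled grain mass to kg/ha
#'
#' Plot yields are measured by harvesting a small sampled area and weighing
#' the sun-dried grain; `(mass_g / area_m2)` g/m2 scales to kg/ha by the
#' factor 10.
#'
#' @param sample_mass_g grain mass of the sample, grams (>= 0).
#' @param sample_area_m2 harvested area, square metres (> 0).
#' @return Yield in kg/ha.
#' @export
yield_to_kg_ha <- function(sample_mass_g, sample_area_m2) {
  if (any(sample_area_m2 <= 0)) stop("sample area must be positive", call. = FALSE)
  if (any(sample_mass_g < 0)) stop("sample mass must be non-negative", call. = FALSE)
  (sample_mass_g / sample_area_m2) * 10
}

#' N partial factor productivity
#'
#' `NPFP = GY / Ni`: grain yield per kilogram of N fertilizer applied.
#' Undefined at the zero-N control.
#'
#' @param gy grain yield, kg/ha (>= 0).
#' @param ni N rate, kg N/ha (> 0).
#' @return NPFP in kg yield / kg N.
#' @export
compute_npfp <- function(gy, ni) {
  if (any(ni <= 0)) {
    stop("NPFP is undefined for the zero-N control (Ni must be > 0)",
         call. = FALSE)
  }
  if (any(gy < 0)) stop("yield must be non-negative", call. = FALSE)
  gy / ni
}

#' Agronomical N use efficiency
#'
#' `aNUE = (GY - GY_N0) / Ni`: the yield gain over the unfertilized control
#' per kilogram of N applied. May be negative when a fertilized plot yields
#' below its control. Undefined at the zero-N control.
#'
#' @param gy grain yield of the fertilized plot, kg/ha.
#' @param gy_n0 grain yield of the paired zero-N plot, kg/ha.
#' @param ni N rate, kg N/ha (> 0).
#' @return aNUE in kg yield / kg N.
#' @export
compute_anue <- function(gy, gy_n0, ni) {
  if (any(ni <= 0)) {
    stop("aNUE is undefined for the zero-N control (Ni must be > 0)",
         call. = FALSE)
  }
  (gy - gy_n0) / ni
}

#' Build the per-plot trait table
#'
#' Joins plot yields onto the trial layout and derives NPFP and aNUE for
#' every fertilized plot. The zero-N reference yield `GY_N0` is resolved
#' per plot by the pairing rule: `"replicate"` (default) uses the N0 plot
#' of the same variety and replicate; `"variety-mean"` uses the mean N0
#' yield of the same variety. Control (N0) plots keep `NA` traits.
#'
#' @param yields tibble with `plot_id` and `yield_kg_ha`.
#' @param layout plot-layout tibble (`plot_id`, `n_level`, `variety`,
#'   `replicate`).
#' @param pairing `"replicate"` or `"variety-mean"`.
#' @return Tibble: `plot_id`, `n_level`, `variety`, `replicate`,
#'   `yield_kg_ha`, `npfp`, `anue`, `paired_n0_plot_id` (`NA` for the
#'   variety-mean rule and for N0 rows).
#' @export
build_trait_table <- function(yields, layout, pairing = c("replicate", "variety-mean")) {
  pairing <- match.arg(pairing)
  tab <- dplyr::left_join(
    dplyr::select(layout, "plot_id", "n_level", "variety", "replicate"),
    dplyr::select(yields, "plot_id", "yield_kg_ha"),
    by = "plot_id"
  )
  if (any(is.na(tab$yield_kg_ha))) {
    stop("missing yield for plots: ",
         paste(tab$plot_id[is.na(tab$yield_kg_ha)], collapse = ", "),
         call. = FALSE)
  }
  n0 <- dplyr::filter(tab, .data$n_level == 0)
  if (pairing == "replicate") {
    ref <- dplyr::select(n0, "variety", "replicate",
                         paired_n0_plot_id = "plot_id", gy_n0 = "yield_kg_ha")
    tab <- dplyr::left_join(tab, ref, by = c("variety", "replicate"))
  } else {
    ref <- dplyr::summarise(dplyr::group_by(n0, .data$variety),
                            gy_n0 = mean(.data$yield_kg_ha), .groups = "drop")
    tab <- dplyr::left_join(tab, ref, by = "variety")
    tab$paired_n0_plot_id <- NA_character_
  }
  fert <- tab$n_level > 0
  if (any(fert & is.na(tab$gy_n0))) {
    stop("no zero-N pair found for plots: ",
         paste(tab$plot_id[fert & is.na(tab$gy_n0)], collapse = ", "),
         call. = FALSE)
  }
  tab$npfp <- ifelse(fert, tab$yield_kg_ha / tab$n_level, NA_real_)
  tab$anue <- ifelse(fert, (tab$yield_kg_ha - tab$gy_n0) / tab$n_level, NA_real_)
  tab$paired_n0_plot_id[!fert] <- NA_character_
  dplyr::select(tab, "plot_id", "n_level", "variety", "replicate",
                "yield_kg_ha", "npfp", "anue", "paired_n0_plot_id")
}
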