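#' Mean panel digital numbers
#'
#' Averages raw DN over the central `inner_side x inner_side` square of each
#' reference panel (centred on the panel polygon's bounding-box centre), to
#' avoid panel boundary effects. Pixels qualify by the pixel-centre rule.
#'
#' @param stack a [band_stack()] in DN units.
#' @param panels panel tibble (`panel_id`, `geometry`, `reflectance`).
#' @param inner_side side of the central extraction square, m (default 0.2).
#' @return Tibble: `panel_id`, one column per band with the mean DN, and
#'   `n_pixels`.
#' @export
extract_panel_dn <- function(stack, panels, inner_side = 0.2) {
  stopifnot(inherits(stack, "band_stack"))
  if (stack$units != "DN") stop("stack must be in DN units", call. = FALSE)
  d <- dim(stack$values)
  purrr::map_dfr(seq_len(nrow(panels)), function(i) {
    poly <- panels$geometry[[i]]
    xs <- range(poly[, 1]); ys <- range(poly[, 2])
    if (diff(xs) < inner_side || diff(ys) < inner_side) {
      stop("panel ", panels$panel_id[i], " is smaller than the ",
           inner_side, " m extraction square", call. = FALSE)
    }
    cx <- mean(xs); cy <- mean(ys)
    inner <- rectangle_ring(cx - inner_side / 2, cy - inner_side / 2,
                            cx + inner_side / 2, cy + inner_side / 2)
    sel <- polygon_pixel_mask(stack$transform, d[1], d[2], inner)
    if (!any(sel)) {
      stop("no pixel centres inside the inner square of panel ",
           panels$panel_id[i], call. = FALSE)
    }
    means <- vapply(band_names(),
                    function(b) mean(stack$values[, , b][sel], na.rm = TRUE),
                    numeric(1))
    tibble::tibble(panel_id = panels$panel_id[i], !!!as.list(means),
                   n_pixels = sum(sel))
  })
}

#' Fit empirical line calibration coefficients
#'
#' Zero-intercept per-band least squares relating panel DN to known panel
#' reflectance: `a_i = argmin sum_j (R_j - a * DN_j)^2`, with the closed
#' form `a = sum(R * DN) / sum(DN^2)`. One slope per band; no offset term.
#'
#' @param panel_dn matrix or data frame of panel mean DN, panels in rows,
#'   the five bands in columns (e.g. from [extract_panel_dn()]).
#' @param panel_refl matrix/data frame of known reflectances, same shape.
#' @return An `elm_coefficients` object: `slope` (named per band),
#'   `residual_rms` (per band, over panels), `n_panels`.
#' @export
fit_elm <- function(panel_dn, panel_refl) {
  dn <- as.matrix(as.data.frame(panel_dn)[, band_names(), drop = FALSE])
  rf <- as.matrix(as.data.frame(panel_refl)[, band_names(), drop = FALSE])
  if (nrow(dn) < 1) stop("need at least one panel", call. = FALSE)
  if (!all(dim(dn) == dim(rf))) stop("DN/reflectance shape mismatch", call. = FALSE)
  slope <- colSums(rf * dn) / colSums(dn^2)
  if (any(!is.finite(slope))) {
    stop("degenerate ELM fit: all-zero DN in at least one band", call. = FALSE)
  }
  resid <- rf - sweep(dn, 2, slope, `*`)
  structure(
    list(
      slope = stats::setNames(slope, band_names()),
      residual_rms = stats::setNames(sqrt(colMeans(resid^2)), band_names()),
      n_panels = nrow(dn)
    ),
    class = "elm_coefficients"
  )
}

#' @export
print.elm_coefficients <- function(x, ...) {
  cat("<elm_coefficients> fitted on", x$n_panels, "panels\n")
  print(tibble::tibble(band = band_names(), slope = unname(x$slope),
                       residual_rms = unname(x$residual_rms)))
  invisible(x)
}

#' @method tidy elm_coefficients
#' @export
tidy.elm_coefficients <- function(x, ...) {
  tibble::tibble(band = band_names(), slope = unname(x$slope),
                 residual_rms = unname(x$residual_rms),
                 n_panels = x$n_panels)
}

#' Apply empirical line calibration
#'
#' Converts a DN stack to surface reflectance, band by band:
#' `R = DN * a_i`. Values above `clip_max` (noisy bright targets) are
#' clipped, with the per-band clip count recorded in the
#' `"clipped"` attribute; `NA` propagates.
#'
#' @param stack a [band_stack()] in DN units.
#' @param coeffs an [fit_elm()] result.
#' @param clip_max reflectance ceiling (default 1).
#' @return A reflectance [band_stack()].
#' @export
apply_elm <- function(stack, coeffs, clip_max = 1.0) {
  stopifnot(inherits(stack, "band_stack"), inherits(coeffs, "elm_coefficients"))
  if (stack$units == "reflectance") {
    stop("stack is already in reflectance units", call. = FALSE)
  }
  vals <- stack$values
  clipped <- integer(5)
  for (k in seq_along(band_names())) {
    r <- vals[, , k] * coeffs$slope[band_names()[k]]
    clipped[k] <- sum(r > clip_max, na.rm = TRUE)
    vals[, , k] <- pmin(r, clip_max)
  }
  out <- band_stack(vals, units = "reflectance", transform = stack$transform)
  attr(out, "clipped") <- stats::setNames(clipped, band_names())
  out
}

#' Mean absolute percent error between two measurement vectors
#'
#' `PE = 100 * mean(|measured - reference| / |reference|)`. Used to compare
#' camera-derived band reflectance or index values against an independent
#' reference (e.g. a field spectrometer).
#'
#' @param measured,reference equal-length numeric vectors; `reference` must
#'   be nonzero everywhere.
#' @return Percent error (scalar, in percent).
#' @export
percent_error <- function(measured, reference) {
  if (length(measured) != length(reference)) {
    stop("length mismatch", call. = FALSE)
  }
  if (any(reference == 0)) {
    stop("reference contains zero entries", call. = FALSE)
  }
  100 * mean(abs(measured - reference) / abs(reference))
}
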