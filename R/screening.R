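#' Pearson correlation with a two-sided t-test
#'
#' Sample Pearson r and the two-sided p-value from the t distribution with
#' n - 2 degrees of freedom (via [stats::cor.test()]).
#'
#' @param x,y equal-length numeric vectors, n >= 3, non-constant.
#' @return List: `r`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 paired observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Stage-by-stage correlation screen of vegetation indices against a trait
#'
#' Correlates every (index, stage) cell of the vegetation-index table with
#' the chosen per-plot trait. For the NUE traits (`npfp`, `anue`) only
#' fertilized plots enter (the traits are undefined at N0). Cells with
#' fewer than 3 usable plots are flagged `insufficient` rather than failing
#' the screen.
#'
#' @param vi vegetation-index table from [build_vi_table()].
#' @param traits trait table from [build_trait_table()].
#' @param trait one of `"yield_kg_ha"`, `"npfp"`, `"anue"`.
#' @return A `screening_result`: tibble of `index`, `stage`, `r`, `p`, `n`,
#'   `significance` (`"NS"`, `"*"` p<0.05, `"**"` p<0.01) with the trait
#'   name attached; supports [generics::tidy()] and [ggplot2::autoplot()].
#' @export
correlation_screen <- function(vi, traits, trait = c("yield_kg_ha", "npfp", "anue")) {
  trait <- match.arg(trait)
  dat <- dplyr::inner_join(vi, traits[, c("plot_id", trait)], by = "plot_id")
  dat <- dat[!is.na(dat[[trait]]), ]
  stage_order <- unique(vi$stage)
  cells <- purrr::map_dfr(
    split(dat, interaction(dat$index, dat$stage, drop = TRUE)),
    function(cell) {
      base <- tibble::tibble(index = cell$index[1], stage = cell$stage[1])
      res <- tryCatch(pearson_r(cell$value, cell[[trait]]),
                      error = function(e) NULL)
      if (is.null(res)) {
        dplyr::mutate(base, r = NA_real_, p = NA_real_, n = nrow(cell),
                      insufficient = TRUE)
      } else {
        dplyr::mutate(base, r = res$r, p = res$p, n = res$n,
                      insufficient = FALSE)
      }
    }
  )
  cells <- dplyr::mutate(
    cells,
    stage = factor(.data$stage, levels = stage_order),
    significance = dplyr::case_when(
      is.na(.data$p) ~ NA_character_,
      .data$p < 0.01 ~ "**",
      .data$p < 0.05 ~ "*",
      TRUE ~ "NS"
    )
  )
  cells <- dplyr::arrange(cells, .data$index, .data$stage)
  structure(cells, class = c("screening_result", class(cells)), trait = trait)
}

#' @method tidy screening_result
#' @export
tidy.screening_result <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' Stage-generality score of vegetation indices
#'
#' A weighted mean/maximum rank-sum: at each stage the indices are ranked by
#' decreasing `|r|` (rank 1 = strongest association, ties averaged), and
#' each index is scored `w * mean(rank over stages) +
#' (1 - w) * max(rank over stages)`. Lower scores mark indices that are both
#' strong on average and never weak at any stage — i.e. robust to
#' acquisition date. The absolute value makes the score blind to the sign
#' of the association (ratio-type indices correlate negatively by
#' construction).
#'
#' @param screen a `screening_result` from [correlation_screen()].
#' @param weight mean-vs-worst weight `w` in `[0, 1]` (default 0.5;
#'   `w = 1` is pure mean-rank ordering).
#' @return Tibble: `index`, `mean_rank`, `max_rank`, `score`, `rank`
#'   (1 = most stage-general), sorted by score.
#' @export
generality_score <- function(screen, weight = 0.5) {
  if (weight < 0 || weight > 1) {
    stop("weight must lie in [0, 1]", call. = FALSE)
  }
  dat <- tibble::as_tibble(unclass(screen))
  dat <- dat[!is.na(dat$r), ]
  if (length(unique(dat$index)) < 2 || length(unique(dat$stage)) < 1) {
    stop("generality score needs >= 2 indices and >= 1 stage", call. = FALSE)
  }
  ranked <- dplyr::mutate(
    dplyr::group_by(dat, .data$stage),
    stage_rank = rank(-abs(.data$r), ties.method = "average")
  )
  out <- dplyr::summarise(
    dplyr::group_by(ranked, .data$index),
    mean_rank = mean(.data$stage_rank),
    max_rank = max(.data$stage_rank),
    .groups = "drop"
  )
  out <- dplyr::mutate(out,
                       score = weight * .data$mean_rank +
                         (1 - weight) * .data$max_rank)
  out <- dplyr::arrange(out, .data$score, .data$index)
  dplyr::mutate(out, rank = rank(.data$score, ties.method = "average"))
}

#' Heatmap of a correlation screen
#'
#' Index-by-stage heatmap of Pearson r with significance annotation
#' (`*` p < 0.05, `**` p < 0.01, `NS` otherwise).
#'
#' @param object a `screening_result`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot screening_result
#' @export
autoplot.screening_result <- function(object, ...) {
  dat <- tibble::as_tibble(unclass(object))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$stage, y = .data$index,
                                    fill = .data$r)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::geom_text(
      ggplot2::aes(label = ifelse(is.na(.data$r), "",
                                  sprintf("%.2f%s", .data$r,
                                          ifelse(.data$significance == "NS",
                                                 "", .data$significance)))),
      size = 2.8
    ) +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", limits = c(-1, 1)) +
    ggplot2::labs(
      title = paste("Correlation screen:", attr(object, "trait")),
      x = "growth stage", y = NULL, fill = "Pearson r"
    ) +
    ggplot2::theme_minimal()
}
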