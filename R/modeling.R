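#' N-stratified train/test split
#'
#' Within each stratum (N level), `round(train_fraction * size)` plots
#' (half-up rounding, so 2/3 of 9 is exactly 6) are sampled without
#' replacement into the training set; the rest form the test set.
#'
#' @param plot_ids vector of plot identifiers.
#' @param strata stratum label per plot (same length).
#' @param train_fraction fraction in (0, 1), default 2/3.
#' @param seed integer seed; the same seed reproduces the partition.
#' @return List: `train`, `test` (disjoint, union = `plot_ids`).
#' @export
stratified_split <- function(plot_ids, strata, train_fraction = 2 / 3, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must lie in (0, 1)", call. = FALSE)
  }
  if (length(plot_ids) != length(strata)) stop("length mismatch", call. = FALSE)
  sizes <- table(strata)
  if (any(sizes < 2)) {
    stop("every stratum needs at least 2 members; too small: ",
         paste(names(sizes)[sizes < 2], collapse = ", "), call. = FALSE)
  }
  train <- withr::with_seed(seed, {
    unlist(lapply(split(plot_ids, strata), function(ids) {
      k <- floor(train_fraction * length(ids) + 0.5)  # half-up
      k <- max(1L, min(length(ids) - 1L, k))
      sample(ids, k)
    }), use.names = FALSE)
  })
  list(train = train, test = setdiff(plot_ids, train))
}

#' Regression model specification
#'
#' @param family `"lr"` (single-feature linear regression), `"mlr"`
#'   (multiple linear regression), `"smlr"` (bidirectional stepwise AIC
#'   selection), or `"plsr"` (partial least squares).
#' @param features character vector of feature columns
#'   (`"<index>_<stage>"`), or `"all"`.
#' @param trait target trait column (`"yield_kg_ha"`, `"npfp"`, `"anue"`).
#' @param standardize z-score features on the training set and apply those
#'   means/sds to the test set (default TRUE).
#' @param ncomp PLSR component count, or `"cv"` to choose it by seeded
#'   5-fold cross-validation stratified by N level.
#' @return A `model_spec` list.
#' @export
model_spec <- function(family = c("lr", "mlr", "smlr", "plsr"),
                       features = "all",
                       trait = c("yield_kg_ha", "npfp", "anue"),
                       standardize = TRUE,
                       ncomp = "cv") {
  family <- match.arg(family)
  trait <- match.arg(trait)
  if (family == "lr" && (identical(features, "all") || length(features) != 1)) {
    stop("lr uses exactly one feature", call. = FALSE)
  }
  structure(list(family = family, features = features, trait = trait,
                 standardize = standardize, ncomp = ncomp),
            class = "model_spec")
}

## ---- fitters -------------------------------------------------------------

#' Ordinary least squares fit
#'
#' Thin wrapper around [stats::lm()] that rejects rank-deficient designs by
#' naming the aliased columns instead of silently dropping them.
#'
#' @param X data frame / matrix of features (no missing values).
#' @param y numeric response.
#' @param intercept include an intercept (default TRUE).
#' @return A `wv_model` with elements `fit` (the lm), `features`,
#'   `family = "ols"`; supports `predict()`.
#' @export
fit_ols <- function(X, y, intercept = TRUE) {
  X <- as.data.frame(X)
  if (anyNA(X) || anyNA(y)) stop("missing values in model data", call. = FALSE)
  if (nrow(X) <= ncol(X) + 1) {
    stop("need n > p + 1 observations", call. = FALSE)
  }
  dat <- cbind(X, .y = y)
  form <- if (intercept) .y ~ . else .y ~ . + 0
  fit <- stats::lm(form, data = dat)
  co <- stats::coef(fit)
  if (anyNA(co)) {
    stop("collinear feature columns: ",
         paste(names(co)[is.na(co)], collapse = ", "), call. = FALSE)
  }
  structure(list(fit = fit, features = names(X), family = "ols"),
            class = "wv_model")
}

#' Stepwise multiple linear regression (AIC)
#'
#' Bidirectional stepwise selection via [MASS::stepAIC()], starting from
#' the full model: at each step the single add/drop move that most
#' decreases AIC is applied, stopping when no move decreases it.
#' Deterministic given the data.
#'
#' @inheritParams fit_ols
#' @return A `wv_model` with the selected-feature lm and
#'   `features` = selected columns (possibly empty).
#' @export
fit_smlr <- function(X, y) {
  X <- as.data.frame(X)
  if (anyNA(X) || anyNA(y)) stop("missing values in model data", call. = FALSE)
  dat <- cbind(X, .y = y)
  full <- stats::lm(.y ~ ., data = dat)
  step <- MASS::stepAIC(full, direction = "both", trace = 0,
                        scope = list(lower = .y ~ 1, upper = stats::formula(full)))
  selected <- setdiff(names(stats::coef(step)), "(Intercept)")
  structure(list(fit = step, features = selected, family = "smlr"),
            class = "wv_model")
}

#' Partial least squares regression (NIPALS)
#'
#' Univariate-response PLSR: components are extracted sequentially, each
#' X-score direction maximizing covariance with the response in the
#' deflated predictor space (NIPALS); the response is regressed on the
#' scores. With `ncomp = "cv"`, the component count minimizing the mean
#' RMSE over seeded 5-fold cross-validation (folds stratified by
#' `cv_strata`) is used.
#'
#' @inheritParams fit_ols
#' @param ncomp number of latent components (`1..rank(X)`), or `"cv"`.
#' @param cv_strata stratum labels for CV folds (required for `"cv"`).
#' @param cv_seed seed for fold assignment.
#' @param n_folds folds for `"cv"` (default 5).
#' @return A `wv_model` with `coefficients`, `intercept`, `ncomp`,
#'   `cv_rmse` (when selected by CV).
#' @export
fit_plsr <- function(X, y, ncomp = "cv", cv_strata = NULL, cv_seed = 1L,
                     n_folds = 5L) {
  X <- as.matrix(as.data.frame(X))
  if (anyNA(X) || anyNA(y)) stop("missing values in model data", call. = FALSE)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  rk <- qr(Xc)$rank
  cv_rmse <- NULL
  if (identical(ncomp, "cv")) {
    if (is.null(cv_strata)) {
      stop("ncomp = \"cv\" needs cv_strata for stratified folds", call. = FALSE)
    }
    folds <- make_stratified_folds(seq_len(nrow(X)), cv_strata, n_folds, cv_seed)
    max_nc <- min(ncol(X), rk)
    cv_rmse <- vapply(seq_len(max_nc), function(nc) {
      errs <- unlist(lapply(folds, function(idx) {
        fit <- nipals_pls(X[-idx, , drop = FALSE], y[-idx], nc)
        pred <- X[idx, , drop = FALSE] %*% fit$coefficients + fit$intercept
        (y[idx] - pred)^2
      }))
      sqrt(mean(errs))
    }, numeric(1))
    ncomp <- which.min(cv_rmse)
  }
  if (ncomp < 1 || ncomp > rk) {
    stop("ncomp must lie in 1..rank(X) = ", rk, call. = FALSE)
  }
  fit <- nipals_pls(X, y, ncomp)
  structure(c(fit, list(features = colnames(X), family = "plsr",
                        ncomp = ncomp, cv_rmse = cv_rmse)),
            class = "wv_model")
}

## core NIPALS for a single response; X raw (centering done here)
nipals_pls <- function(X, y, ncomp) {
  xm <- colMeans(X); ym <- mean(y)
  E <- sweep(X, 2, xm)
  f <- y - ym
  p <- ncol(X)
  W <- P <- matrix(0, p, ncomp)
  q <- numeric(ncomp)
  for (h in seq_len(ncomp)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { # no covariance left; truncate
      W <- W[, seq_len(h - 1), drop = FALSE]
      P <- P[, seq_len(h - 1), drop = FALSE]
      q <- q[seq_len(h - 1)]
      break
    }
    w <- w / nw
    t_ <- drop(E %*% w)
    tt <- sum(t_^2)
    ph <- drop(crossprod(E, t_)) / tt
    qh <- sum(f * t_) / tt
    E <- E - tcrossprod(t_, ph)
    f <- f - qh * t_
    W[, h] <- w; P[, h] <- ph; q[h] <- qh
  }
  B <- W %*% solve(crossprod(P, W), q)
  list(coefficients = drop(B), intercept = ym - sum(xm * drop(B)))
}

make_stratified_folds <- function(idx, strata, n_folds, seed) {
  assignment <- withr::with_seed(seed, {
    out <- integer(length(idx))
    for (s in unique(strata)) {
      members <- which(strata == s)
      out[members] <- (sample(seq_along(members)) - 1L) %% n_folds + 1L
    }
    out
  })
  lapply(seq_len(n_folds), function(k) idx[assignment == k])
}

#' @export
predict.wv_model <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  if (object$family == "plsr") {
    X <- as.matrix(newdata[, object$features, drop = FALSE])
    drop(X %*% object$coefficients + object$intercept)
  } else {
    unname(stats::predict(object$fit, newdata = newdata))
  }
}

#' @export
print.wv_model <- function(x, ...) {
  cat("<wv_model>", x$family, "with",
      length(x$features), "feature(s)\n")
  invisible(x)
}

## ---- metrics -------------------------------------------------------------

#' Regression evaluation metrics
#'
#' `R2` is the squared sample Pearson correlation between observed and
#' predicted values; `RMSE = sqrt(mean((a - p)^2))`;
#' `MAE = mean(|a - p|)`. When the observed vector is constant, `R2` is
#' undefined and returned as `NA` with a warning (RMSE/MAE still valid).
#'
#' @param y_act observed values (length >= 2).
#' @param y_pred predicted values (same length).
#' @return List: `r2`, `rmse`, `mae`.
#' @export
regression_metrics <- function(y_act, y_pred) {
  if (length(y_act) != length(y_pred)) stop("length mismatch", call. = FALSE)
  if (length(y_act) < 2) stop("need at least 2 observations", call. = FALSE)
  rmse <- sqrt(mean((y_act - y_pred)^2))
  mae <- mean(abs(y_act - y_pred))
  if (stats::sd(y_act) == 0) {
    warning("R2 undefined for constant observations", call. = FALSE)
    r2 <- NA_real_
  } else if (stats::sd(y_pred) == 0) {
    r2 <- 0
  } else {
    r2 <- stats::cor(y_act, y_pred)^2
  }
  list(r2 = r2, rmse = rmse, mae = mae)
}

## ---- repeated evaluation -------------------------------------------------

#' Assemble the wide feature table for modeling
#'
#' Pivots the long vegetation-index table to one row per plot with
#' `<index>_<stage>` feature columns, joined to the trait table.
#'
#' @param vi vegetation-index table from [build_vi_table()].
#' @param traits trait table from [build_trait_table()].
#' @return Wide tibble: `plot_id`, `n_level`, trait columns, features.
#' @export
assemble_model_table <- function(vi, traits) {
  wide <- tidyr::pivot_wider(
    dplyr::mutate(vi, feature = paste(.data$index, .data$stage, sep = "_")),
    id_cols = "plot_id", names_from = "feature", values_from = "value"
  )
  dplyr::inner_join(traits, wide, by = "plot_id")
}

#' Repeated stratified evaluation of a model specification
#'
#' For each of `n_repeats` repeats (repeat k seeded `base_seed + k`): split
#' the plots 2/3 train / 1/3 test stratified by N level, optionally
#' standardize features on the training set, fit the specified model
#' family, and score both sets with [regression_metrics()]. NUE traits
#' automatically restrict to fertilized plots. Identical seeds give
#' identical summaries, and two families evaluated with the same
#' `base_seed` see identical partitions.
#'
#' @param spec a [model_spec()].
#' @param vi vegetation-index table.
#' @param traits trait table.
#' @param n_repeats number of repeats (default 20).
#' @param base_seed integer; repeat k uses seed `base_seed + k`.
#' @param train_fraction passed to [stratified_split()].
#' @return An `evaluation_summary`: per-repeat metrics tibble (`tidy()`),
#'   aggregated means/sds (`glance()`), and the model specification;
#'   `autoplot()` shows
#'   the per-repeat test metrics.
#' @export
repeated_evaluation <- function(spec, vi, traits, n_repeats = 20L,
                                base_seed = 1L, train_fraction = 2 / 3) {
  stopifnot(inherits(spec, "model_spec"))
  dat <- assemble_model_table(vi, traits)
  dat <- dat[!is.na(dat[[spec$trait]]), ]
  feats <- if (identical(spec$features, "all")) {
    setdiff(names(dat), c("plot_id", "n_level", "variety", "replicate",
                          "yield_kg_ha", "npfp", "anue", "paired_n0_plot_id"))
  } else {
    spec$features
  }
  missing_feats <- setdiff(feats, names(dat))
  if (length(missing_feats)) {
    stop("unknown feature columns: ", paste(missing_feats, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(dat[, feats])) {
    stop("missing feature cells; complete the VI table first", call. = FALSE)
  }

  one_repeat <- function(k) {
    seed <- base_seed + k
    split <- stratified_split(dat$plot_id, dat$n_level, train_fraction, seed)
    tr <- dat[dat$plot_id %in% split$train, ]
    te <- dat[dat$plot_id %in% split$test, ]
    Xtr <- as.data.frame(tr[, feats]); Xte <- as.data.frame(te[, feats])
    if (spec$standardize) {
      mu <- vapply(Xtr, mean, numeric(1))
      sdv <- vapply(Xtr, stats::sd, numeric(1))
      sdv[sdv == 0] <- 1
      Xtr <- as.data.frame(scale(Xtr, mu, sdv))
      Xte <- as.data.frame(scale(Xte, mu, sdv))
    }
    ytr <- tr[[spec$trait]]; yte <- te[[spec$trait]]
    model <- switch(
      spec$family,
      lr = ,
      mlr = fit_ols(Xtr, ytr),
      smlr = fit_smlr(Xtr, ytr),
      plsr = fit_plsr(Xtr, ytr, ncomp = spec$ncomp,
                      cv_strata = tr$n_level, cv_seed = seed)
    )
    mtr <- regression_metrics(ytr, predict(model, Xtr))
    mte <- regression_metrics(yte, predict(model, Xte))
    tibble::tibble(
      repeat_id = k, seed = seed,
      n_train = nrow(tr), n_test = nrow(te),
      train_r2 = mtr$r2, train_rmse = mtr$rmse, train_mae = mtr$mae,
      test_r2 = mte$r2, test_rmse = mte$rmse, test_mae = mte$mae,
      n_features = length(model$features),
      error = NA_character_
    )
  }

  per_repeat <- purrr::map_dfr(seq_len(n_repeats), function(k) {
    tryCatch(one_repeat(k), error = function(e) {
      tibble::tibble(repeat_id = k, seed = base_seed + k,
                     n_train = NA_integer_, n_test = NA_integer_,
                     train_r2 = NA_real_, train_rmse = NA_real_,
                     train_mae = NA_real_, test_r2 = NA_real_,
                     test_rmse = NA_real_, test_mae = NA_real_,
                     n_features = NA_integer_,
                     error = conditionMessage(e))
    })
  })
  structure(list(per_repeat = per_repeat, spec = spec,
                 n_repeats = n_repeats, base_seed = base_seed),
            class = "evaluation_summary")
}

#' @export
print.evaluation_summary <- function(x, ...) {
  cat("<evaluation_summary>", x$spec$family, "on", x$spec$trait,
      "-", x$n_repeats, "repeats\n")
  print(glance(x))
  invisible(x)
}

#' @method tidy evaluation_summary
#' @export
tidy.evaluation_summary <- function(x, ...) x$per_repeat

#' @method glance evaluation_summary
#' @export
glance.evaluation_summary <- function(x, ...) {
  ok <- x$per_repeat[is.na(x$per_repeat$error), ]
  metric_cols <- c("train_r2", "train_rmse", "train_mae",
                   "test_r2", "test_rmse", "test_mae")
  out <- tibble::tibble(
    family = x$spec$family, trait = x$spec$trait,
    n_repeats = nrow(ok), n_failed = sum(!is.na(x$per_repeat$error))
  )
  for (m in metric_cols) {
    out[[paste0("mean_", m)]] <- mean(ok[[m]])
    out[[paste0("sd_", m)]] <- stats::sd(ok[[m]])
  }
  out
}

#' @method autoplot evaluation_summary
#' @export
autoplot.evaluation_summary <- function(object, ...) {
  dat <- tidyr::pivot_longer(
    tidy(object)[, c("repeat_id", "test_r2", "test_rmse", "test_mae")],
    cols = -"repeat_id", names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(fill = "grey90") +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.5, size = 1) +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(
      title = sprintf("%s on %s: test metrics over %d repeats",
                      object$spec$family, object$spec$trait,
                      object$n_repeats),
      x = NULL, y = NULL
    ) +
    ggplot2::theme_minimal()
}
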