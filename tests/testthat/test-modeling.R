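# small synthetic feature tables for model tests
sim_xy <- function(n, p, seed, beta = c(3, rep(0, 4)), noise_sd = 0.1) {
  withr::with_seed(seed, {
    X <- matrix(stats::rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("x", seq_len(p))))
    y <- drop(X %*% beta[seq_len(p)]) + stats::rnorm(n, 0, noise_sd)
    list(X = as.data.frame(X), y = y)
  })
}

gaussian_aic <- function(fit) {
  rss <- sum(stats::residuals(fit)^2)
  n <- length(stats::residuals(fit))
  k <- length(stats::coef(fit)) - 1
  n * log(rss / n) + 2 * (k + 1)
}

test_that("stratified splits hit the 2/3 design counts deterministically", {
  ids <- sprintf("P%02d", 1:36)
  strata <- rep(c(0, 100, 200, 300), each = 9)
  s <- stratified_split(ids, strata, seed = 4)
  expect_equal(length(s$train), 24)
  expect_equal(length(s$test), 12)
  per <- table(strata[match(s$train, ids)])
  expect_equal(unname(c(per)), rep(6L, 4))
  expect_setequal(c(s$train, s$test), ids)

  nue <- stratified_split(ids[10:36], strata[10:36], seed = 4)
  expect_equal(length(nue$train), 18)
  expect_equal(length(nue$test), 9)

  expect_identical(stratified_split(ids, strata, seed = 9),
                   stratified_split(ids, strata, seed = 9))
  expect_error(stratified_split(c("a", "b"), c(1, 2)), "at least 2")
  expect_error(stratified_split(ids, strata, train_fraction = 1), "\\(0, 1\\)")
})

test_that("OLS recovers exact linear data and rejects collinearity", {
  d <- sim_xy(30, 3, seed = 1, beta = c(2, -1, 0.5), noise_sd = 0)
  fit <- fit_ols(d$X, d$y)
  expect_equal(unname(stats::coef(fit$fit)[-1]), c(2, -1, 0.5),
               tolerance = 1e-10)
  expect_equal(predict(fit, d$X), d$y, tolerance = 1e-10)

  # closed-form normal equations: x = (0,1,2), y = (1,3,5)
  lin <- fit_ols(data.frame(x = c(0, 1, 2)), c(1, 3, 5))
  expect_equal(unname(stats::coef(lin$fit)), c(1, 2))

  dup <- cbind(d$X, x1b = d$X$x1)
  expect_error(fit_ols(dup, d$y), "collinear.*x1b")
})

test_that("stepwise selection keeps a planted signal and improves AIC", {
  hits <- vapply(1:30, function(s) {
    d <- sim_xy(200, 5, seed = s)
    "x1" %in% fit_smlr(d$X, d$y)$features
  }, logical(1))
  expect_true(all(hits))

  # final AIC never exceeds the full or the empty model's
  for (s in 1:5) {
    d <- sim_xy(40, 5, seed = 100 + s, beta = c(0.4, 0.2, 0, 0, 0),
                noise_sd = 1)
    sel <- fit_smlr(d$X, d$y)
    aic_sel <- gaussian_aic(sel$fit)
    aic_full <- gaussian_aic(stats::lm(d$y ~ ., data = d$X))
    aic_null <- gaussian_aic(stats::lm(d$y ~ 1))
    expect_lte(aic_sel, aic_full + 1e-8)
    expect_lte(aic_sel, aic_null + 1e-8)
  }

  # single candidate with strong signal: same fit as plain OLS
  d1 <- sim_xy(50, 1, seed = 7, beta = 3, noise_sd = 0.1)
  expect_equal(stats::coef(fit_smlr(d1$X, d1$y)$fit),
               stats::coef(fit_ols(d1$X, d1$y)$fit))
})

test_that("PLSR reduces to simple regression and to OLS at full rank", {
  d1 <- sim_xy(40, 1, seed = 2, beta = 2, noise_sd = 0.3)
  pls1 <- fit_plsr(d1$X, d1$y, ncomp = 1)
  ols1 <- fit_ols(d1$X, d1$y)
  expect_equal(predict(pls1, d1$X), predict(ols1, d1$X), tolerance = 1e-8)

  d <- sim_xy(60, 6, seed = 3, beta = c(1, -2, 0.5, 0, 1, 0.2), noise_sd = 0.5)
  pls_full <- fit_plsr(d$X, d$y, ncomp = 6)
  ols <- fit_ols(d$X, d$y)
  expect_equal(predict(pls_full, d$X), predict(ols, d$X), tolerance = 1e-8)

  expect_error(fit_plsr(d$X, d$y, ncomp = 7), "rank")
})

test_that("cross-validation picks few components for one latent direction", {
  small <- vapply(1:100, function(s) {
    withr::with_seed(s, {
      latent <- stats::rnorm(60)
      X <- outer(latent, stats::runif(9, 0.5, 1.5)) +
        matrix(stats::rnorm(60 * 9, 0, 0.3), 60, 9)
      colnames(X) <- paste0("x", 1:9)
      y <- 2 * latent + stats::rnorm(60, 0, 0.3)
      strata <- rep(1:4, length.out = 60)
    })
    fit <- fit_plsr(as.data.frame(X), y, ncomp = "cv", cv_strata = strata,
                    cv_seed = s)
    fit$ncomp <= 3
  }, logical(1))
  expect_gte(mean(small), 0.9)
})

test_that("evaluation metrics match their worked examples", {
  y <- c(1, 2, 3)
  perfect <- regression_metrics(y, y)
  expect_equal(perfect[c("r2", "rmse", "mae")], list(r2 = 1, rmse = 0, mae = 0))

  offset <- regression_metrics(y, y + 2)
  expect_equal(offset$r2, 1)               # correlation-based R2
  expect_equal(offset$rmse, 2)
  expect_equal(offset$mae, 2)

  swapped <- regression_metrics(c(1, 2, 3), c(1, 3, 2))
  expect_equal(swapped$rmse, sqrt(2 / 3))
  expect_equal(swapped$mae, 2 / 3)

  expect_warning(const <- regression_metrics(c(2, 2), c(1, 3)), "undefined")
  expect_true(is.na(const$r2))
  expect_equal(const$rmse, 1)

  # RMSE >= MAE, equality iff all |errors| equal
  set.seed(30)
  for (k in 1:20) {
    a <- stats::rnorm(15); p <- a + stats::rnorm(15)
    m <- regression_metrics(a, p)
    expect_gte(m$rmse, m$mae)
  }
  eq <- suppressWarnings(regression_metrics(c(0, 0, 0), c(1, -1, 1)))
  expect_equal(eq$rmse, eq$mae)
})

test_that("train RMSE never improves when features are removed", {
  d <- sim_xy(50, 5, seed = 11, beta = c(1, 0.5, -0.3, 0.2, 0), noise_sd = 1)
  full <- fit_ols(d$X, d$y)
  sub <- fit_ols(d$X[, 1:2], d$y)
  rmse_full <- regression_metrics(d$y, predict(full, d$X))$rmse
  rmse_sub <- regression_metrics(d$y, predict(sub, d$X[, 1:2]))$rmse
  expect_lte(rmse_full, rmse_sub + 1e-10)
})

test_that("repeated evaluation is seeded, complete and standardization-stable", {
  vi <- shared_vi_table()
  traits <- shared_traits()
  spec <- model_spec("lr", features = "repRVI_LGF", trait = "yield_kg_ha")
  ev <- repeated_evaluation(spec, vi, traits, n_repeats = 6, base_seed = 3)
  expect_equal(nrow(tidy(ev)), 6)
  expect_true(all(is.na(tidy(ev)$error)))
  expect_true(all(tidy(ev)$n_train == 24 & tidy(ev)$n_test == 12))

  ev2 <- repeated_evaluation(spec, vi, traits, n_repeats = 6, base_seed = 3)
  expect_equal(glance(ev), glance(ev2))

  # affine feature transforms leave OLS/PLSR test predictions unchanged
  vi_shift <- vi
  vi_shift$value[vi_shift$index == "repRVI"] <-
    10 * vi_shift$value[vi_shift$index == "repRVI"] + 5
  ev3 <- repeated_evaluation(spec, vi_shift, traits, n_repeats = 6,
                             base_seed = 3)
  expect_equal(tidy(ev)$test_rmse, tidy(ev3)$test_rmse, tolerance = 1e-8)

  pspec <- model_spec("plsr", features = c("repRVI_LGF", "NDVI_LGF",
                                           "MTCI_LGF"),
                      trait = "yield_kg_ha", ncomp = 2)
  pv <- repeated_evaluation(pspec, vi, traits, n_repeats = 4, base_seed = 5)
  pv2 <- repeated_evaluation(pspec, vi_shift, traits, n_repeats = 4,
                             base_seed = 5)
  expect_equal(tidy(pv)$test_rmse, tidy(pv2)$test_rmse, tolerance = 1e-6)

  # noiseless linear target: perfect scores for all four families
  layout <- shared_scene()$layout
  x <- vi$value[vi$index == "repRVI" & vi$stage == "LGF"]
  exact <- tibble::tibble(
    plot_id = vi$plot_id[vi$index == "repRVI" & vi$stage == "LGF"],
    n_level = layout$n_level[match(plot_id, layout$plot_id)],
    variety = "V1", replicate = 1L,
    yield_kg_ha = 9000 - 20000 * x,
    npfp = NA_real_, anue = NA_real_, paired_n0_plot_id = NA_character_
  )
  for (fam in c("lr", "mlr", "smlr", "plsr")) {
    sp <- model_spec(fam,
                     features = if (fam == "lr") "repRVI_LGF" else
                       c("repRVI_LGF", "NDVI_LGF"),
                     trait = "yield_kg_ha",
                     ncomp = if (fam == "plsr") 2 else "cv")
    # stepAIC warns about selecting on an exact fit; expected here
    evx <- suppressWarnings(
      repeated_evaluation(sp, vi, exact, n_repeats = 3, base_seed = 2))
    expect_equal(mean(tidy(evx)$test_r2), 1, tolerance = 1e-6)
    expect_equal(stats::sd(tidy(evx)$test_r2), 0, tolerance = 1e-6)
  }

  # a failing repeat is reported, not fatal
  bad <- traits; bad$npfp <- NA_real_
  sp_bad <- model_spec("lr", features = "repRVI_LGF", trait = "npfp")
  expect_error(repeated_evaluation(sp_bad, vi, bad, n_repeats = 2),
               NA)
})

test_that("model specs validate family-specific constraints", {
  expect_error(model_spec("lr", features = "all"), "exactly one")
  expect_error(model_spec("lr", features = c("a", "b")), "exactly one")
  sp <- model_spec("mlr", trait = "npfp")
  expect_s3_class(sp, "model_spec")
  expect_error(
    repeated_evaluation(model_spec("lr", features = "nosuch",
                                   trait = "yield_kg_ha"),
                        shared_vi_table(), shared_traits(), n_repeats = 2),
    "unknown feature"
  )
})
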