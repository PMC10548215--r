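test_that("stratified split sizes follow the floor-per-stratum rule", {
  mk <- function(n) stratified_split(sprintf("P%03d", 1:n),
                                     rep(c("N1", "N2"), each = n / 2),
                                     seed = 3)
  expect_length(mk(78)$calibration, 62)
  expect_length(mk(88)$calibration, 70)
  expect_length(mk(10)$calibration, 8)
  sp <- mk(88)
  expect_length(intersect(sp$calibration, sp$validation), 0)
  expect_setequal(c(sp$calibration, sp$validation), sprintf("P%03d", 1:88))
  expect_error(stratified_split(c("a", "b"), c("x", "y"), seed = 1),
               "fewer than 2")
})

test_that("one-component PLS on a single predictor equals simple regression", {
  set.seed(6)
  x <- matrix(rnorm(20), 20, 1)
  y <- 2 + 3 * x[, 1] + rnorm(20, 0, 0.2)
  fit <- fit_plsr(x, y, 1)
  ls <- lm(y ~ x)
  expect_equal(predict(fit, x), unname(fitted(ls)), tolerance = 1e-10)
})

test_that("full-component PLS reproduces ordinary least squares", {
  set.seed(7)
  X <- matrix(rnorm(30 * 5), 30, 5)
  y <- drop(X %*% c(1, -2, 0.5, 0, 3)) + rnorm(30, 0, 0.1)
  fit <- fit_plsr(X, y, 5)
  ols <- lm(y ~ X)
  expect_equal(predict(fit, X), unname(fitted(ols)), tolerance = 1e-8)
})

test_that("orthogonal-scores coefficients match the literal transcription", {
  set.seed(8)
  for (dims in list(c(8, 5, 3), c(30, 20, 6))) {
    X <- matrix(rnorm(dims[1] * dims[2]), dims[1], dims[2])
    y <- drop(X %*% rnorm(dims[2])) + rnorm(dims[1], 0, 0.3)
    A <- dims[3]
    fit <- fit_plsr(X, y, A)
    ref <- ref_plsr_coef(X, y, A)
    expect_equal(unname(fit$coefficients[, A]), ref$coef, tolerance = 1e-8)
    expect_equal(unname(fit$intercepts[A]), ref$intercept, tolerance = 1e-8)
  }
})

test_that("PLS scores are mutually orthogonal", {
  set.seed(9)
  X <- matrix(rnorm(25 * 12), 25, 12)
  y <- rnorm(25)
  fit <- fit_plsr(X, y, 6)
  g <- crossprod(fit$scores)
  expect_equal(g - diag(diag(g)), matrix(0, 6, 6), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(fit_plsr(X, rep(1, 25), 2), "zero-variance")
  expect_error(fit_plsr(X, y, 30), "out of range")
})

test_that("LOO component selection finds structure and rejects noise", {
  set.seed(10)
  t_lat <- rnorm(30)
  X <- outer(t_lat, rnorm(8))        # a single latent direction
  y_lin <- 2 * t_lat                 # noiseless response along it
  sel <- select_components_loo(X, y_lin, max_components = 5)
  expect_true(sel$fittable)
  expect_equal(sel$n_components, 1)

  sel1 <- select_components_loo(X, y_lin, max_components = 1)
  expect_equal(sel1$n_components, 1)

  Xn <- matrix(rnorm(30 * 8), 30, 8)
  y_noise <- rnorm(30)               # independent of X
  sel0 <- select_components_loo(Xn, y_noise, max_components = 5)
  expect_false(sel0$fittable)
  expect_equal(sel0$n_components, 0)
})

test_that("jackknife intervals behave like a variance estimate", {
  set.seed(11)
  X <- matrix(rnorm(20 * 4), 20, 4)
  y_exact <- drop(X %*% c(1, 2, -1, 0.5))
  jk <- jackknife_predict(X, y_exact, 4, X[1:5, , drop = FALSE])
  expect_true(all(jk$upper - jk$lower < 1e-6))

  y <- y_exact + rnorm(20, 0, 0.5)
  Xv <- matrix(rnorm(10 * 4), 10, 4)
  jk1 <- jackknife_predict(X, y, 2, Xv)
  jk2 <- jackknife_predict(rbind(X, X), c(y, y), 2, Xv)
  expect_lt(mean(jk2$upper - jk2$lower), mean(jk1$upper - jk1$lower))
})

test_that("jackknife intervals reach near-nominal coverage", {
  set.seed(12)
  cover <- 0; total <- 0
  for (rep in 1:60) {
    X <- matrix(rnorm(30 * 5), 30, 5)
    beta <- rnorm(5)
    y <- drop(X %*% beta) + rnorm(30, 0, 0.5)
    Xv <- matrix(rnorm(8 * 5), 8, 5)
    truth <- drop(Xv %*% beta)
    jk <- jackknife_predict(X, y, 3, Xv)
    # coverage of the noiseless regression surface by the model-uncertainty
    # interval plus residual sd
    s <- sqrt(jk$se^2 + 0.5^2)
    yv <- truth + rnorm(8, 0, 0.5)
    cover <- cover + sum(yv >= jk$prediction - 1.96 * s &
                         yv <= jk$prediction + 1.96 * s)
    total <- total + 8
  }
  expect_gt(cover / total, 0.90)
  expect_lt(cover / total, 0.99)
})

test_that("prediction metrics reproduce their hand-computable cases", {
  m <- evaluate(c(1, 2, 3), c(1, 2, 3))
  expect_equal(m$rmsep, 0)
  expect_equal(m$r2, 1)

  m2 <- evaluate(c(0, 2), c(1, 1))
  expect_equal(m2$rmsep, 1)
  expect_equal(m2$r2, 0)
  expect_equal(m2$pct_rmsep, 50)

  y <- c(1, 2, 3, 6)
  m3 <- evaluate(y, rep(mean(y), 4))
  expect_equal(m3$r2, 0)

  expect_warning(m4 <- evaluate(c(1, 1), c(1, 2)), "constant")
  expect_true(is.na(m4$r2))

  # scale invariance of R2 and %RMSEP; RMSEP scales linearly
  y <- rnorm(20); yh <- y + rnorm(20, 0, 0.3)
  a <- evaluate(y, yh); b <- evaluate(5 * y, 5 * yh)
  expect_equal(a$r2, b$r2)
  expect_equal(a$pct_rmsep, b$pct_rmsep)
  expect_equal(5 * a$rmsep, b$rmsep)
})

test_that("the trait pipeline never leaks validation information", {
  cfg <- synthetic_config()
  ex <- generate_experiment(cfg, seed = 41)
  w <- weekly_average(calibrate_scans(ex$scans))
  run1 <- run_trait_model(w, ex$traits, ex$design, "N",
                          n_wavelengths = 100, jackknife = FALSE, seed = 6)
  # permute the validation responses: selection and coefficients unchanged
  tr2 <- ex$traits
  vid <- match(run1$split$validation, tr2$plant_id)
  tr2$N[vid] <- sample(tr2$N[vid])
  run2 <- run_trait_model(w, tr2, ex$design, "N",
                          n_wavelengths = 100, jackknife = FALSE, seed = 6)
  expect_identical(run1$selection$selected, run2$selection$selected)
  expect_identical(run1$model$coefficients, run2$model$coefficients)
})

test_that("a decoupled response propagates as a not-fittable run", {
  cfg <- tiny_config(weeks = 9L)
  ex <- generate_experiment(cfg, seed = 51)
  w <- weekly_average(calibrate_scans(ex$scans))
  tr <- ex$traits
  set.seed(4)
  tr$junk <- rnorm(nrow(tr))
  run <- run_trait_model(w, tr, ex$design, "junk", n_wavelengths = 20,
                         seed = 8)
  expect_false(run$fittable)
  expect_match(run$diagnosis, "0-component")
})

test_that("transfer calibration refuses a constant trait", {
  cfg <- tiny_config(weeks = 9L)
  ex <- generate_experiment(cfg, seed = 52)
  w <- weekly_average(calibrate_scans(ex$scans))
  tr <- ex$traits
  tr$flat <- ifelse(ex$design$treatment == "N1", 1, rnorm(nrow(tr)))
  expect_error(transfer_experiment(w, tr, ex$design, "flat", "treatment",
                                   "N1", n_wavelengths = 10, seed = 2),
               "constant")
})

test_that("the hyperparameter grid aggregates metrics per cell", {
  cfg <- synthetic_config()
  ex <- generate_experiment(cfg, seed = 61)
  w <- weekly_average(calibrate_scans(ex$scans))
  gr <- hyperparameter_grid(w, ex$traits, ex$design, "N",
                            wavelength_counts = c(50, 200),
                            totals = c(48, 60), iterations = 2, seed = 7)
  expect_equal(nrow(gr), 4)
  expect_true(all(is.finite(gr$se_val_r2[gr$n_fitted == 2])))
  expect_true(all(gr$se_val_rmsep >= 0, na.rm = TRUE))
  expect_error(hyperparameter_grid(w, ex$traits, ex$design, "N",
                                   totals = c(2000), iterations = 1),
               "exceeds")
})
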