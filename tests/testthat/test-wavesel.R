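test_that("covariance PCA of spectra has the stated algebraic properties", {
  set.seed(4)
  # rank-1 data: one component carries everything
  base <- sin(seq(0, pi, length.out = 40))
  vals <- outer(rnorm(12, 5, 2), base)
  ss <- spectra_set(seq(400, 790, by = 10), vals,
                    data.frame(plant_id = sprintf("P%02d", 1:12), week = 6),
                    "plant_week")
  pc <- spectra_pca(ss)
  expect_equal(pc$variance_fraction[1], 1, tolerance = 1e-10)
  expect_equal(sum(pc$variance_fraction), 1, tolerance = 1e-12)
  expect_equal(crossprod(pc$rotation[, 1:5]), diag(5), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_error(spectra_pca(spectra_set(c(500), matrix(1, 1, 1),
                                       data.frame(plant_id = "A", week = 6),
                                       "plant_week")),
               "at least 2")
})

test_that("one PC of synthetic weekly spectra separates treatments", {
  ex <- generate_experiment(synthetic_config(), seed = 13)
  am <- accession_mean(weekly_average(calibrate_scans(ex$scans)), ex$design)
  k <- am$meta$week == 6
  ss <- spectra_set(am$grid, am$values[k, ], am$meta[k, ], am$level)
  pc <- spectra_pca(ss)
  trt <- ss$meta$treatment
  sep <- vapply(1:3, function(j) {
    s <- pc$x[, j]
    abs(mean(s[trt == "N1"]) - mean(s[trt == "N2"])) /
      sqrt(var(s[trt == "N1"]) + var(s[trt == "N2"]))
  }, numeric(1))
  expect_gt(max(sep), 1)
})

test_that("PCA-loading selection keeps top loadings of the retained PCs", {
  # synthetic prcomp-like object: PC1 explains 95% of variance
  rot <- cbind(c(0.1, 0.9, 0.3, 0.05, 0.2), c(0.7, 0.1, 0.1, 0.6, 0.1))
  fake <- list(rotation = rot, variance_fraction = c(0.95, 0.05),
               grid = c(500, 510, 520, 530, 540))
  sel <- select_wsvm(fake, var_threshold = 0.90, top_k = 2)
  expect_equal(sel$selected, c(510, 520))  # two largest |loadings| of PC1
  expect_equal(sel$provenance$n_pc, 1)

  # sign-flip invariance
  fake2 <- fake
  fake2$rotation <- -fake2$rotation
  expect_equal(select_wsvm(fake2, 0.90, 2)$selected, sel$selected)

  # union bound over retained PCs
  fake3 <- list(rotation = rot, variance_fraction = c(0.6, 0.4),
                grid = fake$grid)
  sel3 <- select_wsvm(fake3, var_threshold = 0.90, top_k = 2)
  expect_lte(length(sel3$selected), 2 * 2)
  expect_equal(sel3$provenance$n_pc, 2)
})

test_that("selected treatment wavelengths cover the Red Edge", {
  ex <- generate_experiment(synthetic_config(), seed = 19)
  am <- accession_mean(weekly_average(calibrate_scans(ex$scans)), ex$design)
  k <- am$meta$week == 9
  sel <- select_wsvm(spectra_pca(
    spectra_set(am$grid, am$values[k, ], am$meta[k, ], am$level)))
  expect_true(any(sel$selected >= 700 & sel$selected <= 730))
})

test_that("RReliefF weights match a literal per-iteration transcription", {
  fx <- make_planted_fixture(n = 30, p = 12, informative = c(3, 8),
                             noise_sd = 0.05, seed = 5)
  k <- 10; sigma <- 20; m <- 90
  draws <- with(list(), {set.seed(99); sample.int(30, m, replace = TRUE)})
  ref <- ref_rrelieff(fx$X, fx$y, k, sigma, draws)

  # package implementation with the identical draw sequence
  pkg <- canopyspec:::with_seed(99, sample.int(30, m, replace = TRUE))
  expect_identical(draws, pkg)
  res <- rrelieff_rank(fx$X, fx$y, k_neighbors = k, sigma = sigma,
                       m_iterations = m, seed = 99)
  expect_equal(unname(res$scores), ref, tolerance = 1e-12)
})

test_that("RReliefF scores behave as an attribute relevance measure", {
  fx <- make_planted_fixture(n = 60, p = 30, informative = 7,
                             noise_sd = 0.05, seed = 2)
  X <- fx$X
  X[, 12] <- 4.2  # constant attribute
  X[, 20] <- X[, 7]  # duplicate of the informative column
  res <- rrelieff_rank(X, fx$y, m_iterations = 100 * nrow(X), seed = 3)
  expect_true(all(res$scores >= -1 & res$scores <= 1))
  expect_identical(unname(res$scores[12]), 0)
  expect_equal(unname(res$scores[20]), unname(res$scores[7]),
               tolerance = 1e-12)
  expect_equal(which.max(res$scores), 7, ignore_attr = TRUE)
  expect_error(rrelieff_rank(X, rep(1, nrow(X))), "constant response")
})

test_that("top-n wavelength selection orders by score with wavelength tie-break", {
  sc <- c(`700` = 0.5, `650` = 0.5, `800` = 0.1)
  sel <- select_wplsr(selection_result("rrelieff", sc), 1)
  expect_equal(sel$selected, 650)
  expect_equal(select_wplsr(selection_result("rrelieff", sc), 3)$selected,
               c(650, 700, 800))
  expect_error(select_wplsr(selection_result("rrelieff", sc), 0), "positive")
  expect_error(select_wplsr(selection_result("rrelieff", sc), 4), "exceeds")
  tab <- selection_table(sel)
  expect_equal(tab$rank[tab$wavelength_nm == 650], 1)
  expect_true(tab$selected_flag[tab$wavelength_nm == 650])
})

test_that("planted informative bands rise to the top of the ranking", {
  # ten informative bands among ~600; the ranking should recover most of
  # them within the top 40 under the m = 100n iteration rule
  hits <- vapply(1:5, function(s) {
    fx <- make_planted_fixture(n = 70, p = 600,
                               informative = seq(60, 546, by = 54),
                               noise_sd = 0.3, seed = s)
    res <- rrelieff_rank(fx$X, fx$y, m_iterations = 100 * nrow(fx$X),
                         seed = s + 50)
    top40 <- order(-res$scores)[1:40]
    sum(seq(60, 546, by = 54) %in% top40)
  }, numeric(1))
  expect_true(all(hits >= 8))
})
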