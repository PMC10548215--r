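test_that("design table reproduces the experimental layout", {
  cfg <- synthetic_config()
  d <- make_design(cfg)
  expect_equal(nrow(d), 94)
  expect_equal(length(unique(d$accession)), 23)
  expect_equal(sum(d$subpopulation == "IND"),
               15 * 2 * 2)
  expect_equal(unname(table(d$treatment)), c(47L, 47L), ignore_attr = TRUE)

  tiny <- synthetic_config(n_accessions_ind = 1, n_accessions_trj = 0,
                           reps_per_accession = 1, extra_rep_accessions = 0)
  expect_equal(nrow(make_design(tiny)), 2)

  expect_error(make_design(synthetic_config(reps_per_accession = 0)))
})

test_that("trait missingness leaves 88 complete-nitrogen plants", {
  ex <- generate_experiment(synthetic_config(), seed = 5)
  expect_equal(nrow(ex$traits), 94)
  expect_equal(sum(!is.na(ex$traits$N)), 88)
  expect_equal(sum(is.na(ex$traits$SLA)), 6)
})

test_that("visible reflectance decreases monotonically with chlorophyll", {
  grid <- seq(400, 2500, by = 10)
  lo <- true_reflectance(list(chlorophyll = 1, water = 0, structure = 0), grid)
  hi <- true_reflectance(list(chlorophyll = 2, water = 0, structure = 0), grid)
  vis <- grid %in% seq(640, 670, by = 10)
  expect_true(all(hi[vis] < lo[vis]))
  expect_true(all(hi[grid == 650] < lo[grid == 650]))
  # determinism given the state
  expect_identical(lo, true_reflectance(list(chlorophyll = 1, water = 0,
                                             structure = 0), grid))
  expect_error(true_reflectance(list(chlorophyll = 1, water = 0,
                                     structure = 0), c(350, 700)),
               "supported")
})

test_that("water latent deepens the SWIR troughs and structure lifts the NIR plateau", {
  grid <- seq(400, 2500, by = 5)
  dry <- true_reflectance(list(chlorophyll = 1.5, water = -1, structure = 0), grid)
  wet <- true_reflectance(list(chlorophyll = 1.5, water = 1, structure = 0), grid)
  expect_lt(wet[grid == 1450], dry[grid == 1450])
  expect_lt(wet[grid == 1940], dry[grid == 1940])
  lo <- true_reflectance(list(chlorophyll = 1.5, water = 0, structure = -1), grid)
  hi <- true_reflectance(list(chlorophyll = 1.5, water = 0, structure = 1), grid)
  expect_gt(hi[grid == 850], lo[grid == 850])
})

test_that("reference state spectrum is frozen across runs", {
  grid <- c(450, 550, 650, 715, 850, 1450, 1940, 2400)
  r <- true_reflectance(list(chlorophyll = 1.5, water = 0.2, structure = -0.3),
                        grid)
  expect_equal(r, c(7.1822497, 7.2006183, 5.2352915, 22.9431029,
                    33.4978253, 21.7672963, 18.2700201, 21.9892906),
               tolerance = 1e-6)
})

test_that("noise-free scans round-trip through calibration exactly", {
  grid <- seq(400, 2500, by = 25)
  st <- list(chlorophyll = 1.2, water = 0.5, structure = -0.2)
  scan <- simulate_scan(st, grid, noise_sd = 0, plant_id = "P1", week = 6)
  spec <- calibrate_reflectance(scan)
  expect_equal(spec$reflectance, true_reflectance(st, grid), tolerance = 1e-9)
})

test_that("scan noise has the requested standard deviation", {
  grid <- seq(400, 2399, length.out = 1000)
  st <- list(chlorophyll = 1.5, water = 0, structure = 0)
  scan <- simulate_scan(st, grid, noise_sd = 1, seed = 7)
  err <- calibrate_reflectance(scan)$reflectance - true_reflectance(st, grid)
  expect_gt(sd(err), 0.9)
  expect_lt(sd(err), 1.1)
  scan2 <- simulate_scan(st, grid, noise_sd = 1, seed = 7)
  expect_identical(scan$plant_dn, scan2$plant_dn)
})

test_that("simulated traits carry the designed couplings", {
  # zero noise across a grid of chlorophyll levels: N vs C:N strongly negative
  chl <- seq(0.5, 2.5, length.out = 60)
  N <- 1.4 + 0.9 * chl
  CN <- 40 / N
  expect_lt(cor(N, CN), -0.95)

  # exact proportionality of E and gsw makes the logs perfectly correlated
  cfg <- synthetic_config()
  d <- make_design(cfg)
  st <- draw_plant_states(d, cfg, seed = 3)
  tr <- simulate_traits(st, d, cfg, seed = 4)
  expect_equal(tr$E, 1.6 * tr$gsw)
  expect_equal(cor(log(tr$E), log(tr$gsw)), 1)
  expect_equal(tr$CN, tr$C / tr$N)

  # quantum yields higher under high nitrogen
  expect_gt(mean(tr$pQY[d$treatment == "N1"]),
            mean(tr$pQY[d$treatment == "N2"]))
})

test_that("sample correlations at scale match the emulated structure", {
  cfg <- synthetic_config(n_accessions_ind = 60, n_accessions_trj = 40,
                          reps_per_accession = 3, extra_rep_accessions = 0,
                          n_missing_traits = 0)
  d <- make_design(cfg)
  st <- draw_plant_states(d, cfg, seed = 11)
  tr <- simulate_traits(st, d, cfg, seed = 12)
  expect_gte(nrow(tr), 500)
  expect_lt(cor(tr$N, tr$CN), -0.9)
  expect_gt(cor(log(tr$E), log(tr$gsw)), 0.999)
})

test_that("generated experiments respect the seed contract", {
  cfg <- tiny_config()
  e1 <- generate_experiment(cfg, seed = 1)
  e2 <- generate_experiment(cfg, seed = 1)
  e3 <- generate_experiment(cfg, seed = 2)
  expect_identical(e1$scans$plant_dn, e2$scans$plant_dn)
  expect_identical(e1$traits, e2$traits)
  expect_false(identical(e1$traits$N, e3$traits$N))
  expect_identical(e1$design, e3$design)  # same skeleton across seeds
})

test_that("experiments cover requested weeks with repeated events", {
  cfg <- tiny_config(weeks = 6L)
  ex <- generate_experiment(cfg, seed = 2)
  expect_setequal(unique(ex$scans$meta$week), 6L)
  ev <- table(ex$scans$meta$plant_id)
  expect_true(all(ev >= 2))
})

test_that("treatment separation concentrates in the Red Edge band", {
  hits <- vapply(1:8, function(s) {
    ex <- generate_experiment(synthetic_config(), seed = 400 + s)
    w <- weekly_average(calibrate_scans(ex$scans))
    k <- w$meta$week == 9
    trt <- ex$design$treatment[match(w$meta$plant_id[k], ex$design$plant_id)]
    d <- colMeans(w$values[k, ][trt == "N1", ]) -
      colMeans(w$values[k, ][trt == "N2", ])
    wl <- w$grid[which.max(abs(d))]
    wl >= 680 && wl <= 720
  }, logical(1))
  expect_true(all(hits))
})
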