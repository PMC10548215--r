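test_that("derived traits follow their defining ratios", {
  d <- derive_traits(leaf_area = 100, dry_weight = 0.5, C = 40, N = 2)
  expect_equal(d$SLA, 200)
  expect_equal(d$CN, 20)
  expect_equal(d$SLN, 0.1)           # 500 mg x 2% / 100 cm2
  expect_equal(d$SLA_C, 100 / 200)   # 200 mg C on 100 cm2

  expect_warning(bad <- derive_traits(100, 0, 40, 2), "nonpositive")
  expect_true(is.na(bad$SLA))
})

test_that("trait transforms are natural logs and min-max scalings", {
  tr <- data.frame(E = c(1, 2), gsw = c(1, exp(1)), SLN = c(1, 1),
                   FB = c(2, 6), pQY = c(0.5, 0.7), mQY = c(0.5, 0.6))
  tr$FB <- c(2, 6)
  out <- transform_traits(rbind(tr, data.frame(E = 1, gsw = 1, SLN = 1,
                                               FB = 4, pQY = 0.6, mQY = 0.55)))
  expect_equal(out$log_gsw, c(0, 1, 0))
  expect_equal(out$normFB, c(0, 1, 0.5))
  expect_warning(transform_traits(data.frame(E = -1, gsw = 1, SLN = 1,
                                             FB = 1, pQY = 1, mQY = 1)),
                 "nonpositive")
})

test_that("proportional traits have perfectly correlated logs", {
  gsw <- exp(rnorm(50))
  tr <- data.frame(E = 3.1 * gsw, gsw = gsw, SLN = 1, FB = 1,
                   pQY = 0.5, mQY = 0.5)
  out <- transform_traits(tr)
  expect_equal(cor(out$log_E, out$log_gsw), 1)
})

test_that("correlation analysis mean-imputes and tests at alpha", {
  set.seed(1)
  tr <- data.frame(a = rnorm(30), b = rnorm(30))
  tr$c <- -tr$a
  tr$d <- tr$a + rnorm(30, 0, 0.1)
  # imputation identity: inserting the mean leaves the column mean unchanged
  tr_na <- tr
  tr_na$a[5] <- NA
  m_before <- mean(tr_na$a, na.rm = TRUE)
  res <- correlation_analysis(tr_na, columns = c("a", "b", "c", "d"),
                              alpha = 0.01)
  expect_equal(unname(diag(res$r)), rep(1, 4))
  expect_equal(res$r, t(res$r))
  expect_lt(res$r["a", "c"], -0.9)
  expect_true(res$significant["a", "d"])
  expect_false(res$significant["a", "b"])
  # PSD of the correlation matrix
  expect_gte(min(eigen(res$r, symmetric = TRUE)$values), -1e-10)

  res_full <- correlation_analysis(tr, columns = c("a", "b", "c", "d"))
  expect_equal(cor(ifelse(is.na(tr_na$a), m_before, tr_na$a), tr$b),
               res$r["a", "b"])
  expect_warning(correlation_analysis(data.frame(a = rep(1, 5), b = rnorm(5)),
                                      columns = c("a", "b")), "constant")
})

test_that("trait PCA is correlation-based and affine-invariant", {
  set.seed(2)
  am <- data.frame(accession = sprintf("A%02d", 1:12), treatment = "N1",
                   x = rnorm(12), y = rnorm(12), z = rnorm(12))
  pc <- trait_pca(am, columns = c("x", "y", "z"))
  expect_equal(sum(pc$variance_fraction), 1, tolerance = 1e-12)
  expect_equal(crossprod(pc$rotation), diag(3), tolerance = 1e-10,
               ignore_attr = TRUE)
  # affine rescaling of a column changes nothing (up to sign)
  am2 <- am
  am2$x <- 100 * am$x + 7
  pc2 <- trait_pca(am2, columns = c("x", "y", "z"))
  expect_equal(abs(pc2$rotation), abs(pc$rotation), tolerance = 1e-8)
  expect_equal(pc2$variance_fraction, pc$variance_fraction, tolerance = 1e-10)
  expect_error(trait_pca(transform(am, x = 1), columns = c("x", "y", "z")),
               "zero-variance")
})

test_that("synthetic accession-mean PCA separates treatments on PC1 via N and C:N", {
  ex <- generate_experiment(synthetic_config(), seed = 17)
  tr <- transform_traits(ex$traits)
  am <- accession_mean_traits(tr, ex$design)
  pc <- trait_pca(am)
  grp <- am$treatment
  sc1 <- pc$x[, 1]
  expect_gt(abs(mean(sc1[grp == "N1"]) - mean(sc1[grp == "N2"])),
            2 * sqrt(var(sc1[grp == "N1"]) / 2 + var(sc1[grp == "N2"]) / 2) / 3)
  top2 <- names(sort(abs(pc$rotation[, 1]), decreasing = TRUE))[1:4]
  expect_true(all(c("N", "CN") %in% top2))
})

test_that("UPGMA clustering has monotone merges and recovers separated groups", {
  set.seed(3)
  am <- data.frame(accession = sprintf("A%02d", 1:20),
                   treatment = rep(c("N1", "N2"), each = 10),
                   x = c(rnorm(10), rnorm(10) + 8),
                   y = c(rnorm(10), rnorm(10) + 8),
                   z = rnorm(20))
  cl <- cluster_accessions(am, columns = c("x", "y", "z"), k = 2)
  expect_true(all(diff(cl$hclust$height) >= -1e-10))
  expect_equal(length(unique(cl$clusters[am$treatment == "N1"])), 1)
  expect_equal(length(unique(cl$clusters[am$treatment == "N2"])), 1)
  expect_error(cluster_accessions(am[1, ], columns = c("x", "y", "z")),
               "at least 2")
})

test_that("synthetic trait clustering aligns with treatment, not subpopulation", {
  skip_if_not_installed("mclust")
  ex <- generate_experiment(synthetic_config(), seed = 23)
  tr <- transform_traits(ex$traits)
  am <- accession_mean_traits(tr, ex$design)
  cl <- cluster_accessions(am, k = 2)
  ari_trt <- mclust::adjustedRandIndex(cl$clusters, am$treatment)
  ari_sub <- mclust::adjustedRandIndex(cl$clusters, am$subpopulation)
  expect_gt(ari_trt, ari_sub)
})

test_that("dendrograms export as parseable Newick", {
  am <- data.frame(accession = c("A1", "A2", "A3"), treatment = "N1",
                   x = c(0, 1, 5), y = c(0, 1, 5), z = c(1, 2, 3))
  txt <- dendrogram_newick(cluster_accessions(am, columns = c("x", "y", "z")))
  phy <- ape::read.tree(text = txt)
  expect_setequal(phy$tip.label, c("A1_N1", "A2_N1", "A3_N1"))
})
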