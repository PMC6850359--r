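test_that("LHI centers at the reference means and follows the PC1 formula", {
  ref <- structure(list(mean_sqrt_pasture = 0.3, sd_sqrt_pasture = 0.1,
                        mean_border = 0.02, sd_border = 0.005),
                   class = "reference_stats")
  # landscape exactly at the reference means
  expect_equal(compute_lhi(0.3^2, 0.02, ref), 0)
  # both z-scores equal to 1
  expect_equal(compute_lhi((0.3 + 0.1)^2, 0.025, ref), sqrt(2),
               tolerance = 1e-12)
  # invariance to a common shift of study values and reference means
  ref2 <- ref
  ref2$mean_border <- ref$mean_border + 0.01
  expect_equal(compute_lhi(0.3^2, 0.03, ref2), 0)
})

test_that("LHI equals the PC1 score from an explicit eigendecomposition", {
  set.seed(1)
  n <- 200
  pasture <- runif(n, 0, 0.25)
  border <- runif(n, 0.005, 0.05)
  ref <- reference_stats(pasture, border)
  lhi <- compute_lhi(pasture, border, ref)
  # oracle: PCA of the two standardized variables
  Z <- cbind((sqrt(pasture) - mean(sqrt(pasture))) / sd(sqrt(pasture)),
             (border - mean(border)) / sd(border))
  e <- eigen(cor(Z))
  pc1 <- Z %*% e$vectors[, 1]
  s <- sign(sum(pc1 * lhi))  # PC sign is arbitrary
  expect_equal(lhi, as.vector(s * pc1), tolerance = 1e-10)
})

test_that("LHI rejects invalid reference statistics", {
  bad <- structure(list(mean_sqrt_pasture = 0.3, sd_sqrt_pasture = 0,
                        mean_border = 0.02, sd_border = 0.005),
                   class = "reference_stats")
  expect_error(compute_lhi(0.1, 0.02, bad), "positive")
  expect_error(reference_stats(rep(0.1, 5), rep(0.02, 5)), "invalid")
})

test_that("proportion extensive is the ley+fallow share of arable land", {
  expect_equal(proportion_extensive(10, 10, 100), 0.2)
  expect_equal(proportion_extensive(0, 0, 50), 0)
  expect_error(proportion_extensive(1, 1, 0), "arable")
  set.seed(2)
  ley <- runif(20, 0, 30); fal <- runif(20, 0, 30)
  ar <- ley + fal + runif(20, 1, 100)
  expect_equal(proportion_extensive(ley, fal, ar), (ley + fal) / ar)
})

test_that("extensive quality is the sqrt share of high-quality land", {
  expect_equal(extensive_quality(10, 0, 0), 1)       # all fallow
  expect_equal(extensive_quality(0, 50, 0), 0)       # managed ley only
  expect_equal(extensive_quality(1, 3, 1), sqrt(2 / 4), tolerance = 1e-12)
  expect_warning(out <- extensive_quality(0, 0, 0), "no extensive land")
  expect_equal(out, 0)
  expect_warning(out <- extensive_quality(0, 0, 0, undefined = NA), "EQ")
  expect_true(is.na(out))
  expect_error(extensive_quality(1, 1, 2), "exceeds")
})

test_that("crop diversity is the Hill number of order 1", {
  expect_equal(crop_diversity(c(10, rep(0, 12))), 1)
  expect_equal(crop_diversity(rep(3.7, 13)), 13, tolerance = 1e-12)
  # oracle: exponential Shannon entropy via vegan
  expect_equal(crop_diversity(c(50, 30, 20)),
               exp(vegan::diversity(c(50, 30, 20), index = "shannon")),
               tolerance = 1e-12)
  set.seed(3)
  a <- rexp(13)
  expect_equal(crop_diversity(a), exp(vegan::diversity(a)),
               tolerance = 1e-10)
  # permutation and scale invariance
  expect_equal(crop_diversity(a), crop_diversity(rev(a) * 7))
  expect_error(crop_diversity(rep(0, 13)), "all crop areas are zero")
})

test_that("proportion spring sown and 3-year ley mean follow their ratios", {
  expect_equal(proportion_spring_sown(30, 60), 0.5)
  expect_equal(proportion_spring_sown(0, 60), 0)
  expect_error(proportion_spring_sown(1, 0), "zero")
  expect_equal(mean_ley_3yr(c(10, 20, 30), 100), 0.2)
  expect_equal(mean_ley_3yr(c(7, 7, 7), 70), 0.1)
  expect_error(mean_ley_3yr(c(1, 2), 10), "3 yearly values")
  m <- matrix(runif(9, 0, 20), 3, 3)
  fa <- c(100, 150, 200)
  expect_equal(mean_ley_3yr(m, fa), rowMeans(m) / fa)
})

test_that("variance inflation matches the 1/(1 - R^2) definition", {
  # predictors orthogonal to each other and to the intercept give exactly 1
  set.seed(40)
  X <- qr.Q(qr(cbind(1, matrix(rnorm(100), 20, 5))))[, -1]
  expect_equal(unname(variance_inflation(X)), rep(1, 5), tolerance = 1e-10)
  # duplicated predictor: infinite with warning
  Xd <- cbind(a = X[, 1], b = X[, 1], c = X[, 2])
  expect_warning(v <- variance_inflation(Xd), "collinearity")
  expect_true(all(is.infinite(v[c("a", "b")])))
  # random correlated table vs explicit oracle
  set.seed(4)
  Z <- matrix(rnorm(40 * 4), 40, 4) %*% chol(0.5 + 0.5 * diag(4))
  colnames(Z) <- paste0("x", 1:4)
  v <- variance_inflation(Z)
  oracle <- sapply(1:4, function(k) {
    r2 <- summary(lm(Z[, k] ~ Z[, -k]))$r.squared
    1 / (1 - r2)
  })
  expect_equal(unname(v), oracle, tolerance = 1e-10)
  expect_error(variance_inflation(Z[1:3, ]), "more rows")
  expect_error(variance_inflation(Z[, 1, drop = FALSE]), "at least 2")
})

test_that("the predictor pipeline is deterministic and writes/reads CSV", {
  set.seed(5)
  tr <- jsdm_truth(n_sites = 12, J = 2, seed = 5)
  ds <- suppressWarnings(simulate_dataset(tr))
  p1 <- landscape_predictors(ds$raw, ds$ref)
  p2 <- landscape_predictors(ds$raw, ds$ref)
  expect_identical(p1, p2)
  expect_true(all(c("FA", "LHI", "PE", "EQ", "CD", "PSS", "FA_std",
                    "PSS_std") %in% names(p1)))
  expect_equal(mean(p1$CD_std), 0, tolerance = 1e-12)
  expect_equal(sd(p1$CD_std), 1, tolerance = 1e-12)
  f <- withr::local_tempfile(fileext = ".csv")
  write_predictors(p1, f)
  p3 <- read_predictors(f)
  expect_equal(p3$LHI, p1$LHI, tolerance = 1e-12)
  raw2 <- ds$raw
  raw2$crop05 <- NULL
  expect_error(landscape_predictors(raw2, ds$ref), "crop05")
})
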