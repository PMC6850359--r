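test_that("design matrix standardizes columns and forms interactions", {
  set.seed(8)
  pred <- generate_predictors(jsdm_truth(n_sites = 25))
  X <- build_design_matrix(pred)
  expect_equal(ncol(X), 11)
  expect_equal(colnames(X)[1], "(Intercept)")
  for (v in c("FA", "LHI", "PE", "EQ", "CD", "PSS")) {
    expect_equal(mean(X[, v]), 0, tolerance = 1e-10)
    expect_equal(sd(X[, v]), 1, tolerance = 1e-10)
  }
  # interaction columns are elementwise products of standardized parents
  for (v in c("PE", "EQ", "CD", "PSS"))
    expect_equal(X[, paste0("LHI:", v)], X[, "LHI"] * X[, v],
                 tolerance = 1e-12)
  # raw-unit metadata is preserved
  expect_equal(unname(attr(X, "scale")["FA"]), sd(pred$FA))
  expect_equal(attr(X, "lhi_range_std"), range(X[, "LHI"]))
  pred$CD <- 3
  expect_error(build_design_matrix(pred), "CD")
})

test_that("latent log density matches the multivariate normal", {
  set.seed(9)
  n <- 4; J <- 3; K <- 2
  X <- cbind(1, rnorm(n))
  B <- matrix(rnorm(K * J), K, J)
  # M = XB with identity covariance: per-site density is -(J/2) log(2 pi)
  expect_equal(latent_logdensity(X %*% B, X, B, diag(J)),
               -n * J / 2 * log(2 * pi), tolerance = 1e-12)
  # J = 1 reduces to the univariate normal
  m1 <- matrix(rnorm(n), n, 1)
  expect_equal(latent_logdensity(m1, X, B[, 1, drop = FALSE],
                                 matrix(4, 1, 1)),
               sum(dnorm(m1, X %*% B[, 1], 2, log = TRUE)),
               tolerance = 1e-12)
  # random instance vs direct quadratic-form/determinant oracle
  A <- matrix(rnorm(J * J), J); Sigma <- crossprod(A) + diag(J)
  M <- X %*% B + matrix(rnorm(n * J), n, J)
  E <- M - X %*% B
  oracle <- sum(sapply(seq_len(n), function(i) {
    -0.5 * (J * log(2 * pi) + determinant(Sigma)$modulus +
              t(E[i, ]) %*% solve(Sigma) %*% E[i, ])
  }))
  expect_equal(latent_logdensity(M, X, B, Sigma), oracle, tolerance = 1e-10)
  expect_error(latent_logdensity(M, X, B, matrix(c(1, 2, 0, 2, 1, 0, 0, 0, 1),
                                                 3)), "positive-definite")
})

counts_for_loglik <- function(y) {
  data.frame(site_id = 1, visit = seq_along(y), observer_id = 1,
             n_points = 1, species = "s1", count = y)
}

test_that("observation log likelihood has the stated families and limits", {
  # Poisson, mu = 1, y = 0: log density is -1
  cnt <- counts_for_loglik(0)
  M <- matrix(0, 1, 1)
  expect_equal(observation_loglik(cnt, M, 0, 0, family = "poisson"), -1)
  # negative binomial converges to Poisson as theta -> infinity
  for (y in c(0, 3, 20)) for (mu in c(0.5, 2, 10)) {
    cnt <- counts_for_loglik(y)
    M <- matrix(log(mu), 1, 1)
    expect_equal(
      observation_loglik(cnt, M, 0, 0, theta = 1e8, family = "negbinomial"),
      observation_loglik(cnt, M, 0, 0, family = "poisson"),
      tolerance = 1e-4)
  }
  expect_error(observation_loglik(counts_for_loglik(-1), M, 0, 0,
                                  family = "poisson"), "negative counts")
  expect_error(observation_loglik(counts_for_loglik(1), M, 0, 0,
                                  theta = -1, family = "negbinomial"),
               "positive")
})

test_that("negative binomial parameterization gives Var = mu + mu^2/theta", {
  # moments of the pmf implied by observation_loglik itself
  mu <- 5; th <- 2
  y <- 0:500
  p <- exp(vapply(y, function(yy)
    observation_loglik(counts_for_loglik(yy), matrix(log(mu), 1, 1), 0, 0,
                       theta = th, family = "negbinomial"), numeric(1)))
  expect_equal(sum(p), 1, tolerance = 1e-10)
  expect_equal(sum(y * p), mu, tolerance = 1e-8)
  expect_equal(sum((y - mu)^2 * p), mu + mu^2 / th, tolerance = 1e-6)
})

test_that("covariance decomposition round-trips", {
  expect_equal(sigma_to_correlation(diag(3)),
               list(R = diag(3), sigma = rep(1, 3)))
  d <- sigma_to_correlation(diag(c(4, 9)))
  expect_equal(d$sigma, c(2, 3))
  expect_equal(d$R, diag(2))
  set.seed(10)
  A <- matrix(rnorm(16), 4); S <- crossprod(A) + diag(4)
  d <- sigma_to_correlation(S)
  expect_equal(diag(d$sigma) %*% d$R %*% diag(d$sigma), S,
               tolerance = 1e-10)
  expect_error(sigma_to_correlation(matrix(c(1, 2, 2, 1), 2)),
               "positive-definite")
})

test_that("all four covariance priors yield valid draws", {
  set.seed(11)
  for (fl in c("IW", "SIW", "SSIW", "SSLKJ")) {
    draws <- sample_sigma_prior(fl, J = 4, n = 25)
    for (S in draws) {
      expect_true(all(eigen(S, symmetric = TRUE,
                            only.values = TRUE)$values > 0))
      expect_equal(S, t(S), tolerance = 1e-12)
      # implied correlation has exact unit diagonal
      expect_equal(diag(sigma_to_correlation(S)$R), rep(1, 4))
    }
  }
  expect_error(sample_sigma_prior("IW", J = 1), "J >= 2")
})

test_that("separation-strategy priors decouple SDs from correlations", {
  set.seed(12)
  draws <- sample_sigma_prior("SSLKJ", J = 2, n = 2000)
  s1 <- sapply(draws, function(S) sqrt(S[1, 1]))
  r12 <- sapply(draws, function(S) sigma_to_correlation(S)$R[1, 2])
  # sampled SD and correlation are independent by construction
  expect_lt(abs(cor(rank(s1), rank(r12))), 0.06)
})

test_that("LKJ(1) draws have uniform pairwise correlation at J = 2", {
  set.seed(13)
  r <- replicate(4000, rlkj(2)[1, 2])
  ks <- suppressWarnings(ks.test(r, "punif", -1, 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("joint log density assembles its terms additively", {
  set.seed(14)
  tr <- jsdm_truth(n_sites = 2, J = 2, seed = 14)
  ds <- suppressWarnings(simulate_dataset(tr))
  X <- ds$design
  J <- 2; K <- 11; n <- 2
  Sigma <- diag(c(0.2, 0.3))
  prm <- jsdm_params(
    B = ds$latent$B, mu_B = tr$mu_B, sigma_B = tr$sigma_B, Sigma = Sigma,
    theta = tr$theta, site_effects = ds$latent$site_effects,
    observer_effects = ds$latent$observer_effects,
    sigma_S = tr$sigma_S, sigma_O = tr$sigma_O, M = ds$latent$M)
  cfg <- jsdm_config("negbinomial", "SSLKJ")
  terms <- joint_logdensity(ds$counts, X, prm, cfg, by_term = TRUE)
  # hand-assembled sum of the individual densities
  dec <- sigma_to_correlation(Sigma)
  hand <- sum(observation_loglik(ds$counts, prm$M, prm$site_effects,
                                 prm$observer_effects, prm$theta,
                                 "negbinomial")) +
    latent_logdensity(prm$M, X, prm$B, Sigma) +
    sum(dnorm(prm$B, rep(tr$mu_B, J), rep(tr$sigma_B, J), log = TRUE)) +
    sum(dnorm(prm$site_effects, 0, tr$sigma_S, log = TRUE)) +
    sum(dnorm(prm$observer_effects, 0, tr$sigma_O, log = TRUE)) +
    sum(dnorm(tr$mu_B, 0, cfg$scale_mu, log = TRUE)) +
    sum(log(2) - log(pi * cfg$scale_sigma_b) -
          log1p((tr$sigma_B / cfg$scale_sigma_b)^2)) +
    (log(2) - log(pi * 2.5) - log1p((tr$sigma_S / 2.5)^2)) +
    (log(2) - log(pi * 2.5) - log1p((tr$sigma_O / 2.5)^2)) +
    sum(log(cfg$theta_rate) - cfg$theta_rate / tr$theta -
          2 * log(tr$theta)) +
    sum(log(2) - log(pi * cfg$scale_sigma_j) -
          log1p((dec$sigma / cfg$scale_sigma_j)^2))  # LKJ(1) term is 0
  expect_equal(sum(terms), hand, tolerance = 1e-10)
  # dropping one site's data removes exactly that site's contributions
  keep <- ds$counts$site_id == 1
  prm1 <- prm
  prm1$M <- prm$M[1, , drop = FALSE]
  prm1$site_effects <- prm$site_effects[1]
  t1 <- joint_logdensity(ds$counts[keep, ], X[1, , drop = FALSE], prm1,
                         cfg, by_term = TRUE)
  ll_full <- observation_loglik(ds$counts, prm$M, prm$site_effects,
                                prm$observer_effects, prm$theta,
                                "negbinomial")
  expect_equal(unname(terms["obs"] - t1["obs"]), sum(ll_full[!keep]),
               tolerance = 1e-10)
  # Poisson configuration ignores theta entirely
  cfgp <- jsdm_config("poisson", "SSLKJ")
  prm_a <- prm; prm_a$theta <- c(1, 1)
  prm_b <- prm; prm_b$theta <- c(50, 0.1)
  expect_equal(joint_logdensity(ds$counts, X, prm_a, cfgp),
               joint_logdensity(ds$counts, X, prm_b, cfgp))
})

test_that("model configuration validates and round-trips through YAML", {
  cfg <- jsdm_config("poisson", "SIW", "strong", chains = 3, iter = 500,
                     seed = 99)
  expect_equal(cfg$scale_mu, 10)
  expect_equal(cfg$scale_sigma_b, 2.5)
  expect_equal(cfg$theta_rate, 1)
  expect_equal(cfg$warmup, 250)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_model_config(cfg, f)
  cfg2 <- read_model_config(f)
  expect_equal(cfg2, cfg)
  expect_error(jsdm_config(family = "binomial"), "should be one of")
})
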