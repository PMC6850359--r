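#' Model configuration
#'
#' Collects the distributional and prior choices of the joint count model,
#' plus sampler settings, in one validated object.
#'
#' Regularization levels couple the hyper-prior scales: `"weak"` selects
#' Normal(0, 100) for the coefficient hyper-means, Cauchy+(0, 5) for
#' SD-type hyper-parameters and Exponential(0.5) for the inverse dispersion
#' 1/theta; `"strong"` selects Normal(0, 10), Cauchy+(0, 2.5) and
#' Exponential(1). Individual scales can be overridden, e.g. to pair weakly
#' regularized coefficients with the more informative Exponential(1)
#' dispersion prior. The site- and observer-effect SDs always carry
#' Cauchy+(0, 2.5) priors. The inverse-Wishart degrees of freedom are
#' `J + 1` with an identity scale matrix; the LKJ shape is 1 (uniform over
#' correlation matrices).
#'
#' @param family observation family: `"negbinomial"` (variance
#'   `mu + mu^2/theta`) or `"poisson"` (`theta` ignored).
#' @param sigma_prior prior construction for the residual covariance
#'   `Sigma`: `"SSLKJ"` (separation strategy, LKJ correlation), `"SSIW"`
#'   (separation strategy, correlation from an inverse-Wishart draw),
#'   `"SIW"` (scaled inverse-Wishart) or `"IW"` (inverse-Wishart).
#' @param regularization `"weak"` or `"strong"` (see Details).
#' @param chains,iter MCMC layout; half of `iter` is warm-up. Defaults give
#'   5 x 4000 with 10,000 retained draws.
#' @param seed integer seed controlling all sampler randomness.
#' @param scale_mu,scale_sigma_b,theta_rate optional overrides of the
#'   regularization-implied scales.
#' @param scale_sigma_s,scale_sigma_o half-Cauchy scales of the random-effect
#'   SD priors.
#' @param lkj_shape LKJ shape parameter (SSLKJ only).
#' @param latent_residual if `FALSE` the latent residual is dropped
#'   (`M = XB` exactly); a degenerate variant used for testing against
#'   closed-form posteriors.
#' @param include_ranef if `FALSE`, site and observer random effects are
#'   dropped (testing aid).
#' @param round_policy how fractional (Starling-corrected) counts are
#'   discretized before likelihood evaluation: `"half-up"` (round to
#'   nearest, ties up) or `"none"` (error on fractional counts).
#' @return Object of class `"jsdm_config"`.
#' @export
jsdm_config <- function(family = c("negbinomial", "poisson"),
                        sigma_prior = c("SSLKJ", "SSIW", "SIW", "IW"),
                        regularization = c("weak", "strong"),
                        chains = 5, iter = 4000, seed = 1,
                        scale_mu = NULL, scale_sigma_b = NULL,
                        theta_rate = NULL,
                        scale_sigma_s = 2.5, scale_sigma_o = 2.5,
                        lkj_shape = 1,
                        latent_residual = TRUE, include_ranef = TRUE,
                        round_policy = c("half-up", "none")) {
  family <- match.arg(family)
  sigma_prior <- match.arg(sigma_prior)
  regularization <- match.arg(regularization)
  weak <- regularization == "weak"
  cfg <- list(
    family = family, sigma_prior = sigma_prior,
    regularization = regularization,
    chains = as.integer(chains), iter = as.integer(iter),
    warmup = as.integer(iter) %/% 2L, seed = as.integer(seed),
    scale_mu = if (is.null(scale_mu)) (if (weak) 100 else 10) else scale_mu,
    scale_sigma_b = if (is.null(scale_sigma_b)) (if (weak) 5 else 2.5)
                    else scale_sigma_b,
    scale_sigma_j = if (weak) 5 else 2.5,
    theta_rate = if (is.null(theta_rate)) (if (weak) 0.5 else 1)
                 else theta_rate,
    scale_sigma_s = scale_sigma_s, scale_sigma_o = scale_sigma_o,
    lkj_shape = lkj_shape,
    latent_residual = isTRUE(latent_residual),
    include_ranef = isTRUE(include_ranef),
    round_policy = match.arg(round_policy)
  )
  stopifnot(cfg$chains >= 1, cfg$iter >= 2, cfg$scale_mu > 0,
            cfg$scale_sigma_b > 0, cfg$theta_rate > 0, cfg$lkj_shape > 0)
  class(cfg) <- "jsdm_config"
  cfg
}

#' @export
print.jsdm_config <- function(x, ...) {
  cat("joint count model configuration\n")
  cat(sprintf("  family: %s   Sigma prior: %s   regularization: %s\n",
              x$family, x$sigma_prior, x$regularization))
  cat(sprintf("  mu_B ~ N(0, %g^2); sigma_B ~ Cauchy+(0, %g); 1/theta ~ Exp(%g)\n",
              x$scale_mu, x$scale_sigma_b, x$theta_rate))
  cat(sprintf("  sampler: %d chain(s) x %d iterations (%d warm-up), seed %d\n",
              x$chains, x$iter, x$warmup, x$seed))
  invisible(x)
}

#' Model-configuration file I/O
#'
#' Serializes a [jsdm_config()] to a YAML key-value file and back.
#'
#' @param config a `jsdm_config`.
#' @param path file path.
#' @name config_io
#' @export
write_model_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname config_io
#' @export
read_model_config <- function(path) {
  v <- yaml::read_yaml(path)
  do.call(jsdm_config, v[intersect(names(v), names(formals(jsdm_config)))])
}

# design-matrix column names, fixed order (K = 11)
design_colnames <- function() {
  c("(Intercept)", "FA", "LHI", "PE", "EQ", "CD", "PSS",
    "LHI:PE", "LHI:EQ", "LHI:CD", "LHI:PSS")
}

#' Build the model design matrix
#'
#' Standardizes the six landscape predictors (mean 0, SD 1 within the
#' dataset), forms the four LHI-by-land-use interactions from the
#' standardized components, and prepends an intercept. Column metadata
#' records each predictor's raw-unit mean and SD, so effect sizes can be
#' reported per raw-unit SD (e.g. "per 45 ha of farmland"), and the
#' standardized range of LHI used when summarizing effects at the least /
#' most heterogeneous landscape.
#'
#' @param predictors a [landscape_predictors()] table (or any data.frame
#'   with numeric columns `FA`, `LHI`, `PE`, `EQ`, `CD`, `PSS`).
#' @return `n x 11` matrix of class `"jsdm_design"` with attributes
#'   `center`, `scale` (named, raw units) and `lhi_range_std`.
#' @export
build_design_matrix <- function(predictors) {
  vars <- c("FA", "LHI", "PE", "EQ", "CD", "PSS")
  miss <- setdiff(vars, names(predictors))
  if (length(miss)) stop("predictor table lacks: ", paste(miss, collapse = ", "))
  raw <- as.matrix(as.data.frame(predictors)[vars])
  if (anyNA(raw)) stop("predictors contain missing values")
  ctr <- colMeans(raw)
  scl <- apply(raw, 2, stats::sd)
  zero <- scl <= 0 | !is.finite(scl)
  if (any(zero))
    stop("zero-variance predictor(s): ", paste(vars[zero], collapse = ", "))
  z <- sweep(sweep(raw, 2, ctr), 2, scl, "/")
  X <- cbind(1, z,
             z[, "LHI"] * z[, "PE"], z[, "LHI"] * z[, "EQ"],
             z[, "LHI"] * z[, "CD"], z[, "LHI"] * z[, "PSS"])
  colnames(X) <- design_colnames()
  attr(X, "center") <- ctr
  attr(X, "scale") <- scl
  attr(X, "lhi_range_std") <- range(z[, "LHI"])
  class(X) <- c("jsdm_design", class(X))
  X
}

# ---- density building blocks ------------------------------------------------

half_cauchy_logpdf <- function(x, scale) {
  ifelse(x > 0, log(2) - log(pi * scale) - log1p((x / scale)^2), -Inf)
}

half_normal_logpdf <- function(x, scale) {
  ifelse(x > 0, log(2) + stats::dnorm(x, 0, scale, log = TRUE), -Inf)
}

# density of theta when 1/theta ~ Exponential(rate)
theta_logpdf <- function(theta, rate) {
  ifelse(theta > 0, log(rate) - rate / theta - 2 * log(theta), -Inf)
}

lmvgamma <- function(a, p) {
  p * (p - 1) / 4 * log(pi) + sum(lgamma(a + (1 - seq_len(p)) / 2))
}

# inverse-Wishart(df, scale = I) log density of a PD matrix
inv_wishart_logpdf <- function(sigma, df) {
  J <- nrow(sigma)
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  ldet <- 2 * sum(log(diag(ch)))
  tr_inv <- sum(chol2inv(ch) * diag(J))
  -(df * J / 2) * log(2) - lmvgamma(df / 2, J) -
    ((df + J + 1) / 2) * ldet - tr_inv / 2
}

# LKJ log density of a correlation matrix, up to its normalizing constant
# (constant in R for fixed J and shape, so irrelevant to sampling and to
# additivity checks)
lkj_logpdf <- function(R, shape = 1) {
  ch <- tryCatch(chol(R), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  (shape - 1) * 2 * sum(log(diag(ch)))
}

#' Log density of the latent multivariate-normal abundances
#'
#' Sum over sites of the J-dimensional multivariate normal log density of
#' the latent log-abundance rows `M[i, ]` with mean `X[i, ] %*% B` and
#' common covariance `Sigma`.
#'
#' @param M `n x J` latent matrix.
#' @param X `n x K` design matrix.
#' @param B `K x J` coefficient matrix.
#' @param Sigma `J x J` positive-definite covariance.
#' @return Scalar log density.
#' @export
latent_logdensity <- function(M, X, B, Sigma) {
  M <- as.matrix(M); X <- as.matrix(X); B <- as.matrix(B)
  n <- nrow(M); J <- ncol(M)
  stopifnot(nrow(X) == n, ncol(X) == nrow(B), ncol(B) == J,
            nrow(Sigma) == J, ncol(Sigma) == J)
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) stop("Sigma is not positive-definite")
  E <- M - X %*% B
  # quadratic forms via triangular solve
  q <- colSums(backsolve(ch, t(E), transpose = TRUE)^2)
  ldet <- 2 * sum(log(diag(ch)))
  sum(-0.5 * (J * log(2 * pi) + ldet + q))
}

#' Pointwise observation log likelihood
#'
#' Per-observation log likelihood of the counts given the latent abundances
#' and random effects, on the scale needed for WAIC. The expected count for
#' a record of species j at site i, visit v is
#' `mu = exp(M[i, j] + site[i] + observer[o(i, v)] + log n_points[i, v])`.
#' Under `"poisson"` the variance equals the mean (dispersion fixed at 1);
#' under `"negbinomial"` the variance is `mu + mu^2 / theta[j]`
#' (gamma-Poisson mixture with shape `theta[j]`).
#'
#' @param counts a count table ([aggregate_counts()]) with integer counts.
#' @param design the [build_design_matrix()] used for site ordering (only
#'   site order is taken from its rownames); alternatively `NULL` to order
#'   sites as they appear.
#' @param M `n x J` latent log-abundance matrix (sites x species, species
#'   in the column order of `sort(unique(counts$species))`).
#' @param site_effects length-n vector.
#' @param observer_effects named or ordered vector over observers.
#' @param theta length-J dispersion vector (ignored for Poisson).
#' @param family `"negbinomial"` or `"poisson"`.
#' @return Numeric vector, one log likelihood per row of `counts` (in row
#'   order).
#' @export
observation_loglik <- function(counts, M, site_effects, observer_effects,
                               theta = NULL,
                               family = c("negbinomial", "poisson"),
                               design = NULL) {
  family <- match.arg(family)
  fr <- as_model_frame(counts)
  if (any(fr$count < 0)) stop("negative counts")
  if (family == "negbinomial") {
    if (is.null(theta)) stop("theta required for the negative binomial family")
    if (any(theta <= 0)) stop("theta must be positive")
  }
  m <- M[cbind(fr$site, fr$species)]
  eta <- m + site_effects[fr$site] + observer_effects[fr$observer] + fr$log_np
  mu <- exp(eta)
  if (family == "poisson")
    stats::dpois(fr$count, mu, log = TRUE)
  else
    stats::dnbinom(fr$count, size = theta[fr$species], mu = mu, log = TRUE)
}

# canonical long model frame: integer site/observer/species indices
as_model_frame <- function(counts) {
  if (!is.null(attr(counts, "model_frame"))) return(attr(counts, "model_frame"))
  req <- c("site_id", "visit", "observer_id", "n_points", "species", "count")
  miss <- setdiff(req, names(counts))
  if (length(miss)) stop("count table lacks columns: ",
                         paste(miss, collapse = ", "))
  sites <- sort(unique(counts$site_id))
  obs <- sort(unique(counts$observer_id))
  spp <- sort(unique(counts$species))
  data.frame(
    site = match(counts$site_id, sites),
    visit = counts$visit,
    observer = match(counts$observer_id, obs),
    species = match(counts$species, spp),
    count = counts$count,
    log_np = log(counts$n_points),
    stringsAsFactors = FALSE
  )
}

# level sets in the canonical order used by as_model_frame
model_levels <- function(counts) {
  list(sites = sort(unique(counts$site_id)),
       observers = sort(unique(counts$observer_id)),
       species = sort(unique(counts$species)))
}

#' Decompose a covariance matrix into SDs and a correlation matrix
#'
#' @param Sigma positive-definite matrix.
#' @return List with `R` (correlation matrix, unit diagonal) and `sigma`
#'   (vector of standard deviations), satisfying
#'   `diag(sigma) %*% R %*% diag(sigma) == Sigma` to numerical precision.
#' @export
sigma_to_correlation <- function(Sigma) {
  ev <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ev)) stop("Sigma is not positive-definite")
  s <- sqrt(diag(Sigma))
  R <- Sigma / tcrossprod(s)
  diag(R) <- 1
  list(R = R, sigma = s)
}

#' Draw a correlation matrix from the LKJ distribution
#'
#' C-vine construction: canonical partial correlations are drawn from
#' shifted Beta distributions and assembled into the Cholesky factor of the
#' correlation matrix. With `shape = 1` the distribution is uniform over
#' the space of correlation matrices; at `J = 2` the single correlation is
#' then uniform on (-1, 1).
#'
#' @param J dimension (>= 2).
#' @param shape LKJ shape parameter (> 0).
#' @param chol if `TRUE` return the lower-triangular Cholesky factor `W`
#'   with `R = W %*% t(W)` instead of `R`.
#' @return `J x J` correlation matrix (or its Cholesky factor).
#' @export
rlkj <- function(J, shape = 1, chol = FALSE) {
  stopifnot(J >= 2, shape > 0)
  W <- diag(J)
  pr <- matrix(0, J, J)
  for (k in seq_len(J - 1)) {
    a <- shape + (J - 1 - k) / 2
    pr[k, (k + 1):J] <- 2 * stats::rbeta(J - k, a, a) - 1
  }
  for (j in 2:J) {
    W[j, 1] <- pr[1, j]
    cum <- sqrt(1 - pr[1, j]^2)
    if (j > 2) for (k in 2:(j - 1)) {
      W[j, k] <- pr[k, j] * cum
      cum <- cum * sqrt(1 - pr[k, j]^2)
    }
    W[j, j] <- cum
  }
  if (chol) W else tcrossprod(W)
}

#' Draw residual covariance matrices from the four prior constructions
#'
#' Forward-samples `Sigma` under the prior used in model fitting:
#' \describe{
#' \item{IW}{`Sigma ~ invWishart(J + 1, I)`.}
#' \item{SIW}{scaled inverse-Wishart: `Q ~ invWishart(J + 1, I)`,
#'   `xi_j ~ Normal+(0, 1)`, `Sigma = diag(xi) Q diag(xi)`.}
#' \item{SSIW}{separation strategy: the correlation matrix is extracted
#'   from an inverse-Wishart draw (`R = D^-1 Q D^-1`, `D = sqrt(diag(Q))`)
#'   and recombined with half-Cauchy SDs.}
#' \item{SSLKJ}{separation strategy with `R ~ LKJ(1)` and half-Cauchy SDs.}
#' }
#' The half-Cauchy scale is 5 (`"weak"`) or 2.5 (`"strong"`).
#'
#' @param flavor one of `"IW"`, `"SIW"`, `"SSIW"`, `"SSLKJ"`.
#' @param J dimension (>= 2).
#' @param regularization `"weak"` or `"strong"` (SD prior scale).
#' @param n number of draws.
#' @return A list of `n` covariance matrices (a single matrix if `n = 1`).
#' @export
sample_sigma_prior <- function(flavor = c("SSLKJ", "SSIW", "SIW", "IW"),
                               J, regularization = c("weak", "strong"),
                               n = 1) {
  flavor <- match.arg(flavor)
  regularization <- match.arg(regularization)
  stopifnot(J >= 2)
  df <- J + 1
  s_scale <- if (regularization == "weak") 5 else 2.5
  draw1 <- function() {
    switch(flavor,
      IW = chol2inv(chol(stats::rWishart(1, df, diag(J))[, , 1])),
      SIW = {
        Q <- chol2inv(chol(stats::rWishart(1, df, diag(J))[, , 1]))
        xi <- abs(stats::rnorm(J))
        Q * tcrossprod(xi)
      },
      SSIW = {
        Q <- chol2inv(chol(stats::rWishart(1, df, diag(J))[, , 1]))
        R <- sigma_to_correlation(Q)$R
        s <- abs(s_scale * stats::rcauchy(J))
        R * tcrossprod(s)
      },
      SSLKJ = {
        R <- rlkj(J, shape = 1)
        s <- abs(s_scale * stats::rcauchy(J))
        R * tcrossprod(s)
      })
  }
  out <- replicate(n, draw1(), simplify = FALSE)
  if (n == 1) out[[1]] else out
}

#' Parameter set of the joint model
#'
#' Bundles one complete parameter draw and validates its constraints.
#' Under the `SIW` flavor the underlying unscaled covariance `Q` and
#' scaling vector `xi` must be supplied (their priors enter the joint
#' density); under `SSIW` the underlying `Q`; under `SSLKJ` the correlation
#' `R` and SD vector `sigma_j` are taken from `Sigma` itself.
#'
#' @param B `K x J` coefficient matrix; `mu_B`, `sigma_B` its length-K
#'   hyper-parameters (`sigma_B > 0`).
#' @param Sigma `J x J` positive-definite residual covariance.
#' @param theta length-J positive dispersions (`NULL` under Poisson).
#' @param site_effects,observer_effects random-effect vectors with SDs
#'   `sigma_S`, `sigma_O` (> 0).
#' @param M `n x J` latent log-abundance matrix.
#' @param Q,xi flavor-specific underlying quantities (see Details).
#' @return Object of class `"jsdm_params"`.
#' @export
jsdm_params <- function(B, mu_B, sigma_B, Sigma, theta = NULL,
                        site_effects, observer_effects,
                        sigma_S, sigma_O, M, Q = NULL, xi = NULL) {
  B <- as.matrix(B); M <- as.matrix(M)
  K <- nrow(B); J <- ncol(B)
  stopifnot(length(mu_B) == K, length(sigma_B) == K, all(sigma_B > 0),
            nrow(Sigma) == J, ncol(Sigma) == J, ncol(M) == J,
            sigma_S > 0, sigma_O > 0)
  if (!isTRUE(all.equal(Sigma, t(Sigma), tolerance = 1e-8)))
    stop("Sigma must be symmetric")
  if (inherits(tryCatch(chol(Sigma), error = function(e) e), "error"))
    stop("Sigma must be positive-definite")
  if (!is.null(theta) && any(theta <= 0)) stop("theta must be positive")
  dec <- sigma_to_correlation(Sigma)
  out <- list(B = B, mu_B = mu_B, sigma_B = sigma_B, Sigma = Sigma,
              R = dec$R, sigma_j = dec$sigma, theta = theta,
              site_effects = site_effects,
              observer_effects = observer_effects,
              sigma_S = sigma_S, sigma_O = sigma_O, M = M, Q = Q, xi = xi)
  class(out) <- "jsdm_params"
  out
}

#' Joint log density of data and parameters
#'
#' The unnormalized log posterior kernel: observation log likelihood plus
#' latent multivariate-normal log density plus random-effect and
#' hierarchical-coefficient log densities plus all hyper-prior log
#' densities implied by the configuration. The LKJ correlation prior enters
#' up to its (parameter-free) normalizing constant.
#'
#' @param counts count table with integer counts.
#' @param design [build_design_matrix()] output.
#' @param params [jsdm_params()] parameter set.
#' @param config [jsdm_config()].
#' @param by_term if `TRUE`, return the named vector of additive
#'   components instead of their sum.
#' @return Scalar log density (or named vector when `by_term`).
#' @export
joint_logdensity <- function(counts, design, params, config,
                             by_term = FALSE) {
  p <- params
  J <- ncol(p$B); K <- nrow(p$B)
  stopifnot(ncol(design) == K)
  terms <- c(
    obs = sum(observation_loglik(counts, p$M, p$site_effects,
                                 p$observer_effects, p$theta, config$family)),
    latent = latent_logdensity(p$M, design, p$B, p$Sigma),
    coef = sum(stats::dnorm(p$B, rep(p$mu_B, J),
                            rep(p$sigma_B, J), log = TRUE)),
    ranef = sum(stats::dnorm(p$site_effects, 0, p$sigma_S, log = TRUE)) +
            sum(stats::dnorm(p$observer_effects, 0, p$sigma_O, log = TRUE)),
    hyper_mu = sum(stats::dnorm(p$mu_B, 0, config$scale_mu, log = TRUE)),
    hyper_sigma_b = sum(half_cauchy_logpdf(p$sigma_B, config$scale_sigma_b)),
    hyper_ranef_sd = half_cauchy_logpdf(p$sigma_S, config$scale_sigma_s) +
                     half_cauchy_logpdf(p$sigma_O, config$scale_sigma_o),
    dispersion = if (config$family == "negbinomial")
                   sum(theta_logpdf(p$theta, config$theta_rate)) else 0,
    sigma_prior = sigma_prior_logdensity(p, config, J)
  )
  if (by_term) terms else sum(terms)
}

sigma_prior_logdensity <- function(p, config, J) {
  df <- J + 1
  switch(config$sigma_prior,
    IW = inv_wishart_logpdf(p$Sigma, df),
    SIW = {
      if (is.null(p$Q) || is.null(p$xi))
        stop("SIW flavor requires Q and xi in the parameter set")
      inv_wishart_logpdf(p$Q, df) + sum(half_normal_logpdf(p$xi, 1))
    },
    SSIW = {
      if (is.null(p$Q)) stop("SSIW flavor requires Q in the parameter set")
      inv_wishart_logpdf(p$Q, df) +
        sum(half_cauchy_logpdf(p$sigma_j, config$scale_sigma_j))
    },
    SSLKJ = lkj_logpdf(p$R, config$lkj_shape) +
            sum(half_cauchy_logpdf(p$sigma_j, config$scale_sigma_j))
  )
}
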