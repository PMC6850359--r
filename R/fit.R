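#' Fit the joint count model by MCMC
#'
#' Runs the adaptive Metropolis-within-Gibbs sampler (compiled in C++) for
#' the hierarchical multivariate count model under the family, covariance
#' prior and regularization level of the configuration. The default
#' contract is 5 chains of 4,000 iterations, half warm-up, i.e. 10,000
#' retained draws; reduced-scale overrides are simply smaller `chains` /
#' `iter` values in the configuration and are recorded in the returned
#' object.
#'
#' Counts must be integers for the count likelihoods; fractional
#' (Starling-corrected) counts are discretized according to
#' `config$round_policy` (default: round to nearest, ties up).
#'
#' After sampling, split R-hat is computed for the monitored
#' hyper-parameters; any value above 1.01 flags the run (a `message` is
#' emitted and the `flagged` field set). The sampler is not
#' Hamiltonian, so divergence counts and energy diagnostics do not exist
#' and are reported as `NA`.
#'
#' @param counts count table ([aggregate_counts()] or compatible
#'   data.frame).
#' @param design design matrix from [build_design_matrix()]; rows must
#'   correspond to the sites of `counts` (matched by rownames when present,
#'   otherwise by sorted site order).
#' @param config a [jsdm_config()].
#' @return Object of class `"jsdm_fit"`: list with elements `draws`
#'   (matrix, retained draws x parameters, named columns), `chain`
#'   (chain index per draw), `loglik` (draws x observations pointwise
#'   log-likelihood matrix), `diagnostics` (from [convergence_report()]),
#'   `flagged`, `levels` (site/observer/species labels), `coef_names`,
#'   `config`, `counts`, `design`, and sampler metadata (`seed`,
#'   `divergences = NA`, `ebfmi = NA`).
#' @export
fit_model <- function(counts, design, config = jsdm_config()) {
  fr <- as_model_frame(counts)
  lev <- model_levels(counts)
  n <- length(lev$sites); J <- length(lev$species)
  nO <- length(lev$observers)
  X <- as.matrix(design)
  if (nrow(X) != n)
    stop("design has ", nrow(X), " rows but counts cover ", n, " sites")
  if (!is.null(rownames(X)) && all(lev$sites %in% rownames(X)))
    X <- X[match(as.character(lev$sites), rownames(X)), , drop = FALSE]
  K <- ncol(X)

  y <- fr$count
  if (any(abs(y - round(y)) > 1e-9)) {
    if (config$round_policy == "none")
      stop("fractional counts with round_policy = 'none'")
    y <- floor(y + 0.5)  # round half up
  }
  y <- round(y)

  dat <- list(X = X, y = as.numeric(y), site = fr$site - 1L,
              species = fr$species - 1L, observer = fr$observer - 1L,
              log_np = fr$log_np, n = n, J = J, n_observers = nO)
  ccfg <- list(
    family_code = match(config$family, c("poisson", "negbinomial")) - 1L,
    flavor_code = match(config$sigma_prior,
                        c("IW", "SIW", "SSIW", "SSLKJ")) - 1L,
    scale_mu = config$scale_mu, scale_sigma_b = config$scale_sigma_b,
    scale_sigma_j = config$scale_sigma_j, theta_rate = config$theta_rate,
    scale_sigma_s = config$scale_sigma_s,
    scale_sigma_o = config$scale_sigma_o,
    lkj_shape = config$lkj_shape,
    latent_residual = config$latent_residual,
    include_ranef = config$include_ranef)

  nsv <- sigma_param_length(config$sigma_prior, J)
  base_int <- log(max(mean(y), 0.1) / mean(exp(fr$log_np)))

  set.seed(config$seed)
  draws <- vector("list", config$chains)
  for (ch in seq_len(config$chains)) {
    init <- list(
      mu_B = c(base_int, rep(0, K - 1)) + stats::rnorm(K, 0, 0.05),
      sigma_B = rep(0.5, K) * exp(stats::rnorm(K, 0, 0.1)),
      B = matrix(c(base_int, rep(0, K - 1)) + stats::rnorm(K * J, 0, 0.1),
                 K, J),
      zM = matrix(stats::rnorm(n * J, 0, 0.1), n, J),
      sv = stats::rnorm(max(nsv, 1), 0, 0.05),
      zs = rep(0, n), zo = rep(0, nO),
      sigma_S = 0.3 * exp(stats::rnorm(1, 0, 0.1)),
      sigma_O = 0.3 * exp(stats::rnorm(1, 0, 0.1)),
      log_theta = rep(log(2), J) + stats::rnorm(J, 0, 0.1))
    res <- .run_jsdm_chain(dat, ccfg, config$iter,
                           config$warmup, init)
    draws[[ch]] <- res$draws
  }
  n_keep <- config$iter - config$warmup
  all_draws <- do.call(rbind, draws)
  colnames(all_draws) <- draw_names(K, J, n, nO)
  chain <- rep(seq_len(config$chains), each = n_keep)

  fit <- structure(list(
    draws = all_draws, chain = chain,
    levels = lev, coef_names = colnames(X),
    config = config, counts = counts, design = X,
    seed = config$seed, divergences = NA_integer_, ebfmi = NA_real_),
    class = "jsdm_fit")
  fit$loglik <- pointwise_loglik(fit)
  mon <- monitored_params(fit)
  fit$diagnostics <- convergence_report(fit, parameters = mon)
  bad <- fit$diagnostics$rhat > 1.01 & is.finite(fit$diagnostics$rhat)
  fit$flagged <- any(bad)
  if (fit$flagged)
    message("convergence flag: split R-hat > 1.01 for ",
            paste(utils::head(fit$diagnostics$parameter[bad], 8),
                  collapse = ", "),
            if (sum(bad) > 8) " ..." else "")
  fit
}

sigma_param_length <- function(flavor, J) {
  Jt <- J * (J + 1) / 2; Jp <- J * (J - 1) / 2
  switch(flavor, IW = Jt, SIW = Jt + J, SSIW = Jt + J, SSLKJ = Jp + J)
}

draw_names <- function(K, J, n, nO) {
  c(sprintf("mu_B[%d]", 1:K),
    sprintf("sigma_B[%d]", 1:K),
    sprintf("B[%d,%d]", rep(1:K, J), rep(1:J, each = K)),
    "sigma_S", "sigma_O",
    sprintf("site[%d]", 1:n),
    sprintf("observer[%d]", 1:nO),
    sprintf("theta[%d]", 1:J),
    sprintf("sigma[%d]", 1:J),
    sprintf("Sigma[%d,%d]", rep(1:J, J), rep(1:J, each = J)),
    sprintf("R[%d,%d]", rep(1:J, J), rep(1:J, each = J)),
    sprintf("M[%d,%d]", rep(1:n, J), rep(1:J, each = n)))
}

monitored_params <- function(fit) {
  nm <- colnames(fit$draws)
  mon <- grepl("^(mu_B|sigma_B)\\[", nm) | nm %in% c("sigma_S", "sigma_O")
  if (fit$config$family == "negbinomial") mon <- mon | grepl("^theta\\[", nm)
  if (fit$config$latent_residual) mon <- mon | grepl("^sigma\\[", nm)
  nm[mon]
}

#' Extract draws of a parameter block
#'
#' @param fit a [fit_model()] result.
#' @param name parameter block name (`"mu_B"`, `"B"`, `"Sigma"`, ...) or an
#'   exact column name.
#' @return Matrix of draws (retained draws x matching parameters).
#' @export
draws_of <- function(fit, name) {
  nm <- colnames(fit$draws)
  hit <- nm == name | startsWith(nm, paste0(name, "["))
  if (!any(hit)) stop("no parameter matches '", name, "'")
  fit$draws[, hit, drop = FALSE]
}

# pointwise log-likelihood (draws x observations), for WAIC
pointwise_loglik <- function(fit) {
  fr <- as_model_frame(fit$counts)
  y <- fr$count
  if (any(abs(y - round(y)) > 1e-9)) y <- floor(y + 0.5)
  n <- length(fit$levels$sites); J <- length(fit$levels$species)
  nb <- fit$config$family == "negbinomial"
  d <- fit$draws
  Mcols <- sprintf("M[%d,%d]", fr$site, fr$species)
  sitecols <- sprintf("site[%d]", fr$site)
  obscols <- sprintf("observer[%d]", fr$observer)
  Mi <- d[, Mcols, drop = FALSE]
  lmu <- Mi + d[, sitecols, drop = FALSE] + d[, obscols, drop = FALSE] +
    matrix(fr$log_np, nrow(d), length(y), byrow = TRUE)
  ymat <- matrix(y, nrow(d), length(y), byrow = TRUE)
  if (nb) {
    th <- d[, sprintf("theta[%d]", fr$species), drop = FALSE]
    ll <- stats::dnbinom(ymat, size = th, mu = exp(lmu), log = TRUE)
  } else {
    ll <- stats::dpois(ymat, exp(lmu), log = TRUE)
  }
  dimnames(ll) <- NULL
  ll
}

#' @export
print.jsdm_fit <- function(x, ...) {
  cat("joint count model fit\n")
  cat(sprintf("  %d species, %d sites, %d observations\n",
              length(x$levels$species), length(x$levels$sites),
              ncol(x$loglik)))
  cat(sprintf("  family %s, Sigma prior %s, %d chain(s) x %d iterations\n",
              x$config$family, x$config$sigma_prior, x$config$chains,
              x$config$iter))
  cat(sprintf("  %d retained draws; max split R-hat %.3f%s\n",
              nrow(x$draws), max(x$diagnostics$rhat, na.rm = TRUE),
              if (isTRUE(x$flagged)) " [FLAGGED]" else ""))
  invisible(x)
}

#' Convergence diagnostics
#'
#' Split R-hat (each chain halved, potential scale reduction over the
#' resulting sequences), effective sample size (via [coda::effectiveSize()]
#' summed over chains), and -- for samplers that define them -- divergence
#' counts and energy diagnostics per chain. This package's
#' Metropolis-within-Gibbs sampler has no divergences or energy, so those
#' columns are `NA`. With a single chain, R-hat is not defined and is
#' reported as `NA`.
#'
#' @param fit a `jsdm_fit`, or a numeric matrix of draws (iterations x
#'   parameters) with `chain` supplied.
#' @param chain integer vector of chain indices (rows of the matrix).
#' @param parameters optional character vector restricting the report.
#' @return data.frame: `parameter`, `rhat`, `ess`, `divergences`, `ebfmi`.
#' @export
convergence_report <- function(fit, chain = NULL, parameters = NULL) {
  if (inherits(fit, "jsdm_fit")) {
    draws <- fit$draws; chain <- fit$chain
  } else {
    draws <- as.matrix(fit)
    if (is.null(chain)) chain <- rep(1L, nrow(draws))
  }
  if (!is.null(parameters)) {
    keep <- colnames(draws) %in% parameters
    draws <- draws[, keep, drop = FALSE]
  }
  nch <- length(unique(chain))
  rhat <- apply(draws, 2, split_rhat, chain = chain)
  ess <- apply(draws, 2, function(x) {
    if (all(!is.finite(x)) || stats::var(x) == 0) return(NA_real_)
    sum(vapply(split(x, chain),
               function(xc) as.numeric(coda::effectiveSize(xc)),
               numeric(1)))
  })
  data.frame(parameter = colnames(draws),
             rhat = if (nch >= 2) rhat else NA_real_,
             ess = ess,
             divergences = NA_integer_, ebfmi = NA_real_,
             row.names = NULL)
}

#' Split R-hat for one parameter
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half, so within-chain trends are detected as well as between-chain
#' disagreement. Identical chains give exactly 1.
#'
#' @param x numeric draws.
#' @param chain chain index per element.
#' @return R-hat (NA for a single sequence or degenerate draws).
#' @export
split_rhat <- function(x, chain) {
  seqs <- unlist(lapply(split(x, chain), function(xc) {
    h <- length(xc) %/% 2
    if (h < 2) return(list(xc))
    list(xc[1:h], xc[(h + 1):(2 * h)])
  }), recursive = FALSE)
  seqs <- seqs[lengths(seqs) >= 2]
  m <- length(seqs)
  if (m < 2) return(NA_real_)
  nh <- min(lengths(seqs))
  seqs <- lapply(seqs, function(s) s[1:nh])
  means <- vapply(seqs, mean, numeric(1))
  vars <- vapply(seqs, stats::var, numeric(1))
  W <- mean(vars)
  B <- nh * stats::var(means)
  if (W == 0) return(if (B == 0) 1 else Inf)
  # finite-sample values below 1 are clamped: identical chains give exactly 1
  max(1, sqrt(((nh - 1) / nh * W + B / nh) / W))
}
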