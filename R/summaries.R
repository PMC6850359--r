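#' Widely applicable information criterion
#'
#' WAIC on the deviance scale from a pointwise log-likelihood matrix:
#' `lppd = sum over observations of log(mean over draws of the
#' likelihood)`, `p_waic = sum of the per-observation variance of the
#' log-likelihood over draws`, `WAIC = -2 (lppd - p_waic)`. The standard
#' error is `sqrt(n_obs * var(pointwise WAIC contributions))`.
#'
#' @param loglik matrix of pointwise log likelihoods, draws x observations
#'   (as in `fit$loglik`), or a `jsdm_fit`.
#' @return List with `waic`, `se`, `lppd`, `p_waic` and the per-observation
#'   vector `pointwise`.
#' @export
waic <- function(loglik) {
  if (inherits(loglik, "jsdm_fit")) loglik <- loglik$loglik
  loglik <- as.matrix(loglik)
  if (any(!is.finite(loglik))) stop("non-finite log-likelihood entries")
  # column-wise log-mean-exp with stabilizing shift
  mx <- apply(loglik, 2, max)
  lppd_i <- mx + log(colMeans(exp(sweep(loglik, 2, mx))))
  p_i <- apply(loglik, 2, stats::var)
  pointwise <- -2 * (lppd_i - p_i)
  n <- ncol(loglik)
  list(waic = sum(pointwise), se = sqrt(n * stats::var(pointwise)),
       lppd = sum(lppd_i), p_waic = sum(p_i), pointwise = pointwise)
}

#' WAIC difference between two models
#'
#' Difference of WAICs for two models fitted to the *same* observations,
#' with a standard error from the paired per-observation WAIC differences
#' (`se = sqrt(n * var(pointwise_A - pointwise_B))`), which respects the
#' pairing in the data.
#'
#' @param model_a,model_b `jsdm_fit` objects or pointwise log-likelihood
#'   matrices over identical observation sets.
#' @return List with `delta_waic` (A minus B), `se`, and the two [waic()]
#'   results.
#' @export
delta_waic <- function(model_a, model_b) {
  wa <- waic(model_a); wb <- waic(model_b)
  if (length(wa$pointwise) != length(wb$pointwise))
    stop("models were fitted to different observation sets")
  d <- wa$pointwise - wb$pointwise
  list(delta_waic = wa$waic - wb$waic,
       se = sqrt(length(d) * stats::var(d)),
       waic_a = wa, waic_b = wb)
}

#' Highest posterior density interval
#'
#' The shortest contiguous interval containing `ceiling(mass * n)` of the
#' sorted draws; ties in width are broken toward the lower window start.
#' For unimodal posteriors this estimates the HPD credible interval and is
#' never wider than the equal-tail interval computed from the same draws.
#'
#' @param draws numeric vector of posterior draws (>= 2).
#' @param mass probability mass in (0, 1), default 0.95.
#' @return Named vector `c(lower, upper)`.
#' @export
hpd_interval <- function(draws, mass = 0.95) {
  draws <- draws[is.finite(draws)]
  n <- length(draws)
  if (n < 2) stop("need at least 2 draws")
  if (mass <= 0 || mass >= 1) stop("mass must be in (0, 1)")
  x <- sort(draws)
  m <- ceiling(mass * n)
  if (m >= n) return(c(lower = x[1], upper = x[n]))
  starts <- 1:(n - m + 1)
  widths <- x[starts + m - 1] - x[starts]
  i <- which.min(widths)  # which.min takes the first (lowest) minimizer
  c(lower = x[i], upper = x[i + m - 1])
}

#' Posterior probability of a positive effect
#'
#' Fraction of draws strictly greater than zero.
#'
#' @param draws numeric vector of posterior draws.
#' @return Probability in `[0, 1]`.
#' @export
p_positive <- function(draws) {
  if (!length(draws)) stop("need at least 1 draw")
  mean(draws > 0)
}

#' Log-scale effect to percentage change
#'
#' Converts log-link effects to the percentage change in expected
#' abundance: `100 * (exp(x) - 1)`. Applied draw-wise before summarizing.
#'
#' @param x log-scale value(s) or draws.
#' @return Percentage change(s).
#' @export
percent_change <- function(x) {
  if (any(!is.finite(x))) stop("non-finite input")
  100 * (exp(x) - 1)
}

#' Combined main + interaction effect at a given heterogeneity level
#'
#' For predictors interacting with the landscape heterogeneity index, the
#' effect at a specific (standardized) LHI value is the draw-wise sum
#' `main + lhi_value * interaction`. Typically evaluated at the minimum and
#' maximum standardized LHI of the dataset (the least and most
#' heterogeneous landscapes).
#'
#' @param main_draws,interaction_draws equal-length draw vectors.
#' @param lhi_value LHI on the standardized scale of the design matrix.
#' @return Draw vector of combined effects.
#' @export
combined_effect <- function(main_draws, interaction_draws, lhi_value) {
  if (length(main_draws) != length(interaction_draws))
    stop("draw vectors have different lengths")
  main_draws + lhi_value * interaction_draws
}

#' Posterior summaries of species-average and species-level effects
#'
#' Summarizes the coefficient hyper-means (posterior mean, 95% HPD,
#' p_positive, and the same on the percentage scale), the between-species
#' effect SDs (posterior median, with the percentage translation
#' `100 * (exp(sigma) - 1)`), and -- for land-use predictors involved in an
#' LHI interaction -- the combined effects at the minimum and maximum
#' standardized LHI of the dataset.
#'
#' @param fit a [fit_model()] result.
#' @param mass HPD mass (default 0.95).
#' @param lhi_range standardized LHI range `c(min, max)`; defaults to the
#'   `lhi_range_std` attribute recorded by [build_design_matrix()].
#' @return data.frame with columns `parameter`, `lhi` (`"min"`, `"max"` or
#'   `NA`), `estimate` (log scale; mean, or median for SD-type rows),
#'   `hpd_lower`, `hpd_upper`, `p_positive`, `pct`, `pct_lower`,
#'   `pct_upper`.
#' @export
effect_summary <- function(fit, mass = 0.95, lhi_range = NULL) {
  if (is.null(lhi_range)) lhi_range <- attr(fit$design, "lhi_range_std")
  if (is.null(lhi_range)) stop("lhi_range not supplied and not recorded")
  cn <- fit$coef_names
  K <- length(cn)
  rows <- list()
  add <- function(name, lhi, draws, sd_type = FALSE) {
    h <- hpd_interval(draws, mass)
    ph <- hpd_interval(percent_change(draws), mass)
    rows[[length(rows) + 1]] <<- data.frame(
      parameter = name, lhi = lhi,
      estimate = if (sd_type) stats::median(draws) else mean(draws),
      hpd_lower = h[["lower"]], hpd_upper = h[["upper"]],
      p_positive = p_positive(draws),
      pct = if (sd_type) percent_change(stats::median(draws))
            else mean(percent_change(draws)),
      pct_lower = ph[["lower"]], pct_upper = ph[["upper"]])
  }
  mu <- draws_of(fit, "mu_B"); sb <- draws_of(fit, "sigma_B")
  inter <- grepl("^LHI:", cn)
  for (k in seq_len(K)) {
    add(paste0("mu_", cn[k]), NA_character_, mu[, k])
    add(paste0("sigma_", cn[k]), NA_character_, sb[, k], sd_type = TRUE)
  }
  for (k in which(inter)) {
    main <- sub("^LHI:", "", cn[k])
    km <- match(main, cn)
    for (lhi in c("min", "max")) {
      v <- if (lhi == "min") lhi_range[1] else lhi_range[2]
      add(paste0("mu_", main), lhi, combined_effect(mu[, km], mu[, k], v))
    }
  }
  do.call(rbind, rows)
}

#' Residual correlation and variance summaries
#'
#' Posterior summaries of the between-species residual correlations and
#' the species residual SDs: per species pair, the posterior mean
#' correlation, 95% HPD bounds, interval width and whether the interval
#' excludes zero; per species, the posterior median residual SD on the log
#' scale and translated to a percentage (`100 * (exp(sigma) - 1)`).
#'
#' @param fit a `jsdm_fit`, or a list of covariance-matrix draws.
#' @param mass HPD mass.
#' @return List with data.frames `correlations` (`species_1`, `species_2`,
#'   `mean`, `hpd_lower`, `hpd_upper`, `width`, `excludes_zero`) and
#'   `sd` (`species`, `sigma_median`, `sigma_lower`, `sigma_upper`,
#'   `pct_median`, `pct_lower`, `pct_upper`).
#' @export
residual_correlation_summary <- function(fit, mass = 0.95) {
  if (inherits(fit, "jsdm_fit")) {
    J <- length(fit$levels$species)
    spp <- as.character(fit$levels$species)
    Rd <- draws_of(fit, "R")
    Sd <- draws_of(fit, "sigma")
    get_r <- function(j1, j2) Rd[, sprintf("R[%d,%d]", j1, j2)]
    get_s <- function(j) Sd[, j]
  } else {
    stopifnot(is.list(fit), length(fit) >= 2)
    J <- nrow(fit[[1]])
    spp <- as.character(seq_len(J))
    decs <- lapply(fit, sigma_to_correlation)
    get_r <- function(j1, j2) vapply(decs, function(d) d$R[j1, j2],
                                     numeric(1))
    get_s <- function(j) vapply(decs, function(d) d$sigma[j], numeric(1))
  }
  pairs <- which(upper.tri(diag(J)), arr.ind = TRUE)
  cor_tab <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(t) {
    j1 <- pairs[t, 1]; j2 <- pairs[t, 2]
    r <- get_r(j1, j2)
    if (stats::var(r) == 0) {
      h <- c(lower = r[1], upper = r[1])
    } else h <- hpd_interval(r, mass)
    data.frame(species_1 = spp[j1], species_2 = spp[j2],
               mean = mean(r), hpd_lower = h[["lower"]],
               hpd_upper = h[["upper"]],
               width = h[["upper"]] - h[["lower"]],
               excludes_zero = h[["lower"]] > 0 | h[["upper"]] < 0)
  }))
  sd_tab <- do.call(rbind, lapply(seq_len(J), function(j) {
    s <- get_s(j)
    h <- if (stats::var(s) == 0) c(lower = s[1], upper = s[1])
         else hpd_interval(s, mass)
    data.frame(species = spp[j], sigma_median = stats::median(s),
               sigma_lower = h[["lower"]], sigma_upper = h[["upper"]],
               pct_median = percent_change(stats::median(s)),
               pct_lower = percent_change(h[["lower"]]),
               pct_upper = percent_change(h[["upper"]]))
  }))
  list(correlations = cor_tab, sd = sd_tab)
}

#' Draws-file I/O
#'
#' Writes the retained draws with their chain and iteration indices to a
#' CSV (columns: `chain`, `iteration`, then one column per parameter) and
#' reads such files back.
#'
#' @param fit a `jsdm_fit` (write) / file path (read).
#' @param path file path.
#' @name draws_io
#' @export
write_draws <- function(fit, path) {
  d <- data.frame(chain = fit$chain,
                  iteration = stats::ave(fit$chain, fit$chain,
                                         FUN = seq_along),
                  fit$draws, check.names = FALSE)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname draws_io
#' @export
read_draws <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  list(draws = as.matrix(d[, -(1:2), drop = FALSE]), chain = d$chain)
}
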