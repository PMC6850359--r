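#' Target moments of the landscape predictors
#'
#' Default means, SDs and ranges used by the synthetic landscape generator,
#' chosen to emulate the distribution of the six predictors across the
#' study region's agricultural landscapes (farmland area in hectares, the
#' heterogeneity index on its PC1 scale, the three proportions as
#' fractions, crop diversity as an effective number of crop types).
#'
#' @return data.frame with columns `var`, `mean`, `sd`, `min`, `max`.
#' @export
predictor_moments <- function() {
  data.frame(
    var  = c("FA", "LHI", "PE", "EQ", "CD", "PSS"),
    mean = c(245.3, 0.124, 0.260, 0.399, 4.481, 0.476),
    sd   = c(45.37, 1.075, 0.196, 0.275, 0.939, 0.186),
    min  = c(137.70, -1.762, 0.00268, 0.0495, 2.938, 0.164),
    max  = c(293.86, 1.843, 0.664, 1.000, 6.398, 0.929))
}

# default latent correlation targets between predictors: low collinearity,
# as produced by the quasi-orthogonal survey design
default_predictor_corr <- function() {
  v <- c("FA", "LHI", "PE", "EQ", "CD", "PSS")
  C <- diag(6); dimnames(C) <- list(v, v)
  C["FA", "LHI"] <- C["LHI", "FA"] <- -0.20
  C["LHI", "PE"] <- C["PE", "LHI"] <- 0.20
  C["PE", "EQ"]  <- C["EQ", "PE"]  <- 0.30
  C["CD", "PSS"] <- C["PSS", "CD"] <- 0.25
  C["PE", "CD"]  <- C["CD", "PE"]  <- -0.15
  C
}

#' Generative truth for synthetic datasets
#'
#' Collects every quantity needed to simulate data from the joint count
#' model: design dimensions, the coefficient hyper-parameters, the residual
#' covariance, dispersions, random-effect SDs and the predictor target
#' moments. Defaults emulate the study conditions: 33 landscapes x 15
#' species x 2 visits, 5 observers, 11-16 points per visit, predictor
#' moments as in [predictor_moments()], hierarchical species coefficients
#' with species-average effects of the order reported for farmland birds
#' (tens of percent per predictor SD), moderate between-species variation,
#' diagonal residual covariance with log-scale SD 0.4, negative-binomial
#' overdispersion theta = 1.5, and expected counts of a few to a few tens
#' of birds per visit.
#'
#' @param n_sites,J,visits,n_observers design dimensions.
#' @param npoints_range integer range of surveyed points per visit.
#' @param mu_B,sigma_B length-11 hyper-parameters (design-matrix column
#'   order: intercept, FA, LHI, PE, EQ, CD, PSS, then the four LHI
#'   interactions).
#' @param Sigma `J x J` residual covariance (default `0.4^2 * I`).
#' @param theta length-J dispersion (recycled), used when
#'   `family = "negbinomial"`.
#' @param sigma_S,sigma_O random-effect SDs.
#' @param family observation family.
#' @param moments predictor target moments ([predictor_moments()] layout).
#' @param corr latent predictor correlation matrix.
#' @param seed integer seed.
#' @return Object of class `"jsdm_truth"`.
#' @export
jsdm_truth <- function(n_sites = 33, J = 15, visits = 2, n_observers = 5,
                       npoints_range = c(11, 16),
                       mu_B = c(-1.0, 0.29, 0.12, 0.30, -0.03, 0.20, 0.05,
                                -0.25, 0.00, -0.15, -0.05),
                       sigma_B = c(1.0, rep(0.25, 10)),
                       Sigma = NULL, theta = 1.5,
                       sigma_S = 0.3, sigma_O = 0.2,
                       family = c("negbinomial", "poisson"),
                       moments = predictor_moments(),
                       corr = default_predictor_corr(),
                       seed = 1) {
  family <- match.arg(family)
  if (is.null(Sigma)) Sigma <- diag(0.4^2, J)
  stopifnot(length(mu_B) == 11, length(sigma_B) == 11, all(sigma_B > 0),
            nrow(Sigma) == J, sigma_S > 0, sigma_O > 0,
            n_sites >= 2, J >= 1, visits >= 1,
            npoints_range[1] >= 1, npoints_range[2] >= npoints_range[1])
  theta <- rep(theta, length.out = J)
  stopifnot(all(theta > 0))
  out <- list(n_sites = n_sites, J = J, visits = visits,
              n_observers = n_observers, npoints_range = npoints_range,
              mu_B = mu_B, sigma_B = sigma_B, Sigma = Sigma, theta = theta,
              sigma_S = sigma_S, sigma_O = sigma_O, family = family,
              moments = moments, corr = corr, seed = as.integer(seed))
  class(out) <- "jsdm_truth"
  out
}

#' Generate synthetic landscape predictors
#'
#' Draws the six predictors from a correlated latent Gaussian with the
#' target means and SDs, then clips to their natural domains (fractions to
#' `[0, 1]`, crop diversity to `[1, 13]`, farmland area to positive
#' values). With the default low-correlation targets the realized variance
#' inflation factors stay below 3, matching the collinearity level the
#' quasi-orthogonal design achieves.
#'
#' @param truth a [jsdm_truth()] (its `moments`, `corr`, `n_sites` are
#'   used), or `NULL` to use defaults with `n_sites`.
#' @param n_sites number of landscapes (overrides `truth`).
#' @return data.frame `site_id`, `FA`, `LHI`, `PE`, `EQ`, `CD`, `PSS`.
#' @export
generate_predictors <- function(truth = NULL, n_sites = NULL) {
  if (is.null(truth)) truth <- jsdm_truth()
  n <- if (is.null(n_sites)) truth$n_sites else n_sites
  mo <- truth$moments
  C <- truth$corr
  ch <- tryCatch(chol(C), error = function(e)
    stop("infeasible predictor correlation targets (not positive-definite)"))
  Z <- matrix(stats::rnorm(n * 6), n, 6) %*% ch
  X <- sweep(sweep(Z, 2, mo$sd, "*"), 2, mo$mean, "+")
  colnames(X) <- mo$var
  # PE floored just above 0: real landscapes retain a trace of ley/fallow,
  # and a strictly positive extensive area keeps EQ well defined
  X[, "PE"] <- pmin(pmax(X[, "PE"], 0.002), 1)
  X[, "EQ"] <- pmin(pmax(X[, "EQ"], 0), 1)
  X[, "PSS"] <- pmin(pmax(X[, "PSS"], 0), 1)
  X[, "CD"] <- pmin(pmax(X[, "CD"], 1), 13)
  X[, "FA"] <- pmax(X[, "FA"], 1)
  data.frame(site_id = seq_len(n), X)
}

#' Space-filling landscape selection
#'
#' Greedy maximin selection of `n_select` candidates in a two-dimensional
#' plane (typically expected ley proportion x landscape heterogeneity):
#' coordinates are standardized, the most mutually distant pair is chosen
#' first, then each step adds the candidate maximizing its minimum distance
#' to the already-selected set. This emulates picking study landscapes that
#' cover as much as possible of the two-dimensional design space.
#'
#' @param candidates data.frame or matrix with two numeric columns.
#' @param n_select number of landscapes to select (<= candidates).
#' @return Integer vector of selected row indices.
#' @export
space_filling_selection <- function(candidates, n_select) {
  X <- as.matrix(candidates)[, 1:2, drop = FALSE]
  n <- nrow(X)
  stopifnot(n_select >= 1, n_select <= n)
  if (n_select == n) return(seq_len(n))
  s <- apply(X, 2, stats::sd)
  if (any(s == 0)) stop("degenerate candidates: a coordinate is constant")
  Z <- scale(X)
  D <- as.matrix(stats::dist(Z))
  first <- which(D == max(D), arr.ind = TRUE)[1, ]
  sel <- as.integer(first)
  if (n_select == 1) return(sel[1])
  mind <- pmin(D[, sel[1]], D[, sel[2]])
  while (length(sel) < n_select) {
    mind[sel] <- -Inf
    nxt <- which.max(mind)
    sel <- c(sel, nxt)
    mind <- pmin(mind, D[, nxt])
  }
  sort(sel)
}

#' Simulate the count table from predictors and a generative truth
#'
#' Draws species coefficients `B` from their hierarchical normal, latent
#' log abundances `M` row-wise from `MVN(XB, Sigma)`, site and observer
#' effects from their normals, observer assignments rotating so that no
#' landscape is visited twice by the same observer, points surveyed per
#' visit uniformly in `npoints_range`, and finally counts from the
#' configured family with the log-points offset. All intermediate latent
#' quantities are returned for parameter-recovery testing.
#'
#' @param predictors a predictor table ([generate_predictors()] or
#'   [landscape_predictors()]).
#' @param truth a [jsdm_truth()].
#' @return List: `counts` (count table), `design`
#'   ([build_design_matrix()] output), and `latent` (list `B`, `M`,
#'   `site_effects`, `observer_effects`, `n_points`).
#' @export
simulate_counts <- function(predictors, truth) {
  X <- build_design_matrix(predictors)
  n <- nrow(X); J <- truth$J; K <- ncol(X)
  B <- matrix(stats::rnorm(K * J, truth$mu_B, truth$sigma_B), K, J)
  eta <- X %*% B
  U <- chol(truth$Sigma)
  M <- eta + matrix(stats::rnorm(n * J), n, J) %*% U
  if (max(M) > 30)
    stop("latent log abundance overflows exp(); lower mu_B[1] or SDs")
  site <- stats::rnorm(n, 0, truth$sigma_S)
  obs <- stats::rnorm(truth$n_observers, 0, truth$sigma_O)
  grid <- expand.grid(site_id = seq_len(n), visit = seq_len(truth$visits))
  # rotate observers: landscape i gets observers (i + v - 1) mod n_observers
  grid$observer_id <- ((grid$site_id + grid$visit - 2) %%
                         truth$n_observers) + 1
  np_vals <- seq(truth$npoints_range[1], truth$npoints_range[2])
  grid$n_points <- np_vals[sample.int(length(np_vals), nrow(grid),
                                      replace = TRUE)]
  long <- merge(grid, data.frame(species = seq_len(J)), by = NULL)
  mu <- exp(M[cbind(long$site_id, long$species)] + site[long$site_id] +
              obs[long$observer_id] + log(long$n_points))
  long$count <- if (truth$family == "poisson") stats::rpois(nrow(long), mu)
    else stats::rnbinom(nrow(long), size = truth$theta[long$species],
                        mu = mu)
  long$species <- sprintf("sp%02d", long$species)
  counts <- long[order(long$site_id, long$visit, long$species),
                 c("site_id", "visit", "observer_id", "n_points",
                   "species", "count")]
  rownames(counts) <- NULL
  class(counts) <- c("count_table", "data.frame")
  list(counts = counts, design = X,
       latent = list(B = B, M = M, site_effects = site,
                     observer_effects = obs,
                     n_points = grid))
}

#' Simulate a complete synthetic dataset
#'
#' End-to-end generator: landscape predictors are drawn from their target
#' moments, a raw land-use table is back-constructed so that running the
#' predictor pipeline ([landscape_predictors()]) on it reproduces the
#' generated predictor values, and counts are simulated from the model.
#' Regeneration with the same seed is bit-identical.
#'
#' @param truth a [jsdm_truth()].
#' @param seed overrides `truth$seed`.
#' @return List of class `"jsdm_dataset"`: `raw` (raw landscape table),
#'   `ref` (the [reference_stats()] used), `predictors`, `counts`,
#'   `design`, `latent`, `truth`.
#' @export
simulate_dataset <- function(truth = jsdm_truth(), seed = NULL) {
  set.seed(if (is.null(seed)) truth$seed else seed)
  pred <- generate_predictors(truth)
  ref <- synthetic_reference()
  raw <- raw_from_predictors(pred, ref)
  sim <- simulate_counts(pred, truth)
  out <- list(raw = raw, ref = ref, predictors = pred,
              counts = sim$counts, design = sim$design,
              latent = sim$latent, truth = truth)
  class(out) <- "jsdm_dataset"
  out
}

# fixed reference statistics of the synthetic representative landscape set
synthetic_reference <- function() {
  structure(list(mean_sqrt_pasture = 0.25, sd_sqrt_pasture = 0.10,
                 mean_border = 0.020, sd_border = 0.008),
            class = "reference_stats")
}

# invert the predictor definitions into a plausible raw land-use table;
# exact inverse so the predictor pipeline round-trips
raw_from_predictors <- function(pred, ref) {
  n <- nrow(pred)
  # LHI: put both components at the same z-score z = LHI / sqrt(2)
  z <- pred$LHI / sqrt(2)
  sqrtp <- pmin(pmax(ref$mean_sqrt_pasture + z * ref$sd_sqrt_pasture,
                     0.01), 0.99)
  border <- pmin(pmax(ref$mean_border + z * ref$sd_border, 1e-4), 0.2)
  # recompute the achievable LHI after clamping (clamping is essentially
  # never active under the default moments)
  lhi <- compute_lhi(sqrtp^2, border, ref)
  FA <- pred$FA
  arable <- FA * (1 - sqrtp^2 - border)
  ext <- pred$PE * arable                  # ley + fallow
  q <- pred$EQ^2                           # (fallow + nonmanaged) share
  fallow <- 0.6 * q * ext
  nonmanaged <- 0.4 * q * ext
  ley <- ext - fallow
  # crop areas: geometric shares over 13 types tuned to the CD target
  rest <- pmax(arable - ext, 1e-6)
  crops <- t(vapply(pred$CD, function(cd) geometric_shares(cd, 13),
                    numeric(13)))
  crops <- crops * rest
  colnames(crops) <- sprintf("crop%02d", 1:13)
  # types 1-4 are the cereals and oil-seed rape
  total_cosr <- pmax(rowSums(crops[, 1:4, drop = FALSE]), 1e-8)
  raw <- data.frame(
    site_id = pred$site_id,
    farmland_area = FA,
    pasture_prop = sqrtp^2,
    border_prop = border,
    ley_area = ley, fallow_area = fallow,
    nonmanaged_ley_area = nonmanaged,
    arable_area = arable,
    spring_cereal_osr_area = pred$PSS * total_cosr,
    total_cereal_osr_area = total_cosr,
    ley_prev1 = ley * 0.9, ley_prev2 = ley, ley_prev3 = ley * 1.1)
  cbind(raw, crops, data.frame(LHI_check = lhi))[
    , c(names(raw), colnames(crops))]
}

# shares p_t proportional to w^(t-1) whose Hill-Shannon diversity equals cd
geometric_shares <- function(cd, n_types) {
  stopifnot(cd >= 1, cd <= n_types)
  if (cd >= n_types - 1e-9) return(rep(1 / n_types, n_types))
  if (cd <= 1 + 1e-9) return(c(1, rep(0, n_types - 1)))
  hill <- function(w) {
    p <- w^(0:(n_types - 1)); p <- p / sum(p)
    p <- p[p > 0]
    exp(-sum(p * log(p)))
  }
  w <- stats::uniroot(function(w) hill(w) - cd, c(1e-8, 1 - 1e-12),
                      tol = 1e-12)$root
  p <- w^(0:(n_types - 1))
  p / sum(p)
}

#' Write a synthetic dataset to CSV files
#'
#' Writes `raw_landscapes.csv`, `predictors.csv`, `counts.csv` and
#' `truth.yaml` (the generative parameter values, for recovery testing)
#' into a directory.
#'
#' @param dataset a [simulate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(dataset$raw, file.path(dir, "raw_landscapes.csv"),
                   row.names = FALSE)
  write_predictors(dataset$predictors, file.path(dir, "predictors.csv"))
  write_count_table(dataset$counts, file.path(dir, "counts.csv"))
  tr <- dataset$truth
  tr$Sigma <- as.vector(tr$Sigma)
  tr$corr <- as.vector(tr$corr)
  tr$moments <- NULL
  yaml::write_yaml(unclass(tr), file.path(dir, "truth.yaml"))
  invisible(dir)
}

#' Parameter-recovery report
#'
#' Compares a posterior sample against the generative truth: for each
#' hyper-parameter (and optionally every species coefficient), the true
#' value, posterior mean and median, 95% HPD bounds, whether the interval
#' covers the truth, and the standardized bias
#' `(posterior mean - truth) / posterior SD`.
#'
#' @param truth a [jsdm_truth()]; for coefficient-level rows the realized
#'   `B` draw must be supplied via `latent` (from [simulate_counts()]).
#' @param fit a [fit_model()] result on data generated under `truth`.
#' @param latent optional `latent` element of [simulate_counts()].
#' @param mass HPD mass.
#' @return data.frame: `parameter`, `true`, `post_mean`, `post_median`,
#'   `hpd_lower`, `hpd_upper`, `covered`, `std_bias`; with an attribute
#'   `coverage` giving the aggregate coverage rate.
#' @export
recovery_report <- function(truth, fit, latent = NULL, mass = 0.95) {
  K <- length(truth$mu_B)
  tru <- c(stats::setNames(truth$mu_B, sprintf("mu_B[%d]", 1:K)),
           stats::setNames(truth$sigma_B, sprintf("sigma_B[%d]", 1:K)),
           sigma_S = truth$sigma_S, sigma_O = truth$sigma_O)
  if (fit$config$family == "negbinomial" && truth$family == "negbinomial")
    tru <- c(tru, stats::setNames(truth$theta,
                                  sprintf("theta[%d]", 1:truth$J)))
  if (fit$config$latent_residual)
    tru <- c(tru, stats::setNames(sqrt(diag(truth$Sigma)),
                                  sprintf("sigma[%d]", 1:truth$J)))
  if (!is.null(latent)) {
    Bn <- sprintf("B[%d,%d]", rep(1:K, truth$J), rep(1:truth$J, each = K))
    tru <- c(tru, stats::setNames(as.vector(latent$B), Bn))
  }
  missing <- setdiff(names(tru), colnames(fit$draws))
  if (length(missing))
    stop("parameters absent from the posterior sample: ",
         paste(missing, collapse = ", "))
  rows <- lapply(names(tru), function(nm) {
    x <- fit$draws[, nm]
    h <- hpd_interval(x, mass)
    data.frame(parameter = nm, true = tru[[nm]],
               post_mean = mean(x), post_median = stats::median(x),
               hpd_lower = h[["lower"]], hpd_upper = h[["upper"]],
               covered = tru[[nm]] >= h[["lower"]] &
                         tru[[nm]] <= h[["upper"]],
               std_bias = (mean(x) - tru[[nm]]) /
                 max(stats::sd(x), .Machine$double.eps))
  })
  out <- do.call(rbind, rows)
  attr(out, "coverage") <- mean(out$covered)
  out
}
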