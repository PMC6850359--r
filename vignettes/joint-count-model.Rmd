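---
title: "A joint hierarchical count model for farmland-bird surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A joint hierarchical count model for farmland-bird surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(birdjsdm)
```

## The scientific problem

Farmland birds respond to the intensity and heterogeneity of agricultural
land use, but the candidate drivers — how much of the rotation is under
extensive use (ley and fallow), the quality of that extensive land, the
diversity of crops, the balance of spring- versus autumn-sown crops — are
correlated with each other and with the amount of seminatural habitat in the
landscape. Modelling each species separately wastes the information shared
between species and is fragile for rare species; pooling species into a
single index can mask opposing responses. This package implements the middle
road: a *joint species distribution model* in which all species' counts are
regressed on the same landscape predictors simultaneously, species-specific
coefficients are drawn from a common distribution, and a residual covariance
captures co-variation between species beyond the predictors.

## Predictors

For every 1-km-radius landscape the package computes, from a raw table of
land-use areas (`landscape_predictors()`):

* **FA** — farmland area (ha).
* **LHI** — landscape heterogeneity index:
  $\mathrm{LHI} = \tfrac{\sqrt{2}}{2}(z_{\sqrt{\text{pasture}}} +
  z_{\text{border}})$, the first-principal-component score of the
  square-root-transformed seminatural-pasture proportion and the
  field-border proportion, standardized against a *representative*
  landscape set (`reference_stats()`) rather than the study sample. Field
  borders are taken to be 1 m wide, so border length (m) equals border area
  (m²).
* **PE** — proportion extensive cropping: (ley + fallow) / arable area.
* **EQ** — extensive quality:
  $\sqrt{(\text{fallow} + \text{non-managed ley}) / (\text{fallow} +
  \text{all ley})}$. The square root applies to the ratio, not its
  components. Landscapes with no extensive land have an undefined ratio;
  they receive a configurable imputation (default 0) with a warning, making
  the handling explicit.
* **CD** — crop diversity: the exponential of the Shannon entropy of the 13
  structural crop-type areas (a Hill number of order 1, i.e. the *effective
  number of crop types*, in [1, 13]). The effective-number scale is the
  appropriate one here: observed crop diversities well above $\ln 13
  \approx 2.56$ only make sense as Hill numbers, and the effective-number
  convention is standard for diversity comparisons.
* **PSS** — proportion of cereals and oil-seed rape that is spring sown.

Collinearity among predictors is summarized by variance inflation factors
(`variance_inflation()`, $\mathrm{VIF}_k = 1/(1-R^2_k)$).

## Survey processing

Point-count records pass through three steps (`filter_by_distance()`,
`starling_correction()`, `aggregate_counts()`): observations beyond 150 m
are discarded (the boundary is inclusive — "within 150 m" is read as
$\le 150$); Starling counts dated strictly after 4 June are divided by 3,
because post-fledging flocks are roughly one-third adults (with 4.01
fledged young per pair, the adult fraction is $2/(2+4.01) \approx 1/3$;
`adult_fraction_from_brood()`); and counts are summed over points within
each landscape and visit, zero-filling surveyed-but-unobserved species of
the fixed 15-species farmland set (`farmland_species()`). The number of
points actually surveyed per visit (11–16) is carried along as the offset
source. Corrected Starling counts may be fractional; they are kept
fractional in the count table and discretized only at the likelihood
(default: round to nearest, ties up), so the provenance of a correction
stays visible and no other records are silently changed.

`max_over_visits()` provides the maximum-over-visits summary used for
descriptive totals; it is never a model input — the model uses both visits.

## The model

With sites $i = 1..n$, species $j = 1..J$, visits $v$, observers $o$:

$$
\begin{aligned}
X_i B &= \beta_0 + \beta_1 FA_i + \beta_2 LHI_i + \beta_3 PE_i +
\beta_4 EQ_i + \beta_5 CD_i + \beta_6 PSS_i \\
&\quad + \beta_7 LHI_i\!\times\!PE_i + \beta_8 LHI_i\!\times\!EQ_i +
\beta_9 LHI_i\!\times\!CD_i + \beta_{10} LHI_i\!\times\!PSS_i \\
M_i &\sim N^J(X_i B,\ \Sigma) \\
Y_{ivj} &\sim F\!\left(\exp(M_{ij} + site_i + observer_{o(i,v)} +
\log npoints_{iv}),\ \theta_j\right) \\
B_{kj} &\sim N(\mu_{B(k)},\ \sigma^2_{B(k)}), \qquad
site_i \sim N(0, \sigma^2_S), \qquad observer_o \sim N(0, \sigma^2_O)
\end{aligned}
$$

$F$ is Poisson (variance = mean, $\theta_j \equiv 1$) or negative binomial
parameterized as a gamma–Poisson mixture with shape $\theta_j$, so that
$\mathrm{Var} = \mu + \mu^2/\theta_j$. Non-intercept design columns are
standardized within the dataset and interactions are formed from the
standardized components (`build_design_matrix()`), so coefficients are per
predictor SD; the raw-unit SDs are kept as column metadata for reporting
(e.g. "per 45 ha of farmland").

Indexing conventions that the displayed equations leave implicit are
resolved as follows: the latent $M$ is per (site, species) and shared by
the two visits; site and observer effects are scalar per site/observer and
common across species (the single variance components $\sigma^2_S,
\sigma^2_O$ imply species-common effects); the subscript in the prior line
for the site effect is read as a per-site index. The intercept row of $B$
receives the same hierarchical prior as the slopes.

### Priors and the four covariance constructions

Hyper-priors come in two regularization levels: weak —
$\mu_{B(k)} \sim N(0, 100^2)$, SD-type parameters $\sim$ Cauchy⁺(0, 5),
$1/\theta_j \sim$ Exp(0.5) — and strong — $N(0, 10^2)$, Cauchy⁺(0, 2.5),
Exp(1). The random-effect SDs always carry Cauchy⁺(0, 2.5). Individual
scales can be overridden in `jsdm_config()`, e.g. to combine weakly
regularized coefficients with the more informative Exp(1) dispersion prior.

The residual covariance $\Sigma$ admits four constructions
(`sample_sigma_prior()` draws from each):

* **IW**: $\Sigma \sim \mathrm{invWishart}(J+1, I)$;
* **SIW**: $\Sigma = \Delta Q \Delta$ with
  $Q \sim \mathrm{invWishart}(J+1, I)$, $\xi_j \sim N^+(0,1)$,
  $\Delta = \mathrm{diag}(\xi)$;
* **SSIW** (separation strategy): the correlation matrix is extracted from
  an inverse-Wishart draw, $R = \Delta_Q Q \Delta_Q$ with
  $\Delta_Q = \mathrm{diag}(1/\sqrt{Q_{jj}})$, and recombined with
  half-Cauchy SDs;
* **SSLKJ**: $R \sim \mathrm{LKJ}(1)$ (uniform over correlation matrices)
  with half-Cauchy SDs.

The inverse-Wishart couples variances with correlations (large variances
drag correlations away from zero); the separation strategies break that
coupling, which is why they are offered alongside it and why comparing the
four on the same data is informative.

## Sampling

`fit_model()` runs an adaptive Metropolis-within-Gibbs sampler written in
C++ (Rcpp/RcppArmadillo). The parameterization interweaves complementary
coordinate systems, which is what makes a Gibbs-type sampler viable for
this hierarchy:

* latent abundances are carried as whitened residuals
  ($M = XB + z_M L_\Sigma^\top$), so the covariance parameters can move
  without dragging the latents (non-centered in $\Sigma$);
* the coefficient hyper-mean $\mu_{B(k)}$ has an exact conjugate Gibbs
  update given $B$, and an additional joint "shift" move proposes moving
  $\mu_{B(k)}$ and the whole row $B_{k\cdot}$ together against the
  likelihood;
* the covariance parameters get both a non-centered sweep (likelihood
  informed) and a centered sweep against the residuals (ancillarity–
  sufficiency interweaving), removing the funnel between residual scales
  and latents;
* likelihood-invariant rotations reallocate mass between the intercept and
  the site/observer effects, and between each site effect and its latent
  row — the classic weakly identified directions of random-effect models;
* $\sigma_B$, $\sigma_S$, $\sigma_O$ are slice-sampled from their centered
  conditionals (no likelihood evaluations).

$\mathrm{LKJ}(\eta)$ is implemented through the C-vine construction:
canonical partial correlations with shifted-Beta priors assemble directly
into the Cholesky factor of $R$; at $\eta = 1$, $J = 2$ the implied
marginal correlation is uniform on $(-1, 1)$, which the tests verify by a
Kolmogorov–Smirnov check. Inverse-Wishart blocks are parameterized by the
Cholesky factor with log diagonal, with the exact transform Jacobians.

Proposal scales adapt toward 44% acceptance during warm-up only, so the
retained chain is Markovian. All randomness flows through R's RNG: the
same seed, data and configuration reproduce draws bit-identically. The
default contract is 5 chains × 4,000 iterations, half warm-up (10,000
retained draws); reduced settings are ordinary configuration values.

Because the sampler is not Hamiltonian there are no divergences or energy
diagnostics; `convergence_report()` reports them as `NA` and relies on
split R-hat (flagging threshold 1.01, with finite-sample values below 1
clamped to exactly 1) and effective sample size. The sampler was validated
against an independent MCMC implementation of the same posterior (JAGS via
`rjags`) on small instances — posterior means agree well within the
posterior spread — and against a closed-form conjugate limit
(intercept-only Poisson with latent residual and random effects disabled).

## Post-posterior analysis

* `waic()` — deviance-scale WAIC, $-2(\mathrm{lppd} - p_{WAIC})$, from the
  pointwise log-likelihood draws; `delta_waic()` pairs the per-observation
  contributions for the SE of a difference.
* `hpd_interval()` — shortest window containing $\lceil 0.95 n \rceil$
  sorted draws; ties broken toward the lower start.
* `p_positive()`, `percent_change()` ($100(e^x - 1)$),
  `combined_effect()` (main + LHI × interaction at the minimum or maximum
  standardized LHI).
* `effect_summary()` — posterior means (medians for SD-type parameters)
  with HPD bounds on the log and percentage scales. Residual SDs are
  translated to percentages as $100(e^{\sigma}-1)$, the same log-link
  transform used for coefficients.
* `residual_correlation_summary()` — per-pair posterior mean correlation,
  HPD, width, and whether the interval excludes zero.

## The synthetic-data generator

`simulate_dataset()` emulates the study conditions end to end so every
stage is testable without the field data: 33 landscapes × 15 species × 2
visits by default, 5 observers rotating so no landscape is visited twice by
the same observer, 11–16 points per visit. Predictors are drawn from a
correlated latent Gaussian matched to the reported predictor means, SDs and
ranges, with low correlation targets so realized VIFs stay below 3 (the
collinearity level a quasi-orthogonal design achieves); fractions are
clipped to [0, 1] (PE floored just above 0 so EQ stays defined), CD to
[1, 13]. A raw land-use table is then *back-constructed* by inverting the
predictor definitions — equal z-scores for the two LHI components, the EQ
ratio split 60/40 between fallow and non-managed ley, crop areas with
geometric shares tuned by root-finding to the CD target — so that running
the predictor pipeline on the raw table reproduces the generated predictor
values exactly (a tested round trip).

Default generative parameters are chosen once to emulate the study system:
species-average effects of a few tens of percent per predictor SD,
between-species coefficient SD 0.25 (1.0 for the intercept, reflecting the
two-orders-of-magnitude abundance differences among farmland species),
diagonal residual covariance with log-scale SD 0.4, dispersion
$\theta = 1.5$, site SD 0.3 and observer SD 0.2, and an intercept placing
median expected counts at a few to a few tens of birds per site and visit —
the order of magnitude of real farmland-bird point counts.

What the generator does **not** emulate: spatially explicit landscape
geometry (and hence spatial autocorrelation), detectability varying with
distance or habitat, temporal trends within the season, and the farm-
centered sampling bias of the original design. Passing recovery tests
therefore show the *inference machinery* is correct and calibrated for data
generated from the assumed model — not that the model is adequate for any
particular field dataset.

## Verification strategy and problem sizes

The test suite checks every summary statistic against an independent
oracle (exhaustive HPD search, hand-computed WAIC, explicit PCA projection
for LHI, $1/(1-R^2)$ regressions for VIF, the Poisson limit of the
negative binomial), validates all four covariance priors (positive
definiteness, unit-diagonal correlations, the LKJ uniformity law), and runs
two simulation studies scaled for a desktop: a parameter-recovery study
(20 replicates, 30 sites × 5 species, negative binomial + SSLKJ, 2 chains ×
1,000 iterations) whose 95% HPD coverage of the coefficient hyper-means
must be statistically compatible with 0.95, and a model-comparison study
(20 replicates of strongly overdispersed data, $\theta = 0.8$) in which the
negative-binomial model must beat Poisson in WAIC at least 19 times of 20.
These sizes keep a full run in a few minutes while leaving the binomial
coverage test enough trials (220) to detect meaningful miscalibration.
`scripts/acceptance.R` reruns the same quantities from scratch under a
user-supplied seed.

## Known limitations

* The sampler's scalar updates mix more slowly than gradient-based
  samplers for strongly correlated posteriors; for final inferences at
  full scale, use the default 5 × 4,000 contract and check the reported
  R-hat and ESS rather than shortened chains.
* The LKJ prior density is evaluated up to its normalizing constant
  (constant in the parameters), so `joint_logdensity()` under SSLKJ is an
  unnormalized kernel; all differences and MCMC uses are unaffected.
* EQ's imputation for landscapes with no extensive land (default 0) is a
  modelling choice; sensitivity can be checked via the `eq_undefined`
  argument.
* `space_filling_selection()` is a greedy maximin heuristic; it spreads
  points well but is not an optimal design algorithm.
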