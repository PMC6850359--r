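# birdjsdm

Joint species distribution modelling of farmland-bird point counts along
agricultural land-use gradients.

## What it does, and for whom

Ecologists evaluating agri-environment measures need to know how bird
abundances respond to reversible aspects of agricultural intensification —
the share of ley and fallow in the rotation, the quality of that extensive
land, crop diversity, the spring/autumn sowing balance — against a backdrop
of landscape heterogeneity (seminatural pastures, field borders). Because
the 15 focal farmland species range from very common to rare, and because
species may co-vary for reasons outside the predictors, the counts are
modelled **jointly**: one hierarchical multivariate count regression instead
of 15 fragile single-species models.

The model, for site *i*, species *j*, visit *v*:

```
X_i B   = b0 + b1 FA + b2 LHI + b3 PE + b4 EQ + b5 CD + b6 PSS
          + b7 LHI:PE + b8 LHI:EQ + b9 LHI:CD + b10 LHI:PSS
M_i     ~ MVN_J(X_i B, Sigma)                      (latent log abundance)
Y_ivj   ~ F(exp(M_ij + site_i + observer_o(i,v) + log npoints_iv), theta_j)
B_kj    ~ N(mu_B(k), sigma_B(k)^2)                 (hierarchical coefficients)
site_i  ~ N(0, sigma_S^2);   observer_o ~ N(0, sigma_O^2)
```

with `F` Poisson or negative binomial (`Var = mu + mu^2/theta_j`), and four
alternative priors for the residual covariance `Sigma`: inverse-Wishart
(IW), scaled inverse-Wishart (SIW), and two separation-strategy priors that
decouple standard deviations from correlations (SSIW and SSLKJ, the latter
with an LKJ prior directly on the correlation matrix). Model variants are
compared by WAIC; effects are summarized by posterior means, 95% highest-
posterior-density intervals, `p_positive`, and percentage change
`100*(exp(b)-1)`, including combined main + interaction effects at the
least and most heterogeneous landscapes.

The package covers the full pipeline:

* **Predictors** — `landscape_predictors()` builds FA, LHI, PE, EQ, CD
  (Hill–Shannon effective number of crop types) and PSS from raw land-use
  areas; `variance_inflation()` reports collinearity.
* **Surveys** — `filter_by_distance()` (150 m), `starling_correction()`
  (post-fledging flocks divided by 3), `aggregate_counts()` (landscape ×
  visit count table with the surveyed-points offset).
* **Model** — `build_design_matrix()`, `jsdm_config()`, `fit_model()` (an
  adaptive Metropolis-within-Gibbs sampler in C++ with interweaved
  centered/non-centered updates), `convergence_report()`.
* **Summaries** — `waic()`, `delta_waic()`, `hpd_interval()`,
  `p_positive()`, `percent_change()`, `combined_effect()`,
  `effect_summary()`, `residual_correlation_summary()`.
* **Synthetic data** — `jsdm_truth()`, `simulate_dataset()`,
  `recovery_report()`: a generator emulating the study design (33
  landscapes × 15 species × 2 visits, 5 rotating observers, 11–16 points
  per visit) so that parameter recovery is testable end to end.

## Worked example

Simulate a scaled-down dataset (30 landscapes, 5 species), fit the
negative-binomial model with the LKJ separation-strategy prior, and
summarize:

```r
library(birdjsdm)
truth  <- jsdm_truth(n_sites = 30, J = 5, seed = 1)
data   <- simulate_dataset(truth)
config <- jsdm_config(family = "negbinomial", sigma_prior = "SSLKJ",
                      chains = 2, iter = 2000, seed = 1)
fit <- fit_model(data$counts, data$design, config)
fit
#> joint count model fit
#>   5 species, 30 sites, 300 observations
#>   family negbinomial, Sigma prior SSLKJ, 2 chain(s) x 2000 iterations
#>   2000 retained draws; max split R-hat 1.060 [FLAGGED]
```

(The short 2-chain run is flagged by the 1.01 split-R-hat threshold —
exactly what the diagnostic is for; the default contract is 5 chains ×
4,000 iterations.)

```r
es <- effect_summary(fit)
subset(es, parameter %in% c("mu_FA", "mu_LHI", "mu_PE"))
#>  parameter  lhi estimate hpd_lower hpd_upper p_positive   pct
#>      mu_FA <NA>   0.1851    -0.263      0.72       0.82  25.3
#>     mu_LHI <NA>  -0.0073    -0.616      0.56       0.48   4.3
#>      mu_PE <NA>   0.4406    -0.100      0.87       0.97  61.0
#>      mu_PE  min   1.1328     0.083      2.23       0.98 851.8
#>      mu_PE  max  -0.3916    -1.716      0.79       0.21 -14.1
```

Read: a 1-SD increase in the proportion of extensive cropping is associated
with a +61% species-average abundance change (`p_positive` = 0.97) at mean
heterogeneity; the effect is strong in the most homogeneous landscape
(`lhi = "min"`, combined main + interaction effect) and absent-to-negative
in the most heterogeneous one — the interaction structure the model is
built to expose.

```r
waic(fit)$waic
#> [1] 1510.3
rec <- recovery_report(truth, fit)
attr(rec, "coverage")
#> [1] 0.97
```

`recovery_report()` confirms the 95% HPD intervals cover the generating
hyper-parameters at about the nominal rate.

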