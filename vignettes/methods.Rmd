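---
title: "Spatial additive mixed models and district ranking for childhood anaemia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial additive mixed models and district ranking for childhood anaemia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anaemiagamm)
```

## The problem

Anaemia in children aged 6--59 months is commonly assessed from
cluster-sampled household surveys (DHS/MIS-style designs): children are
nested in households, households in sampled clusters with recorded GPS
coordinates, and clusters in administrative districts. A child is
classified anaemic when the altitude-adjusted haemoglobin concentration
falls strictly below 11 g/dl (the WHO threshold for this age group).
Risk-factor analyses of such data must deal with two kinds of spatial
structure at once: *spatial autocorrelation* (nearby clusters resemble each
other because climate, parasite exposure and access to care vary smoothly
in space) and *district-level heterogeneity* (unmeasured district-specific
factors such as local health policy). Ignoring either biases the
covariate effects and their standard errors.

This package fits a generalized additive mixed model (GAMM) for the binary
anaemia outcome $y_{hijk}$ of child $k$ in household $j$ of cluster $i$ in
district $h$:

$$\operatorname{logit}\,\pi_{hijk} \;=\; \mathbf{x}_{hijk}'\boldsymbol\beta
\;+\; U_h \;+\; f(\text{age}_{hijk}) \;+\;
f_{\text{spat}}(\text{lon}_i, \text{lat}_i),$$

with linear fixed effects $\boldsymbol\beta$ (child, household and
cluster-level covariates with dummy coding against fixed reference
levels), an i.i.d. district random effect $U_h \sim N(0,
\sigma^2_{\text{district}})$, a penalized-spline smooth of age, and a
tensor-product penalized-spline surface over the cluster coordinates. On
top of the fit, districts are *appraised*: the realised values of $U_h$
are predicted by BLUP, standardized, and ranked within country to flag the
best- and worst-performing districts with respect to the odds of anaemia.
Households are indexed but carry no random effect: the model contains
exactly the terms listed above.

## P-splines and their penalties

Each smooth is a B-spline expansion $f(z) = \sum_m \alpha_m B_m(z)$ on
equally spaced knots. `make_knots()` places `n_segments` equal segments on
the covariate range and continues the knot grid `degree` knots beyond each
boundary with the same spacing. This equal-spacing extension (rather than
repeating the boundary knots) is deliberate: it keeps the basis a
partition of unity on the closed domain *and* makes the null space of the
second-order difference penalty correspond exactly to linear functions of
$z$, so "no smoothing" degenerates to a straight line, as the mixed-model
machinery below assumes. The default is a cubic basis on 20 segments
(23 basis functions) for the age smooth — a moderately large knot count,
with the difference penalty guarding against overfitting.

Wiggliness is penalized through differences of adjacent coefficients:
$P(\lambda) = \tfrac{\lambda}{2}\sum_m (\Delta^v \alpha_m)^2$ with $v = 2$
for the age smooth (departures from a linear trend are charged) and $v =
1$ marginals for the spatial term. `difference_penalty()` returns the
corresponding matrix $K = D_v'D_v$.

The spatial surface uses the tensor product of two marginal bases,
$f_{\text{spat}}(\text{lon}, \text{lat}) = \sum_{m_1}\sum_{m_2}
\alpha_{m_1 m_2} B_{m_1}(\text{lon}) B_{m_2}(\text{lat})$, with the
penalty summing squared deviations of each coefficient from its four
nearest neighbours on the coefficient grid (`spatial_penalty()`, the
Kronecker sum of the two marginal first-difference penalties; its null
space is the constant sheet). The default marginal dimension is 20 basis
functions per axis (`spatial_segments = 17` cubic segments). A published
formulation that indexes one basis function per cluster is treated as a
typesetting artifact: it would give a saturated, unidentifiable surface.
Where survey geography leaves grid regions empty the corresponding basis
columns are rank-deficient over the data; this is benign, because those
coefficients are fully regularized by the penalty.

## The mixed-model representation

`reparameterize()` converts each penalized term to mixed-model form via
the spectral decomposition of its penalty: penalized columns $B U_+
\Lambda_+^{-1/2}$ whose coefficients are exchangeable random effects with
variance $\tau^2 = 1/\lambda$, plus unpenalized null-space columns. The
constant direction of every null space is dropped (the model intercept
carries it), and the remaining null column of the order-2 age penalty — an
exactly linear function of age — joins the fixed effects. Reported smooths
are centered to average zero over the observed records, so the intercept
and the curves are jointly identifiable; centering is applied at
reporting time as a linear transform of the coefficients, which leaves
fitted probabilities untouched.

## Estimation: penalized IWLS + working-model REML

Estimation is empirical Bayes, maximizing a penalized likelihood rather
than sampling a posterior:

* **Inner loop** (`piwls_step()`): at fixed variance components
  $\theta = (\tau^2_{\text{age}}, \tau^2_{\text{spat}},
  \sigma^2_{\text{district}})$, iteratively weighted least squares on the
  working response $z = \eta + (y - \pi)/w$, $w = \pi(1-\pi)$, solving the
  penalized normal equations $(C'WC + P)\delta = C'Wz$. Fitted
  probabilities are clipped to $[10^{-10}, 1-10^{-10}]$ when forming
  weights. Step-halving guarantees the penalized deviance never
  increases. The solver exploits the district indicator block
  analytically (Schur complement over its diagonal), so the cost per
  iteration is driven by the dense smooth-plus-fixed block only; fits
  with $n = 50{,}000$ children and 200 districts take seconds.
* **Outer loop** (`reml_update()`): at PIWLS convergence the working
  linear mixed model (working response and weights frozen) yields a
  restricted likelihood in $\theta$, maximized on the log scale by
  L-BFGS-B. This is the classical PQL-style bridge between the binomial
  model and REML; it is how "IWLS + REML" is made concrete for a binary
  response. Components may hit the configured floor ($10^{-8}$) and are
  then reported as 0.

The loops alternate to joint convergence. Tolerances: inner relative
coefficient change $<10^{-6}$ (at most 200 iterations); outer relative
change in $\theta$ $< 10^{-3}$, with components below $0.01$ judged on
absolute movement. The outer tolerance is deliberately not tighter: on
binary data the alternation settles into a limit cycle of relative
amplitude around $5\times10^{-4}$ (the weights feed back into $\theta$),
so a $10^{-5}$ threshold would spin until the iteration cap without
changing any reported digit. Refitting the same data is bit-identical; no
randomness enters the fitter.

Inference is conditional on $\hat\theta$: the coefficient covariance is
$(C'W C + P)^{-1}$ (the usual Bayesian posterior covariance of penalized
spline models), which also supplies pointwise bands for the smooths,
delta-method SEs for total effects, and prediction SEs for the BLUPs.
Wald intervals use $z_{0.975} = 1.959964$. Apparent complete separation
(a diverging unpenalized coefficient) is reported as an error naming the
covariate.

## District appraisal

`extract_blups()` returns $\hat U_h$ with prediction SEs; districts with
more children shrink less, and the predicted effects sum to zero across
districts (a consequence of the intercept's estimating equation).
"Standardized" BLUPs are, by default, $\hat U_h / \mathrm{SE}(\hat U_h)$
— a conditional z-like score that accounts for unequal district sample
sizes; an across-district z-score is available as an alternative because
the two can reorder districts and neither is canonical. Ranking is within
country by default (ascending; rank 1 = lowest standardized BLUP =
best-performing), with deterministic lexicographic tie-breaks, and the
top-$k$/bottom-$k$ flags are disjoint whenever a country has at least
$2k$ districts. Districts without sampled clusters receive no BLUP and
appear as missing, never as zero.

## The synthetic-data generator

The raw surveys behind studies of this design are registration-restricted,
so the package ships a seeded generator that emulates their structure and
makes every stage testable by parameter recovery:

* **Geography** (`generate_geography()`): 4 countries with rectangular
  bounding boxes loosely shaped like Kenya, Malawi, Tanzania and Uganda;
  districts nested in countries; clusters with uniform coordinates inside
  the country box and an urban/rural label. The default test-scale
  configuration is 40 districts with 4 clusters each;
  `geography_config_full()` reproduces the survey-scale shape (47 + 26 +
  176 + 121 = 370 districts, 1595 clusters). GPS displacement is not
  modelled — it is a privacy artifact of the real surveys, not structure.
* **Covariates** (`generate_cohort()`): ages uniform on 6--59 months;
  household grouping within clusters; cluster-level altitude, EVI and LST
  constant within cluster; marginals (RDT positivity 25%, education and
  toilet distributions, household size $1+\text{Poisson}(4)$, wealth
  Z-score $N(0,1)$) chosen as plausible for under-five populations in the
  region and freely overridable — published reports do not include the
  covariate marginals, so these are conveniences, not estimates.
* **Truth** (`true_model()`): named log-odds coefficients (defaults
  informed by adjusted odds ratios reported for this population: female
  0.876, positive RDT 4.315, wealth 0.847, country and residence effects
  with a residence-by-country interaction), a single-bump age effect
  rising to about 10 months and turning protective from about 25 months,
  a smooth two-bump spatial surface (positive near the Lake Victoria
  region), and district variance 0.15. The intercept is set so overall
  prevalence lands near one half.
* **Outcomes** (`simulate_outcomes()`): either Bernoulli draws from the
  model probability, or a latent haemoglobin drawn so that the
  probability of falling below the 11 g/dl threshold equals the model
  probability, with the altitude correction added back to the stored raw
  Hb. The two modes agree in prevalence as the latent noise shrinks, and
  the stored records always re-classify to the stored outcome.

What passing recovery tests on these data do **not** show: robustness to
survey weights and stratified sampling (not modelled), to informative GPS
displacement, to missingness or measurement error in covariates, or to
covariate distributions matching any particular country's survey. The
generator validates the estimator under its own assumptions, which is the
strongest claim desk-scale synthetic data can support.

## Altitude adjustment

The haemoglobin altitude correction is the CDC/DHS quadratic:
$\text{corr} = \max(0,\, -0.032A + 0.022A^2)$ g/dl with $A$ the altitude
in thousands of feet, subtracted from the measured value before applying
the 11 g/dl threshold. The correction is zero below about 443 m (where
the quadratic is negative) and nondecreasing in altitude. The formula is
an argument of `adjust_hb_for_altitude()`, so a different convention can
be swapped in without touching the classification.

## Model-building helpers

`univariate_screen()` reproduces the usual screening step: a
single-covariate logistic fit, keep when $p < 0.10$ (likelihood-ratio
p-values by default; Wald optional for single-column covariates — reports
of this design rarely say which was used, so both are exposed).
`screen_interactions()` compares the main-effects model against each
two-way interaction by likelihood-ratio test, skipping inestimable pairs
with a warning. The pipeline screens the household head's age on the same
footing as every other candidate rather than hard-coding its exclusion.

## Validation studies and their sizes

Three study drivers are exported, and the acceptance script and test
suite run them at these sizes (chosen to make Monte-Carlo error small at
desk scale):

* `recovery_study()`: 60 replicates of $n = 50{,}000$ children across 200
  districts (spatial basis 6 segments per axis for the study model —
  the synthetic truth surface is smooth, and the reduced basis keeps 60
  fits tractable without visible bias in the recovered fixed effects).
  Checks that the female and malaria-RDT coefficients and the district
  variance are recovered within Monte-Carlo error and that Wald CI
  coverage is near nominal. Sixty replicates rather than the minimal 25
  so that empirical coverage has enough granularity to distinguish, say,
  0.95 from 1.00.
* `ranking_study()`: 25 replicates, 40 districts, 250 children per
  district, $\sigma^2_{\text{district}} = 1$ (a strong signal). Kendall's
  $\tau$ between standardized-BLUP ranks and true district-effect ranks
  is computed within country and averaged, matching the scope of the
  appraisal itself: the league table is per-country, and cross-country
  level differences ride on the weakly identified country fixed effects,
  not on the BLUPs. (Pooling all 40 districts drops $\tau$ from about
  0.92 to 0.77 purely through those country-level shifts — an oracle
  given the true covariate effects shows the same gap.)
* `null_surface_study()`: 5 replicates of $n = 20{,}000$ with a null
  surface and zero district variance; the fitted surface magnitude stays
  small and the district variance sits on the boundary.

## Known limitations

* PQL-style working-model REML carries the usual small-cluster bias for
  binary data; with the survey-like cluster sizes used here (tens to
  hundreds of children per district) the bias is negligible, but the
  estimator should not be trusted for designs with very few children per
  district and large random-effect variances.
* Inference is conditional on the estimated variance components;
  smoothing-parameter uncertainty is not propagated.
* Country fixed effects and a flexible spatial surface over spatially
  disjoint countries are weakly identified jointly: comparisons of
  *levels* across countries should lean on the fixed effects and their
  intervals, not on surface differences.
* Survey design features (weights, stratification) are out of scope; all
  children are treated as equally weighted.

## A worked example

```{r example, eval = FALSE}
library(anaemiagamm)

ds <- simulate_anaemia_data(n_children = 8000, seed = 1)
fit <- fit_anaemia_gamm(ds$records, model_spec(spatial_segments = 5))

aor_table(fit)                 # adjusted odds ratios with 95% CIs
variance_components(fit)       # age, spatial and district variances
smooth_curve(fit)              # centered age effect with bands
total_residence_country_effects(fit)
appraise_districts(fit, k = 3) # per-country district league table

plot_age_effect(fit)
plot_spatial_effect(fit)
```
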