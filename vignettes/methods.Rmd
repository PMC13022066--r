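---
title: "Modelling genetic diversity and range-shift velocity: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling genetic diversity and range-shift velocity: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific question

Species track a warming climate by shifting their geographic ranges,
but they do so at very different velocities. `divshift` implements a
complete inference pipeline for one candidate explanation: that
species-level genetic diversity — nucleotide diversity estimated from
organellar markers, a proxy for standing genetic variation — modulates
the velocity of climate-induced latitudinal range shifts, and does so
differently at the trailing edge, centroid and leading edge of a
species' range, depending on how fast local isotherms are moving.

The unit of analysis is one published range-shift estimate: a species,
a taxonomic class, a range position (trailing edge, centroid or leading
edge), a signed latitudinal shift velocity in km/yr, the signed
latitudinal isotherm velocity over the same period, the species'
nucleotide diversity, and five attributes describing how the original
study measured the shift (number of temporal periods, spatial grain,
data type, sampling design, study-area extent). Such tables are heavily
imbalanced: a few thousand centroid and leading-edge estimates but only
a few hundred trailing-edge ones, repeated observations per species,
and species nested in a handful of taxonomic classes.

# The model

The response is the absolute latitudinal range-shift velocity
$|LRS|_i > 0$. It is modelled with a Gamma distribution and log link:

$$|LRS|_i \sim \mathrm{Gamma}\!\left(\nu,\ \mu_i = e^{\eta_i}\right),
\qquad \mathrm{Var} = \mu_i^2 / \nu,$$

$$\eta_i = b + a_1 GD + a_2 |VIS| + a_3 (GD \times |VIS|)
  + b_{POS} + \Delta a_{1,POS} GD + \Delta a_{2,POS} |VIS|
  + \Delta a_{3,POS} (GD \times |VIS|) + \text{methods} + u_{class},$$

with $u_{class} \sim N(0, \sigma^2_{class})$ a taxonomic-class random
intercept. $GD$ and $|VIS|$ are z-scored so coefficients are directly
comparable; the centroid, occurrence data and balanced sampling are the
reference levels; spatial grain enters as an ordinal 1–4 score. The
marginal (link-scale) effect of genetic diversity at a position and
climate velocity is

$$\frac{\partial \eta}{\partial GD}
  = (a_1 + \Delta a_{1,POS}) + (a_3 + \Delta a_{3,POS})\,|VIS|,$$

an affine function of $|VIS|$ whose sign change locates the climate
velocity at which the genetic-diversity effect reverses.

## Observation weights

Because range positions are grossly imbalanced and species contribute
unequal numbers of estimates, each observation is weighted

$$W_{i} = \frac{1}{N_{obs}(sp_i, pos_i)} \times
          \frac{1}{N_{sp}(pos_i)} \times \frac{1}{3},$$

so each species contributes equally within a position and each of the
three positions contributes exactly 1/3 of the total weight. Weights
enter the likelihood as multipliers of the per-observation Gamma
log-density. Internally they are rescaled to mean 1; this leaves the
coefficient estimates exactly unchanged (a rescaling of the weights is
equivalent to a rescaling of the shape) while keeping shape estimation
on the usual scale. An important statistical consequence of unequal
likelihood weights is that inverse-Hessian standard errors understate
the sampling variance of the weighted estimator (the information
identity fails); the pipeline therefore does all inference by
bootstrap, never from model-based standard errors.

## Fitting

`fit_glmm()` maximises the weighted marginal likelihood directly. For
a single random intercept the conditional log-likelihood of class $c$
collapses, given its intercept $u$, to $A_c - \nu W_c u - T_c e^{-u}$
with three per-class sufficient statistics, so the inner problem is a
one-dimensional root-find per class regardless of $n$. The intercept is
integrated out by adaptive Gauss–Hermite quadrature centred and scaled
at the conditional mode (7 nodes by default; one node reproduces the
Laplace approximation; on 20-observation toy data the 7-node rule
agrees with brute-force integration to ~1e-6, Laplace to ~1e-3). The
outer optimisation (PORT/`nlminb`) uses an exact analytic gradient
obtained by implicit differentiation through the quadrature — the
conditional modes and scales are themselves differentiated, so no
envelope approximation is involved. This makes a full 18-coefficient
fit on ~4700 rows take well under half a second, which is what renders
the resampling protocol (thousands of refits) practical.

Numerical choices:

- The class SD is optimised on its natural scale with a boundary at
  zero (the likelihood is analytic in $\sigma^2$, so the gradient
  vanishes smoothly there). A fit whose class SD falls below
  $10^{-4} \times \mathrm{sd}(\log y)$ is flagged *singular* and
  snapped to the boundary, where the fixed-effect likelihood refines
  the remaining parameters. Warm starts never begin exactly at the
  boundary, where the gradient carries no information.
- Convergence is the PORT relative-function criterion (default
  `rel.tol = 1e-10`; bootstrap refits use `1e-8`, perturbing draws by
  ~1e-4 — two orders below their Monte Carlo spread — for a ~20%
  speed gain).
- Rank-deficient fixed-effect designs are an error, never silently
  repaired.

## Bootstrap inference

Each of $B$ iterations resamples $n$ observations with replacement,
recomputes the weights from the resampled counts (so $N_{obs}$ and
$N_{sp}$ reflect the resampled table), and refits, warm-started at the
full-data estimates. Fits that fail, do not converge, or are singular
are discarded; a seeded uniform subset of `keep` converging fits is
retained (the full protocol uses B = 12000 and keep = 10000; tests and
the acceptance script scale B down while keeping the retention ratio).
Summaries are percentile 95% intervals (type-7 quantiles), the
two-sided bootstrap p-value $2\min(\hat F(0), 1-\hat F(0))$ floored at
$1/n_{draws}$, and a significance flag defined by the interval
excluding zero. Standardisation of $GD$ and $|VIS|$ is computed once on
the post-filter table and held fixed across iterations; re-scaling per
draw would silently change the meaning of a z-unit coefficient.
Iteration seeds are spawned deterministically from the master seed, so
results are independent of execution order.

## Marginal R² and variance partitioning

Goodness of fit uses the lognormal-method marginal R² appropriate for
log-link models:

$$R^2_m = \frac{\sigma^2_f}{\sigma^2_f + \sigma^2_{class} + \ln(1 + 1/\nu)},$$

where $\sigma^2_f$ is the population variance of the fixed-effect
linear predictor across observations (unweighted, the common
convention) and $\ln(1+1/\nu)$ is the lognormal approximation to the
observation-level variance of a Gamma log-link model.

`hierarchical_partition()` decomposes the full-model $R^2_m$ over eight
predictor groups (GD, |VIS|, POS, their two- and three-way
interactions, and the five method covariates combined) by fitting the
GLMM for *every* subset of groups (256 fits; intercept and random
effect always included; the empty subset has $R^2_m = 0$ by
definition) and averaging incremental contributions over hierarchy
levels — the classic hierarchical-partitioning (Shapley) decomposition,
whose per-group *individual* contributions sum exactly to the
full-model $R^2_m$. *Unique* is the loss from dropping the group from
the full model and *average share* the difference. Subsets may contain
an interaction group without its main effects; the level-averaging is
otherwise undefined, and this matches how standard hierarchical
partitioning tooling behaves. Partitioning uses single fits, not the
bootstrap. A non-converging subset fit is retried once from a
perturbed least-squares start, then imputed from its one-group
neighbours and flagged. Aggregated totals per variable (main effect
plus every interaction containing it) are reported by
`aggregate_variable_contribution()`.

## Sensitivity analyses

- **Per-position models**: the data are subset by range position and
  refitted with all position terms removed and weights recomputed
  within the subset, checking that conclusions do not hinge on
  modelling positions jointly.
- **Latitude residual tests**: link-scale residuals
  ($\log y - \hat\eta$, conditional on the class intercepts) of a
  baseline model are regressed on z-scored latitude, and conversely the
  residuals of a latitude+methods model are regressed on the
  climate/genetic terms. Link-scale residuals are used because the
  model is linear on that scale. The paired R² values show whether
  historical legacies captured by latitude explain anything the model
  misses.

# The synthetic-data generator

`generate_dataset()` is the package's test bed: it produces tables with
the statistical structure the analysis assumes, with known truth
attached. Species-level quantities (class membership, nucleotide
diversity) are drawn once per species and broadcast to the species'
rows — genetic diversity is a species-level covariate — while range
position, isotherm velocity and the five method covariates are drawn
per observation, since the original studies differ per estimate.

Default study conditions (each a single a-priori choice, held fixed):

- 1888 species in 7 classes with membership probabilities mirroring the
  observed class imbalance; observation counts per species geometric
  with mean 4673/1888 ≈ 2.48 (the empirical per-species distribution is
  not published; geometric is the natural maximum-entropy choice for a
  count ≥ 1 with a known mean, and it is exposed in the config).
- Position probabilities proportional to 2298/2082/295
  (centroid/leading/trailing).
- Nucleotide diversity lognormal(log 0.006, 0.7), spanning the typical
  0.001–0.02 range; isotherm speed lognormal(log 1.5, 0.7) km/yr with
  ~97% of isotherms moving poleward; a fraction 136/4809 of rows made
  direction-discordant (exactly `round(n·f)` rows, so the filter's
  input is reproducible).
- True coefficients: the centroid GD × |VIS| interaction is −0.086 so
  recovery tests target an effect of realistic magnitude; method
  covariates carry the largest effects (they dominate observed
  range-shift variability); Gamma shape 2 and class SD 0.15, which
  together with the fixed effects put the marginal R² in the mid-40%
  range and leave the class variance a minor component — consistent
  with a model whose explained variance is dominated by fixed effects.
- Latitude is drawn with configurable association to |VIS| and a
  configurable direct effect on the log-mean (both 0 by default); the
  non-null regime exists to exercise the residual tests against a
  planted signal.

The generator standardises GD and |VIS| within the generated sample
when building the linear predictor, matching what preprocessing will
compute downstream; the residual mismatch after the concordance filter
removes ~3% of rows is negligible and bias-free because discordance is
assigned independently of the covariates.

What the generator does **not** emulate: spatial structure (no
polygons, no geographic autocorrelation), taxonomy below class,
correlation between method covariates and taxa, measurement error in
nucleotide diversity, and any dependence of genetic diversity on range
position. Passing tests therefore demonstrate that the pipeline's
estimators and bookkeeping are correct under the model's own
assumptions — not that those assumptions hold in any real dataset.

# Preprocessing rules

- **Directional concordance**: only observations whose shift direction
  matches the isotherm direction are kept. Rows with an exactly zero
  shift or isotherm velocity have undefined concordance and are dropped
  with a logged count; the paper trail for such rows is the
  preprocessing report. (A Gamma response could not accommodate zero
  velocities in any case.)
- **Rare classes**: classes with fewer than 10 distinct species are
  removed; exactly 10 is kept.
- **Outlier species**: continental-scale outliers are handled by an
  optional exclusion list in the run configuration rather than
  hard-coded names, since the pipeline also runs on synthetic data.
- **Standardisation order**: z-scores are computed after all filters
  (the alternative — before filtering — would let excluded rows define
  the coefficient scale).

# Effect curves and predictions

`effect_curve()` evaluates the marginal GD slope on every retained
bootstrap draw over a climate-velocity grid (default 100 points
spanning the observed |VIS| range; the grid is a display choice, not a
model choice), giving pointwise means, percentile bands and
significance flags; `significance_bands()` reports maximal runs of
significant grid points as velocity ranges, split by slope sign.
Intervals are pointwise, not simultaneous. Response-scale predictions
(`predict_response()`) fix the method covariates at a representative
combination — occurrence data, balanced sampling, moderate grain,
1238 km² extent, 4.9 periods — and set the class intercept to its
population mean of zero on the link scale (standard marginal-prediction
practice). Cut-points of 0.003 and 0.015 define the low/high
genetic-diversity scenarios; both are config defaults, not constants.

# Problem sizes used by the test suite

Unit tests run at a few hundred species. The acceptance suite uses the
sizes its properties are defined for: coefficient recovery over 50
replicates of ~5000 observations; bootstrap coverage over 50 replicates
of ~2000 observations with B = 200 (retaining all converging fits);
the 256-subset partition at ~2000 observations; curve/crossing recovery
at ~5000 observations with B = 200, with the sign-change planted at
one |VIS| z-unit via a strong GD × |VIS| interaction (−0.25) so the
crossing is identified to well under the 0.3 km/yr check width. The
acceptance script regenerates the full-scale study (~4700 rows) and
runs a 600/500 bootstrap plus the full partition in about a minute.

# Known limitations

- The fitter supports exactly the model family the pipeline needs:
  Gamma response, log link, one random intercept. It is not a general
  GLMM engine.
- Percentile intervals are the plain bootstrap reading; no BCa
  correction.
- Bootstrap resampling is by observation, ignoring species clustering
  — the literal reading of the resampling protocol; a cluster bootstrap
  by species would be a different (and defensible) design.
- The hierarchical partition refits $2^K$ models; with the default 8
  groups this is 256 GLMM fits, and the implementation caps $K$ at 12.
- With only ~7 classes the class SD is weakly identified; singular
  fits are a normal occurrence in resampling and are excluded from
  ensembles, which is itself part of the protocol being reproduced.
- Model-based standard errors (available via `se = TRUE`) are valid
  only under equal weights; under the position-balancing weights they
  understate sampling variance, which is why they are never used for
  inference here.
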