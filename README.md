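# divshift

Does a species' genetic diversity shape how fast it shifts its range
under climate change? `divshift` is an R package for answering that
question from merged macroecological tables that pair published
latitudinal range-shift estimates (trailing edge, centroid, leading
edge; km/yr) with species-level nucleotide diversity and the local
isotherm-shift velocity. It is aimed at macroecologists and
macrogeneticists who need the full inference pipeline — not just a
model fit — reproducibly, and at methodologists who want every stage
testable against synthetic data with known truth.

## The model

Absolute range-shift velocity is modelled with a weighted Gamma
log-link mixed model:

    |LRS| ~ Gamma(nu, mu),   log mu = b + a1·GD + a2·|VIS| + a3·GD·|VIS|
            + position terms (+ interactions) + method covariates + (1 | Class)

with GD (nucleotide diversity) and |VIS| (absolute isotherm velocity)
z-scored, the range centroid as reference position, and a taxonomic
class random intercept. Observations are weighted
`1/N_obs(sp,pos) x 1/N_sp(pos) x 1/3` so every species counts equally
within a position and the three range positions contribute equally
overall. Inference is by nonparametric bootstrap — resample rows,
recompute weights, refit — because model-based standard errors are
invalid under unequal likelihood weights. The marginal effect of
genetic diversity at a position is `(a1 + Δa1) + (a3 + Δa3)·|VIS|`,
reported as curves over climate velocity with percentile bands and
significance ranges. Goodness of fit uses the lognormal-method marginal
R², and a 256-subset hierarchical partition attributes that R² to
predictor groups.

The package ships its own maximum-likelihood fitter for this model
family (adaptive Gauss–Hermite quadrature over the class intercept,
exact analytic gradients), fast enough for tens of thousands of
bootstrap refits; estimates agree with glmmTMB to ~1e-5 on matched
problems. A seeded synthetic-data generator reproduces the structure of
the merged tables — class and position imbalance, repeated observations
per species, direction-discordant rows — with the generating truth
attached, so every stage is testable offline.

## A worked example

```r
library(divshift)
cfg  <- simulation_config(seed = 42, n_species = 600)
tab  <- generate_dataset(cfg)       # one row per range-shift estimate
prep <- preprocess_table(tab)       # concordance filter, z-scores, weights
print(prep)
#> Preprocessed range-shift table
#>   rows: 1484 input -> 1442 concordant -> 1442 after class filter
#>   dropped: 42 discordant, 0 zero-velocity; classes removed: none
#>   weight sum: 1.000000 over 3 position(s)

ens <- bootstrap_fit(prep$table, B = 200, keep = 150, seed = 7)
s   <- summarize_ensemble(ens)
s[s$coefficient %in% c("gd", "vis", "gd_vis", "gd_vis_pos_trailing"), ]
#>          coefficient    mean  lower   upper       p significant
#>                   gd  0.1400  0.073  0.1869 0.00667        TRUE
#>                  vis  0.2307  0.177  0.2825 0.00667        TRUE
#>               gd_vis -0.0959 -0.174 -0.0601 0.00667        TRUE
#>  gd_vis_pos_trailing -0.2611 -0.616  0.0291 0.08000       FALSE
```

The 42 rows whose shift direction opposed the isotherm direction were
dropped; weights sum to exactly 1 (1/3 per range position). The
centroid GD × |VIS| interaction `gd_vis` is recovered near its
generating value of −0.086 with a 95% interval excluding zero: species
with higher genetic diversity shift faster under slow climate change
and slower under fast climate change. Where does that reversal become
significant at the trailing edge?

```r
grid  <- seq(0.2, 8, length.out = 100)          # km/yr
curve <- effect_curve(ens, "trailing", grid, prep$scaling)
significance_bands(curve)
#>    vis_lo   vis_hi     sign
#>  0.200000 0.830303 positive
#>  3.509091 8.000000 negative
```

The genetic-diversity effect on trailing-edge shift velocity is
significantly positive below ~0.8 km/yr of climate velocity and
significantly negative above ~3.5 km/yr — the pattern expected if high
diversity buffers trailing-edge contractions under rapid warming.

`run_full_analysis()` chains every stage (preprocessing, collinearity
diagnostics, fit, bootstrap, curves, variance partition, latitude
residual tests, per-position sensitivity fits) from a single seeded
configuration, and `inst/scripts/run_analysis.R` exposes the same from
the shell via a YAML config.

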