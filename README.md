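# rumenpls

Compositional PLS and Bayesian linear models for linking rumen microbial
genus abundances to enteric methane yield under contrasting diets.

Ruminant methane is synthesised by rumen archaea, and both methane yield
(g CH4 / kg dry matter intake) and the microbial community shift strongly
with the forage-to-concentrate ratio of the diet. `rumenpls` implements, as
a tested and reusable R package, the full statistical workflow for a
two-diet comparison (a fresh-cut grass diet, GRASS, vs a high-concentrate
total mixed ration, TMR) at the genus level:

- **Compositional preprocessing** — prevalence filtering (with a
  discrimination-guided threshold scan), Geometric Bayesian-multiplicative
  zero replacement, the centered log-ratio (clr) transform, and the
  archaea:bacteria log-ratio (A:B).
- **PLS machinery** — NIPALS PLS1 regression and two-class discriminant
  PLS; dimension selection by the Q² rule
  (Q²ₕ = 1 − PRESSₕ/RSSₕ₋₁, stop at Q²ₕ ≤ 0.0975); variable selection by
  VIP > 0.8 plus jackknife coefficient intervals excluding zero, iterated
  against a repeated-cross-validation criterion; permutation validation.
- **Bayesian linear models** — bounded flat priors, single-site Gibbs
  sampling, posterior summaries with HPD₉₅, P₀ (probability the contrast
  exceeds 0 in the direction of its mean) and P_r (probability it exceeds
  a relevance threshold r = ⅓ of the phenotypic SD), Geweke Z and
  time-series Monte Carlo errors.
- **A synthetic data generator** with known ground truth (diet-shifted
  genera, diet-specific methane drivers including a cross-over genus,
  realistic 16S sparsity) so every stage is testable end-to-end.

## Worked example

```r
library(rumenpls)

# a study-scale synthetic dataset: 26 animals, 203 genera, ~78% zeros
ds <- generate_dataset(sim_config(seed = 1))
ds
#> Synthetic rumen dataset: 26 samples x 203 genera, 77.9% zeros
#>   22 diet-affected genera; 5/5 methane drivers (GRASS/TMR)

# preprocess: filter at 20% prevalence, replace zeros, clr-transform
clr <- clr_transform(replace_zeros(prevalence_filter(ds$counts, 0.2)))

# diet discrimination with iterative VIP/jackknife selection
sel <- iterative_variable_selection(
  clr, factor(ds$phenotypes$diet, levels = c("GRASS", "TMR")),
  cv = cv_spec(k = 4, reps = 20, seed = 11))
sel
#> PLS variable selection (discriminant mode): 23 variables, h = 1
#> misclassification (%): 0.000 +/- 0.000 (20 x 4-fold CV, h = 1)

# how many of the truly diet-shifted genera were recovered?
mean(names(ds$truth$diet_affected) %in% sel$variables)
#> [1] 1
```

The selected model separates the diets with 0% cross-validated
misclassification and recovers all 22 genera whose abundances were
simulated to differ between diets. `run_diet_effects()`,
`run_methane_pls()` and `run_ab_regression()` cover the Bayesian
diet-effect models and within-diet methane prediction;
`full_run()` orchestrates every stage and writes a JSON report plus tidy
CSV tables.

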