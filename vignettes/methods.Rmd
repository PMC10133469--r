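---
title: "Methods: compositional PLS and Bayesian models for rumen methane analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compositional PLS and Bayesian models for rumen methane analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rumenpls)
```

# The problem

Enteric methane is produced by methanogenic archaea fermenting feed in the
rumen, and both methane yield (g CH4 per kg dry matter intake, DMI) and the
microbial community depend strongly on the diet's forage-to-concentrate
ratio. `rumenpls` implements a complete statistical workflow for asking, from
a genus-level 16S count table and animal phenotypes: (i) does diet shift
intake, methane traits and the archaea:bacteria balance; (ii) which genera
discriminate the diets; and (iii) which genera predict methane yield within
each diet. The design it targets is deliberately small — two diet groups
(a fresh-cut grass diet, GRASS, and a high-concentrate total mixed ration,
TMR) of about 13 animals each — so every inferential choice below is made
with n in the teens in mind.

Microbiome counts are compositional: only relative information is
meaningful, and a change in one abundant genus mechanically changes every
other relative abundance. All multivariate analysis therefore happens in
centered log-ratio (clr) coordinates, after prevalence filtering and
model-based replacement of the many zero counts that 16S data contain.

# Compositional preprocessing

**Prevalence filtering.** `prevalence_filter()` keeps genera observed in at
least a fraction `min_prevalence` of samples (boundary inclusive; the
default pipeline threshold is 0.20). `scan_prevalence()` chooses the
threshold on the data: for each candidate it filters, replaces zeros,
clr-transforms, and scores diet discrimination by the repeated-CV
misclassification of a one-component discriminant PLS, selecting the
threshold with minimum misclassification (ties to the smallest). Using the
pipeline's own classifier keeps the scan self-contained and consistent with
the downstream analysis; it replaces the random-forest out-of-bag score that
prevalence-scanning tools in this field typically use.

**Zero replacement.** `replace_zeros()` is a Geometric Bayesian-multiplicative
scheme. For sample $i$ with depth $N_i$, a zero cell of genus $j$ receives
the posterior-expected proportion under a Dirichlet prior with strength
$s_i = \sqrt{N_i}$ and location $t_j$, the (renormalised) geometric mean of
genus $j$'s non-zero proportions across samples:

$$\hat p_{ij} = \frac{s_i\,t_j}{N_i + s_i}.$$

Non-zero cells are multiplicatively shrunk so the row still sums to 1, which
preserves every pairwise ratio among observed parts exactly — the property
that matters for log-ratio analysis. The prior had to be fixed concretely
for reproducibility; the square-root strength makes the imputed mass vanish
as depth grows, and the geometric-mean location borrows abundance
information across samples. The scheme is deliberately isolated behind one
function so an alternative (e.g. multiplicative replacement with
$\delta = 0.65 \times$ the minimum observed proportion) can be swapped in.

**clr transform and A:B.** `clr_transform()` maps each composition row to
$\ln p_{ij} - \overline{\ln p_{i\cdot}}$; rows sum to zero (checked to
1e-10) and the transform is invariant to per-sample count scaling.
`archaea_bacteria_logratio()` computes
$\ln(\sum_{\text{Archaea}} c_{ij} / \sum_{\text{Bacteria}} c_{ij})$ per
sample; genera without a domain assignment are excluded from both sums,
while "unclassified Archaea/Bacteria"-style genera count toward their
domain. A:B is computed on the full table, before prevalence filtering,
since domain totals need no per-genus reliability.

# PLS with Q2, VIP and jackknife selection

`fit_pls()` is a NIPALS PLS1: predictors are centered and autoscaled
(clr variables have heterogeneous variances; constant columns are scaled by
1), the response centered, and components extracted by X-deflation. Weight
vectors have unit norm and score vectors are mutually orthogonal.
Discriminant analysis (DA-PLS) for two classes is PLS1 on a $-1/+1$ dummy
response with class assignment by prediction sign — for a single response
this is equivalent to two-class PLS-DA.

**Dimension choice.** `q2_sequence()` computes, for each dimension $h$,
the full-data residual sum of squares $RSS_h$ and the cross-validated
$PRESS_h$ (summed over test folds within a replicate, averaged across
replicates), then

$$Q^2_h = 1 - \frac{PRESS_h}{RSS_{h-1}}, \qquad RSS_0 = \sum_i (y_i - \bar y)^2.$$

`select_n_components()` stops adding dimensions once $Q^2_h \le 0.0975$
(boundary inclusive) and always retains at least one component: the
workflow always reports a final model, and in this design the final models
are one-component. The $RSS_h$ is the conventional full-data residual sum
of squares of the $h$-component fit.

**Variable selection.** A genus is retained when its VIP,

$$VIP_j = \sqrt{p \; \frac{\sum_h SSY_h\, w_{jh}^2}{\sum_h SSY_h}}, \qquad
SSY_h = q_h^2\, t_h^\top t_h,$$

exceeds 0.8 *and* its jackknife coefficient interval excludes zero. The
jackknife refits the model on every leave-fold-out training set across all
CV replicates and, per variable, uses the Tukey delete-fold variance
$\frac{k-1}{k}\sum_{\text{folds}} (b - \bar b)^2$ computed within each
replicate and averaged across replicates; the interval is
$\bar b \pm t_{0.975,\,m-1}\,\widehat{se}$ with $m = k \times$ replicates
refits. `iterative_variable_selection()` alternates dimension choice,
selection, and re-evaluation of the repeated-CV criterion
(misclassification % to minimise, or predictive ability — the squared
Pearson correlation between test-fold predictions and observations — to
maximise), always on the same seeded folds so CV noise cancels in the
comparison. It stops when the criterion stops strictly improving or nothing
fails the criteria, and returns the best-criterion iteration, with ties
going to the most parsimonious set. If a step would empty the variable set
the previous set is kept and flagged — with n around 13, jackknife
intervals are wide and this is a realistic outcome rather than an error.

**Validation.** `cross_validate()` reports the criterion averaged over
folds then replicates, with the SD across replicates. The permutation
analog shuffles only the *test-set* responses before scoring
(`permute = "test_labels"`), mirroring a validation-stage randomisation
test; a conventional pre-training shuffle is available as
`permute = "full_labels"`. Fold assignment is a pure function of
(seed, replicate, n, labels), stratified by class in discriminant mode, so
results are reproducible across platforms. Because selection and validation
reuse the same samples, the CV estimates are honest about fold-level
refitting but are not an external validation — a caveat inherent to designs
of this size.

# Bayesian linear models

`bayes_lm()` fits fixed-effect linear models (e.g. trait ~ diet + breed +
chamber + week + body weight) with bounded flat priors on all location
parameters (box half-width 1e6) and a flat prior on the residual variance
on (0, 1e6]. Sampling is single-site Gibbs: each coefficient from its full
conditional normal truncated to the prior box (the truncation is virtually
never active at these bounds), the residual variance from its full
conditional scaled inverse chi-square, sampled as
$SSR/\chi^2_{n-2}$. With an intercept present, covariate columns are
centered during sampling — this removes the extreme intercept/body-weight
posterior correlation that would otherwise cripple single-site mixing — and
draws are mapped back to the original parameterisation, which leaves all
slopes untouched. Factors use reference coding with the first level at
zero, so with levels ordered GRASS, TMR the `dietTMR` coefficient is the
TMR − GRASS difference. Aliased columns (chamber and week can be partially
confounded in designs this small) are dropped with a warning naming them.

The default chain (`chain_spec()`) runs 60,000 iterations, discards 10,000
and keeps every 10th draw — exactly 5,000 saved samples. Tests and the
acceptance script run 3,000–6,000 iterations instead: the posterior
summaries involved are location quantities whose Monte Carlo error, not
their value, depends on chain length, and the shorter chains keep the whole
suite inside a couple of minutes.

`posterior_summary()` reports the posterior mean and median; the HPD95
(shortest interval containing 95% of sorted samples); $P_0$, the posterior
probability that the contrast exceeds zero in the direction of its mean;
and $P_r$, the probability it exceeds a relevance threshold $r$ in that
direction, so $P_r \le P_0$ always. The default relevance threshold is
one-third of the phenotypic standard deviation of the raw response
(`relevant_threshold()`). The effect size is the posterior median of the
contrast divided by the residual SD — the SD scale, not the variance,
which is the scale on which reported effect sizes of a few units are
interpretable. Convergence diagnostics are the Geweke Z (first 10% vs last
50% of the chain, variances from a Bartlett lag-window spectral estimator
truncated at 4% of the window length) and the Monte Carlo standard error
from the same spectral estimator at frequency zero, which reduces to
$sd/\sqrt{n}$ for independent draws and inflates under autocorrelation.

# The synthetic data generator

`generate_dataset()` emulates the statistical structure the analysis
assumes, with known ground truth, so every stage can be tested for
*recovery* rather than merely for running. Defaults are fixed to the study
conditions: 13 animals per diet, 203 genera, a target of 78% zero counts
per sample, sequencing depth around 5.1e5 reads (SD 30%), 22 diet-affected
genera shifted by 3 log units (alternating sign), 5 methane-driver genera
per diet with coefficients (2.5, −2.5, 2, −2, 1.5) g/kg DMI per clr unit,
one cross-over genus whose coefficient flips sign between diets, a
TMR − GRASS methane-yield difference of −10.6 g/kg DMI, and residual SD
2 g/kg DMI. Body weight enters at 0.02 g/kg DMI per kg; breed, chamber and
week are balanced factors with zero effect, since the analysis adjusts for
them without needing them to matter.

Mechanically: per-genus log-normal baselines with a per-sample log-scale
noise of SD 1; the baseline spread is calibrated by bisection so the
Poisson-approximate expected zero fraction at the sampled depths matches
the target; counts are a per-sample multinomial draw at the sampled depth,
so row sums equal depths exactly. One archaeal genus is pinned to the top
of the abundance distribution (the ubiquitous dominant methanogen), keeping
the A:B ratio defined in every sample. Methane yield is built from the
*true* underlying clr abundances, before zero replacement, with the driver
clr centered within diet so the configured diet effect is exactly the true
between-diet difference — an unambiguous ground truth. Diet-affected genera
are drawn from the prevalent quarter of the abundance distribution, and
drivers from its top 15 genera: a genus at the detection boundary has an
observed clr dominated by multinomial sampling noise and imputation, and no
method could recover its association — the ground truth must be observable
to be a test of the method rather than of the sequencer.

What the generator does *not* emulate: ecological interactions and
co-occurrence structure, overdispersion beyond the multinomial (a
log-normal sample effect stands in for it), taxonomic mis-assignment,
longitudinal dynamics, and any built-in archaea-methane relationship (A:B
associations in synthetic output are incidental). The spread of per-genus
prevalence is also narrower than in real 16S tables — around 55 of 203
genera pass the 20% filter, versus about half in comparable real data — so
passing recovery tests demonstrates the machinery works where signal is
observable, not that real data are this clean.

# Numerical choices and test scale

- Q2 threshold 0.0975, VIP threshold 0.8, 4-fold × 20-replicate CV for diet
  discrimination, 3-fold × 20 for within-diet methane prediction — the
  protocol settings this workflow targets.
- Degenerate inputs are named errors: all-zero samples, non-positive
  compositions, single-class folds (resampled up to a retry cap), emptied
  selections (previous set kept, flagged).
- Sub-seeds for folds, permutations and chains are derived from the master
  seed by a multiply-and-add hash kept below $2^{31}$; identical
  configuration implies byte-identical output, and `full_run()` reproduces
  its report exactly under a fixed master seed.
- Pearson correlations on pre-corrected data are reported with the
  dispersion $(1-\rho^2)/\sqrt{n-1}$, the first-order standard error of a
  correlation; pre-correction (`precorrect()`) subtracts posterior-mean
  breed and body-weight contributions, centered so the trait mean is
  preserved.
- Within-diet univariate models include breed and body weight only
  (chamber and week are dropped there), matching the within-diet modelling
  asymmetry of the four-trait diet models.
- No multiple-testing correction is applied to per-genus $P_0$/$P_r$; the
  pipeline instead reports them genus by genus, and the null-data test
  verifies that the selection stage keeps the family-wise flag rate below
  10%.
- Test problem sizes: oracle cross-checks use up to 30 × 20 matrices with
  up to 5 components; calibration and recovery properties use the full
  study-scale generator (26 × 203) over 20 seeds, and Bayesian coverage
  uses 100 simulated datasets at 6,000 iterations.

# Known limitations

- The jackknife SE convention (delete-fold Tukey variance averaged over
  replicates) is one of several defensible choices; with n near 13 it is
  conservative, and regression-mode selection frequently retains the full
  variable set as a consequence.
- The test-set-only permutation keeps the trained model fixed and therefore
  tests the scoring stage, not the full training pipeline; the
  `full_labels` mode exists for the stricter question.
- Marginal association signs (univariate coefficients, one-component PLS
  weights) can differ from the partial coefficients that generated the
  data when driver genera are correlated; at n = 13 this is visible in a
  minority of simulation seeds.
- $P_0 \ge 0.95$ corresponds to a 90% two-sided credible interval
  excluding zero; across many null genera roughly 10% would be flagged
  without the selection stage in front of it.
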