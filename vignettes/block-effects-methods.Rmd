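---
title: "Global and partial block effects by cross-validated PLS regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Global and partial block effects by cross-validated PLS regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blockpath)
```

## The problem

In case-control studies that combine a small panel of clinical variables
with a high-dimensional, strongly collinear omics block (metabolomics,
here), one often wants to know not only how well each input block explains
the binary outcome on its own, but how much it still explains once the
information carried by the other block has been accounted for. blockpath
formalizes this on a three-vertex path diagram with roles A (input block),
B (mediating block) and C (output, usually the coded outcome):

* the **global effect** of A on C is the share of C's variance explained by
  a PLS regression of C on A;
* the **partial effect** of A on C given B first removes, by two PLS
  regressions on B, the parts of C and of A that B explains, and then
  measures the share of the C-residuals' variance explained by the
  A-residuals.

In the unidimensional case (single standardized variables) these two
quantities reduce exactly to the squared correlation $r_{AC}^2$ and the
squared partial correlation
$\left(\frac{r_{AC} - r_{AB} r_{BC}}{\sqrt{(1 - r_{AB}^2)(1 - r_{BC}^2)}}\right)^2$,
which is what the package's central oracle tests assert to `1e-8`. The
multivariate generalization replaces each simple regression by a PLS
regression (PLS1 for a univariate response, PLS2 otherwise) and each
variance ratio by a squared-Frobenius-norm ratio. Classical path-analysis
direct/indirect/total effects via path coefficients are a different
decomposition and are deliberately out of scope: regression coefficients
are not trustworthy under the strong collinearity that motivates PLS in the
first place.

## Estimation procedure

All reported percentages are *cross-validated*: for a given component
count, the out-of-fold predictions of a repeated stratified k-fold CV are
pooled per repetition, giving one explained-variance fraction
$1 - RSS_r / TSS$ per repetition; the effect is the mean (and SD) over
repetitions, in percent. Defaults follow the reference protocol: $k = 10$,
50 repetitions, folds stratified on the outcome so each fold matches the
case/control proportions within one sample, and at most
$\min(n - 1, p, 10)$ candidate components.

The component count of every PLS model is chosen by the
one-standard-error rule on the cross-validated residual-sum-of-squares
curve: take the count minimizing the mean CV-RSS, add one standard
deviation, and keep the smallest count whose mean CV-RSS is under that
threshold. The "one standard deviation" is computed across the CV
*repetitions* at the minimizing count: the repetition is the unit of
replication of the whole resampling scheme, whereas a fold-level SD would
mix stratification artifacts into the band. The reported effect SD is
likewise the repetition-level SD.

For the partial effect, three models are involved and each count is tuned
independently by the same rule: C on B, A on B (a PLS2 model when A has
several variables), and finally the C-residuals on the A-residuals. The two
residualizations are fitted once on the full data; the CV randomness
applies to the final residual-on-residual regression, which is the object
the effect is defined on. A fully nested alternative (residualizing inside
every training fold) would guard against a subtle optimism but changes what
is being estimated; users who prefer it can residualize per fold by calling
the building blocks directly. Residual blocks are *not* rescaled to unit
variance before the final regression: the partial effect is a ratio of raw
residual norms, and rescaling would silently change both the denominator
and the VIPs.

## Numerical choices in the PLS core

The PLS core is a from-scratch NIPALS implementation (inner tolerance
`1e-12`, at most 500 iterations, score iteration initialized from the
response column of maximal variance, X and Y both deflated). It is fully
deterministic and agrees with the classical chemometrics algorithms in
fitted values; the test suite checks its predictions and VIPs against
mixOmics to `1e-8` and against the normal-equation OLS oracle at full rank.
Centering is done inside each model fit with training means — never
globally — so that cross-validation folds do not leak the held-out means;
unit-variance scaling, by contrast, is applied once as preprocessing, as in
the reference protocol (a `scale_in_fold` switch re-scales inside folds for
leakage-averse users). If the residual covariance between X and Y vanishes
(weight norm below `1e-12`), extraction stops early and the model keeps the
components found so far; this is the correct behavior for rank-deficient
bootstrap resamples and for a response orthogonal to the predictors, where
the model degenerates to the mean. A mediator that reproduces the input
block exactly yields zero residuals, and the partial effect is returned as
0 with a warning — the correct limit, not an error.

Variable importance in projection is
$VIP_j = \sqrt{p \sum_a SSY_a (w_{ja}/\lVert w_a \rVert)^2 / \sum_a SSY_a}$
with $SSY_a = \lVert q_a \rVert^2 \, t_a^\top t_a$; the mean squared VIP is
1 by construction, making 1 the natural importance reference. Bootstrap
VIP summaries refit the model on resamples drawn with replacement
*stratified on the outcome* (500 repetitions by default): with ~100
samples, an unstratified bootstrap occasionally produces class-degenerate
resamples, and stratification removes that failure mode while preserving
the class balance the model was tuned on (a flag disables it). The
component count is not re-selected per resample — importance is reported
for the model actually selected on the full data.

## Preprocessing

Intensity-like blocks are prepared as is standard in metabolomics: zeros
are replaced by 80% of the variable's smallest strictly positive value
(the minimum is necessarily taken over positive entries — otherwise it
would be the zero being replaced), then log-transformed, then scaled to
unit variance. The log base defaults to natural log and is configurable;
the choice only rescales columns, which the unit-variance scaling then
removes, so it cannot affect any explained-variance percentage — it does
affect log2 fold-changes. Fold-changes are computed on the
transformed-but-unscaled data (the "neither centered nor scaled" data that
enter the model), per variable as log2(case mean / control mean); they are
reported only for global-effect models, since a fold-change of residuals
has no meaningful scale. The outcome is coded 0/1, centered inside the
models and never scaled; every percentage is invariant to swapping the
coding, which the suite verifies.

## The synthetic generator and what it does (not) show

Because the original cohort blocks are only distributed as supplementary
material of the companion publication, the package ships a latent-factor
generator (`generate_multiblock()`) whose defaults emulate the case-study
shape: 99 samples, a 6-variable clinical-like block, a 102-variable
collinear metabolomics-like block, and a binary outcome obtained by a
median split of the latent score (guaranteeing the near-balanced classes of
a matched design; a logistic draw is available). Noise SDs default to 0.5
against unit-variance latent signal — a moderate signal-to-noise ratio for
standardized clinical panels. Three scenarios encode known mediation truth:
`full_mediation` (population partial effect 0), `independent_inputs`
(partial equals global), and `shared_plus_unique` (partial strictly below
global). A separate trivariate Gaussian generator with closed-form
population effects (`population_effects_unidimensional()`) anchors the
quantitative oracles.

Passing these tests shows that the estimator recovers known latent and
correlation structure under Gaussian noise; it does not show robustness to
what the generator omits — heteroscedastic mass-spectrometry noise, batch
effects, missingness mechanisms, or non-linear clinical-metabolome
coupling.

## Problem sizes used in the shipped checks

The unit tests run the CV machinery at reduced settings (typically k = 5
with 4–8 repetitions and small blocks), which estimate the same quantities
with a wider Monte-Carlo band; the protocol defaults (k = 10, 50 repeats,
500 bootstraps, 99 x 102 blocks) are exercised end-to-end in the
acceptance script, and the mediation-recovery checks sweep 20 generator
seeds at n = 500. The full reproduction of the published cohort numbers
runs automatically once the user points `options(blockpath.nuage_dir = ...)`
at the downloaded supplementary blocks.

## A worked example

```{r example, eval = FALSE}
dat <- generate_multiblock(synthetic_spec(seed = 5))
A <- scale_unit_variance(dat$A)   # clinical-like input block
B <- scale_unit_variance(dat$B)   # metabolomics-like mediator
cv <- cv_config(k = 10, repeats = 50, strata = dat$outcome$labels,
                seed = 13)
report <- run_path(path_diagram("A", "B"), list(A = A, B = B),
                   dat$outcome, cv, n_boot = 500,
                   unscaled_blocks = list(A = dat$A))
report
effects_table(report)
vip_table(report, "global")
```

## Known limitations

* Only three-vertex path diagrams (one input, one mediator, one output);
  multi-mediator DAGs and sequential multi-block orthogonalization are out
  of scope.
* The VIP importance threshold is analyst-chosen (1 is the algebraic
  reference; stricter values are appropriate for wide blocks); the package
  exposes it but never derives it from the data.
* Effects are predictive variance shares, not causal estimands: the path
  diagram encodes a conditioning order, not a causal claim.
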