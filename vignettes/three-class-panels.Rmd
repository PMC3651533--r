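---
title: "Evaluating biomarker panels across three ordered disease classes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating biomarker panels across three ordered disease classes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(vuspanel)
```

## The problem

Serum tumor markers for pancreatic carcinoma are usually judged by how well
they separate cancer from everything else. Clinically, however, the relevant
question is a three-way one: is a patient healthy (H), suffering from
pancreatitis (P), or carrying a carcinoma (C)? A marker useful at the bedside
must resolve all three states *simultaneously*. `vuspanel` implements a
complete evaluation framework for this setting: a rank-based three-class
selectivity measure, two routes for building multivariable "meta-marker"
panels, and a bootstrap non-inferiority/superiority test that compares a
panel against a conventional reference marker (a CA 19-9-like quantity) on
the same subjects.

## Volume under the ROC surface

For a scalar marker and three classes in a declared increasing order
H < P < C, the empirical VUS is

$$\widehat{VUS} = \frac{1}{n_1 n_2 n_3}\sum_{i,j,k} w(x_i, y_j, z_k),$$

the fraction of triples (one subject per class) that the marker orders
correctly. An uninformative marker scores 1/6 — the volume of the region
where a random triple happens to be in increasing order — and a perfect
marker scores 1. The estimator is exactly the triple-sum above, computed by
sorted rank counting in $O(n\log n)$; an $O(n^3)$ brute-force enumeration
serves as the oracle in the test suite.

Two tie conventions are available. The default (`tie_rule = "partial"`)
credits 1/2 to a triple with exactly one ordering-consistent equality and
1/6 to a triple tie, so that a constant marker scores exactly the
random-classifier value 1/6. The `"strict"` rule counts ties as failures and
is retained for sensitivity analysis. The class order is always a declared
input and never inferred or auto-flipped: markers that *decrease* along the
clinical order legitimately score below 1/6, which is diagnostic information
in itself.

Confidence intervals are stratified-bootstrap percentile intervals
(resampling within each class, default `B = 2000`); a BCa variant is
available behind `method = "bca"`. The empirical ROC surface — true class
rates $(F_1(c_1),\, F_2(c_2) - F_2(c_1),\, 1 - F_3(c_2))$ over all threshold
pairs $c_1 \le c_2$ — is exported as a grid for external 3-D rendering, and
its numerically integrated volume reproduces the strict-tie VUS exactly on
tie-free data (a cross-check the suite enforces at $10^{-9}$).

```{r vus-example}
tab <- generate_cohort(cohort_config(seed = 7))
tr <- marker_triple(tab$M01, tab$class, order = c("H", "P", "C"))
vus_bootstrap_ci(tr, B = 500, seed = 1)
```

## Panel construction

Two complementary panel builders operate on a `candidate_set` (feature
matrix, three-level classes, optional forced-in features such as the
reference marker):

**Bayes-averaged multinomial logit.** The multinomial logit is approximated
by the Begg–Gray binary decomposition: one binary logistic regression per
non-baseline class against the baseline (healthy controls by default,
configurable), fitted on the samples of those two classes only. The total
deviance plus $p \log n$ gives a subset BIC; all subsets containing the
forced-in features up to `max_subset_size` are enumerated, subsets within
Occam's window ($BIC \le BIC_{min} + 2\log r$, default ratio $r = 20$) are
retained, and posterior weights $\propto e^{-BIC/2}$ average the
coefficients (absent features contribute zero). Perfectly separated fits are
flagged and refitted with a small ridge penalty rather than discarded. The
test suite verifies the approximation against a full maximum-likelihood
multinomial fit and the weights' invariance under affine feature rescaling.

**CAR scores.** As a validation route, classes are encoded by fixed
pseudo-responses (carcinoma 1.0, healthy 0.3, pancreatitis 0.1 — kept
configurable since any such encoding is somewhat arbitrary) and the
correlation-adjusted marginal correlations
$\omega = R_{XX}^{-1/2}\, r_{Xy}$ are computed; the top-$k$ features by
$\omega^2$ (default $k = 2$, matching the penalized model's size) enter an
ordinary least-squares predictor. When the feature correlation matrix is
ill-conditioned (condition number above $10^6$) it is shrunk toward the
identity with the analytic Schäfer–Strimmer intensity.

**Scalarization.** A three-class probabilistic model has no unique scalar
marker. We score samples by the expected ordinal class
$\sum_c \mathrm{rank}(c)\,P(c)$ with ranks (0, 1, 2) along the declared
order, which respects the ordering the VUS measures; $P(\text{carcinoma})$
alone would discard the pancreatitis/healthy distinction. The CAR predictor
is its fitted linear predictor. Monotone single-feature models therefore
reproduce the raw feature's VUS exactly (rank invariance).

## Non-inferiority and superiority

The inference target is $\Delta_{VUS} = VUS_{panel} - VUS_{reference}$ on
paired subjects. `B_outer` stratified resamples yield the
$(100 - 2\delta)\%$ percentile interval of $\Delta^*$ (90% at the default
margin $\delta = 0.05$, an absolute VUS difference considered medically
reasonable); non-inferiority is declared when the lower bound exceeds
$-\delta$ and superiority when it exceeds 0. Because both markers are
evaluated on the *same* resample, a candidate that is a monotone transform
of the reference produces identically zero differences — the suite uses this
to assert pairing. An optional studentized mode uses `B_inner` nested
resamples for a bootstrap-t interval; the percentile construction is the
default because it is fully determined by the stated interval level.
Stratified resampling means a class can never empty in a resample, so no
degenerate-resample handling is needed.

## The synthetic cohort generator

No patient-level data ship with the package; every downstream stage is
exercised on generated cohorts that mimic the structure of a serum
amino-acid study:

* three classes of 40/23/40 subjects (healthy, pancreatitis after exclusion
  of three incomplete samples, carcinoma);
* 26 metabolite concentrations from a Gaussian copula: correlated latents
  (default block structure, four variables per block at latent $\rho = 0.6$)
  with class-dependent latent shifts, pushed through the fixed monotone map
  $\exp(\mu_j + \sigma_j z)$ to a positive µmol/L scale. Because all
  downstream selectivity measures are rank-based, the link choice is
  inconsequential while the latent correlation controls Kendall's
  $\tau = (2/\pi)\arcsin(\rho)$ analytically — this is what makes the
  generator's dependence calibratable and testable;
* five informative metabolites by default (two carcinoma-elevated, one
  pancreatitis-specific, one decreasing, one weakly increasing), the rest
  null;
* a log-normal reference marker (meanlog 3.0/3.6/4.4, sdlog 0.8/1.0/1.1 per
  class) — right-skewed, elevated mainly in carcinoma, of deliberately
  moderate selectivity like CA 19-9;
* 3% MCAR missingness in the reference marker only (about 3 of 103 values),
  mirroring the scale of missingness such studies report. Non-random
  missingness is *not* simulated: samples with failed panels are handled by
  the exclusion rule, which is how such samples are treated in practice.

What the generator does **not** emulate: analytical variability per
metabolite (flow-injection MS/MS CVs), batch or sample-set effects,
covariate structure (age, BMI), and non-Gaussian latent dependence. Passing
tests therefore demonstrate the correctness and calibration of the
*methods*, not any claim about real-patient selectivity values.

## Preprocessing

* **Exclusion**: samples whose count of missing metabolite features exceeds
  a threshold (default 0) are dropped, with a log; dropping below 2 samples
  per class errors instead.
* **Multiple imputation** of the reference marker: three chains (default) of
  bootstrap regression — refit a linear model of the log marker on class and
  the three metabolites most correlated with it on a stratified bootstrap
  resample, impute prediction plus a resampled residual — iterated until the
  across-chain Gelman–Rubin $\hat R$ of every imputed cell is at or below
  1.1; chain draws are averaged. Iteration counts are an observed outcome
  reported in the result, not a contract.
* **Yeo–Johnson** transformation fitted by profile maximum likelihood on
  $\lambda \in [-5, 5]$; the transform is strictly increasing for every
  $\lambda$, so rank statistics ($\tau$, VUS) are invariant to it — both
  property-tested.
* **PCA** on the correlation matrix of the transformed metabolites (the
  only convention under which the Kaiser eigenvalue > 1 retention rule is
  meaningful, given that concentrations span orders of magnitude).
  `retained_k` is overridable because the Kaiser count is an outcome, not a
  design constant; loadings signs are fixed by making each vector's
  largest-magnitude entry positive.

## Descriptive battery

Anderson–Darling composite normality (via the established `nortest`
implementation), Fligner–Killeen variance homogeneity, exact binomial test
of group sex ratios, Games–Howell pairwise comparisons (Welch statistic,
Welch–Satterthwaite df, studentized-range reference — raw pairwise P values
are reported since the studentized-range calibration already embeds
familywise control), and the Kendall $\tau$-b matrix with Hochberg-adjusted
significance over the single family of all metabolite pairs. $\tau$-b is
used because quantified concentrations contain ties after rounding.

## Numerical choices and defaults

| parameter | default | rationale |
|---|---|---|
| `tie_rule` | partial | constant marker scores exactly 1/6 |
| VUS bootstrap `B` | 2000 | standard protocol for marker CIs |
| CI method | percentile | simplest fully-determined construction; BCa optional |
| margin `delta` | 0.05 | absolute VUS difference deemed clinically acceptable |
| `B_outer` / `B_inner` | 1000 / 1000 | outer percentile CI; inner only for studentized mode |
| Occam ratio | 20 | standard model-averaging window |
| pseudo-responses | 1.0 / 0.3 / 0.1 (C/H/P) | fixed encoding, exposed as config |
| CAR `k` | 2 | matches the averaged model's typical panel size |
| imputation chains / $\hat R$ | 3 / 1.1 | conventional MI convergence protocol |

Degenerate inputs are handled explicitly rather than silently: constant
variables error in normality tests and transforms and are flagged (not
zeroed) in the correlation matrix; zero-spread group pairs with equal means
return $P = 1$ in Games–Howell while unequal means error; rank-deficient
feature subsets are rejected from model averaging; perfectly separated
logits are ridge-stabilized and flagged.

## Problem sizes used in the test suite

The statistical calibration checks run at deliberately modest sizes chosen
to keep Monte-Carlo error well inside the asserted bands: CI coverage at the
study's 40/23/40 geometry with 500 replicates of a 500-resample bootstrap;
non-inferiority size at the exact margin (true $\Delta = -0.05$, constructed
from Gaussian shift alternatives whose true VUS is obtained by numerical
integration) with 500 replicates at `B_outer = 300`; familywise size of
Games–Howell under a heteroscedastic three-group null with 1000 replicates;
model-recovery across 100 seeded cohorts. These sizes are the package's own
reproducibility choices and are fixed in the suite.

## Worked pipeline run

```{r pipeline}
cfg <- pipeline_config(
  simulate = cohort_config(seed = 11),
  vus_B = 300, B_outer = 300,  # reduced for the vignette
  seed = 11)
res <- run_pipeline(cfg)
res
```

The report bundle (written when `out_dir` is given) contains the
descriptive table, the pairwise-P table, the $\tau$ and adjusted-P matrices,
the per-feature VUS table (sorted, with the trailing "Random" 1/6 reference
row), the four predictor VUS results, ROC-surface grids, the forest-plot
table, and a JSON manifest of all seeds and settings sufficient to re-run
bit-identically.

## Known limitations

* The VUS here is the exact empirical estimator; smoothed or parametric
  estimation, partial VUS, and misclassification-cost weighting are out of
  scope.
* Subset enumeration in `bma_mlogit` is exhaustive up to `max_subset_size`;
  with very many candidate features a stochastic search would be needed.
* The imputer assumes a log-linear marker–predictor relationship; grossly
  non-log-linear reference markers would need a different predictive model.
* MCAR is the only simulated missingness mechanism; informative missingness
  must be handled by exclusion, as in the intended study design.
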