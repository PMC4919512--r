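---
title: "Multifactorial trajectory modelling of disease progression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multifactorial trajectory modelling of disease progression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multitraj)
```

## The problem

Late-onset neurodegenerative disease involves several concurrent biological
factors — amyloid deposition, glucose metabolism, cerebral blood flow,
resting functional activity, grey-matter structure — each measurable per
brain region by imaging, alongside scalar markers (cognitive scores, CSF and
plasma analytes). `multitraj` reconstructs, per biomarker, a characteristic
trajectory over 30 years of aging for each clinical transition (healthy
aging and progression to early MCI, late MCI or dementia), quantifies each
biomarker's *abnormality* relative to healthy aging, and derives a
data-driven temporal ordering of the factors.

## The observation model

Each standardized biomarker observation for subject $j$ at visit $m$ is
modelled as

$$y_{jm} = \mathbf{x}_{jm}^\top\boldsymbol\beta
  + b_j + b_{\mathrm{age},j}\,\mathrm{age}_{jm} + \varepsilon_{jm},$$

where $\mathbf{x}$ holds an intercept, five main risk factors — age,
disease state DS (an ordinal 1–4 code: HC, EMCI, LMCI, dementia, used
numerically), sex (0/1), education (years) and apoe4 allele count (0/1/2) —
and all ten pairwise interactions: 16 fixed coefficients. $b_j$ and
$b_{\mathrm{age},j}$ are subject-level random intercept and age slope.
Three variants are fitted per biomarker and compared by
$\mathrm{BIC} = k\ln n - 2\ell$:

1. **fixed_robust** — no random effects, estimated by iteratively
   reweighted least squares with Tukey bisquare weights (tolerance $10^{-8}$
   on the relative coefficient change, at most 50 iterations);
2. **mixed_intercept** — adds $b_j$, maximum likelihood;
3. **mixed_intercept_slope** — adds $b_j$ and $b_{\mathrm{age},j}$
   (correlated), maximum likelihood.

Design notes on the fitting contracts:

* ML (not REML) is used for the mixed fits so log-likelihoods are comparable
  across variants under one BIC scale.
* The robust variant has no likelihood of its own; we use the Gaussian
  likelihood of *all* residuals evaluated at the robust coefficients. Using
  the bisquare-*weighted* residual variance instead systematically deflates
  the variance on heavy-tailed data and lets the fixed model spuriously beat
  a true mixed model — the unweighted working likelihood avoids that.
* The random age slope is reparameterized internally on centred/scaled age
  for optimizer conditioning; reported variance components are mapped back
  to the raw-age scale. This changes nothing statistically.
* Parameter counts: 17 (fixed), 18 (+intercept variance), 20 (+slope
  variance and intercept–slope correlation).
* Biomarkers are standardized to sample mean 0, sd 1 (denominator $n-1$)
  across all retained subject-visits *before* fitting, so abnormality values
  of different biomarkers are comparable; constant biomarkers are dropped
  with a warning.

## Quality control

Three ordered steps precede fitting:

1. **Converter removal** — any subject whose DS changes across visits is
   removed entirely, because a within-subject diagnosis change contradicts
   the stable-group assumption of the group-conditional steps below.
2. **Diagnosis-likelihood filtering** — each subject gets a
   leave-one-subject-out Gaussian class-conditional log-likelihood of its
   multimodal feature vector (region-averaged value per imaging factor plus
   scalars, averaged over visits) under its assigned group, rank-normalized
   within group to (0, 1]. Subjects strictly below the within-group 10th
   percentile are removed. The percentile is computed per group (not
   pooled) so small groups are not disproportionately deleted; quantile
   type 6 is used so the $p \to 0$ limit removes nobody while the decile cut
   on $n = 100$ untied scores removes exactly 10; the strictly-below rule
   means all-tied scores remove nobody.
3. **Mahalanobis outlier removal** — within each clinical group, records
   whose squared Mahalanobis distance exceeds the $\chi^2_d(0.95)$ quantile
   are flagged and only the offending biomarker/modality values are deleted
   (not the subject). Imaging factors are tested multivariately across all
   regions ($d$ = number of regions); scalars univariately. When a group is
   too small for a plain covariance ($n < d + 2$) a Ledoit–Wolf-style
   scaled-identity shrinkage covariance is substituted; the $\chi^2$
   reference keeps the full feature count. With ample data the plain sample
   covariance is used, which keeps flagging exactly invariant under affine
   rescaling of any single biomarker.

The likelihood-score construction is our own concrete choice for a step that
admits many definitions; it is deliberately simple, symmetric, and fully
testable (identical subjects receive identical scores; a subject at the
group centroid receives the maximal score).

## Marginalization and trajectories

The fitted fixed-effects predictor is averaged over sex, education and apoe4
to leave $g(\mathrm{age}, \mathrm{DS})$; random effects are set to their
zero population mean. Because the model is linear with pairwise
interactions, $g$ is exactly $a + b\,\mathrm{age} + c\,\mathrm{DS} +
d\,\mathrm{age}\cdot\mathrm{DS}$ with covariate-averaged coefficients. Two
weightings are exposed:

* **uniform** (default): sex and apoe4 uniform over their observed
  categories, education uniform over its observed min–max range. The
  predictor is linear in education, so the range average equals evaluation
  at the midpoint — implemented analytically and verified against a
  dense-grid average in the tests (agreement to $10^{-10}$).
* **empirical**: the joint empirical distribution of subject covariates.

Trajectories evaluate $g$ on a weekly age grid — 1,560 points spanning ages
40–70 inclusive — along a DS path per transition: constant 1 for healthy
aging; otherwise a ramp from 1 at age 40 to the terminal DS (2, 3 or 4) at
age 70. The ramp is linear by default or logistic ("sigmoid", midpoint age
55, 5-to-95% rise width 20 years, both configurable). A raw logistic never
attains its asymptotes, so the sigmoid is affinely normalized to hit the
endpoint values exactly at the grid boundaries; this preserves the midpoint
symmetry (DS = 2.5 at age 55 for the full transition) and keeps every path
starting at DS = 1. Intermediate transitions reach their terminal DS exactly
at age 70 so all transitions are comparable on one grid.

## Abnormality metrics

The abnormality curve of a diseased transition is the pointwise absolute
difference from the same biomarker's healthy-aging trajectory. The raw
abnormality is its trapezoidal integral over the grid; dividing by the
shared constant $K$ (the maximum raw area in the comparison set) yields
total indices in $[0, 1]$ with exactly one biomarker (up to ties) at 1. By
default $K$ is shared across all biomarkers passed in; a per-panel mode
(`k_scope = "group"`, e.g. CSF vs plasma) is available because published
analyses sometimes normalize panels separately. Intermediate indices
truncate the integral at the EMCI and LMCI time points — the first grid
ages where the HC-to-dementia DS path reaches 2 and 3 (ages 50 and 60 under
the linear ramp) — and divide by the same $K$; they protect biomarkers that
are abnormal early but renormalize later from appearing unaffected.

## Ordering

* **Hierarchical matrix** — for each factor pair, region and time point the
  strictly larger abnormality scores 1; exact ties score 0.5 each, which
  keeps $H_{ij} + H_{ji} = 100$ exactly (ties are measure-zero on real data
  but common on synthetic). Rows/columns are reordered by total dominance.
* **Regional vulnerability** — a region's weight is its summed total index
  across factors, normalized to sum 1. Weights derive from time-integrated
  indices rather than instantaneous abnormality.
* **Factor curves** — per factor, the vulnerability-weighted (convex)
  average of regional curves; scalar biomarkers pass through unweighted;
  all curves are divided by the single global maximum.
* **Ranking** — descending area under the normalized curves (or value at a
  fixed age); exact ties are broken alphabetically and flagged.

## Bootstrap

`bootstrap_pipeline()` resamples *subjects* with replacement (all visits of
a subject travel together, preserving the within-subject correlation the
random effects model assumes), reruns the fit-to-ordering pipeline per
replicate, and reports replicate means with 2.5/97.5 percentile bands
(percentile rather than normal-approximation intervals; B = 500 by
default). Per-replicate seeds derive from the root seed by counter, so any
replicate is individually reproducible. Standardization happens once before
resampling — it is part of preprocessing, and it makes the noiseless
sanity case (all replicates identical, zero-width bands) exact. Replicates
whose fit fails are logged and skipped; more than 20% failures abort.
Storing full replicate distributions for per-biomarker curves costs
(grid × biomarkers × B) doubles, so the `keep` argument selects which
quantities get bands; at desk scale the default keeps everything.

## The synthetic cohort generator

`generate_cohort()` draws cohorts from exactly the assumed observation
model: subject-level covariates (baseline age uniform over 40–70, 1-year
visit spacing, sex Bernoulli(0.5), education uniform integer 6–20, apoe4
multinomial (0.6, 0.3, 0.1), DS multinomial over the four groups, constant
within subject), then values from the 16-term fixed predictor plus subject
random intercept/age-slope and Gaussian noise (sd 1 by default). A factor
ordering is planted through factor-specific DS coefficients — by default
1.25, 1.00, 0.75, 0.50, 0.25 sd per DS unit for vascular, amyloid,
metabolic, functional, structural (0.25-sd adjacent gaps), values at which
the ordering is comfortably but not trivially recoverable at a few hundred
subjects — so downstream analyses can be checked against known truth.
Clinical converters (DS raised from a random later visit) and gross
outliers (a fixed multiple of the within-group sd added to chosen records)
are planted from independent random streams derived from the root seed, so
planting never perturbs the core cohort draws.

What the generator does *not* emulate: real visit schedules and attrition,
missing data, non-Gaussian measurement error, spatial correlation between
regions, nonlinear age effects, and covariate-dependent group assignment.
Tests passing on these cohorts therefore validate the statistical machinery
under its own assumptions — not robustness to the full messiness of
observational cohorts.

## Numerical choices and degenerate inputs

* Exact linear data short-circuits the robust IRLS loop (the M-estimate
  coincides with least squares and the scale estimate would be 0).
* Boundary (zero) variance estimates in mixed fits are allowed and
  reported; a single visit per subject triggers a documented
  identifiability warning rather than an error.
* All-zero abnormality curve sets leave indices at 0 with a warning instead
  of dividing by $K = 0$.
* Truncated integrals interpolate linearly at stage ages that fall between
  grid nodes.
* Rank-deficient designs raise an error listing the collinear columns.

## Problem sizes used in the test-suite

The packaged checks run at deliberately modest scale: ordering recovery
uses 300 subjects × 4 visits × 10 regions over 50 replicates; BIC
selection consistency uses 2,000 observations × 100 replicates per variant;
bootstrap coverage uses B = 100 over 20 outer replications on a reduced age
grid. These sizes make the full suite run in minutes while leaving the
statistical margins (e.g. ≥ 90% selection consistency) wide.

## Known limitations

* Everything is linear in the predictors; strongly nonlinear biomarker
  dynamics are only captured through their linear tendency.
* The analysis orders factors by abnormality magnitude over time; it does
  not estimate causal interactions between factors.
* The DS code enters numerically (1–4), treating clinical stages as
  equispaced along the progression axis.
* With noise sd 1 and a few hundred subjects, the sampling error of the
  marginalized DS contrast is of order 0.05–0.1 sd; abnormality values
  below that scale are not distinguishable from zero at such cohort sizes.
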