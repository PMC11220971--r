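---
title: "Latent-class trajectory modelling of cognitive resilience: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent-class trajectory modelling of cognitive resilience}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`resiltraj` identifies subgroups of longitudinal cognitive trajectories in
cognitively unimpaired older adults, conditional on baseline demographics and
imaging biomarkers of Alzheimer's-disease pathology, and characterizes the
subgroups on factors thought to confer cognitive resilience. This vignette is
the package's account of the statistics it implements, the conventions it
adopts where several were defensible, and what its tests do and do not
establish.

## The latent class mixed model

Cognition is measured repeatedly (a composite such as the PACC-5) at
irregular visit times. We posit `G` latent classes; subject `i` belongs to
class `g` with probability

$$\pi_g = \frac{e^{\xi_g}}{\sum_h e^{\xi_h}}, \qquad \xi_G = 0,$$

an intercept-only multinomial logit: covariates deliberately do *not* enter
the membership model, because the membership itself is the object of
discovery. Conditional on class, a latent cognitive process follows a linear
mixed model

$$\Lambda_{ij} = X_{ij}^\top\beta + U_{ij}^\top\delta_g + Z_{ij}^\top b_i + \varepsilon_{ij},$$

with

* $X$: class-common covariates — baseline age (years), sex (1 = female),
  neocortical amyloid (DVR/SUVR), entorhinal tau (SUVR), adjusted hippocampal
  volume (mm³). Their effects $\beta$ are shared across classes so that the
  classes are trajectory classes *adjusting for* pathology, not pathology
  classes.
* $U$: class-specific intercept and slope in time (years from the subject's
  cognitive baseline) — the trajectory itself, $\delta_g$.
* $Z$: subject random intercept and slope, $b_i \sim N(0, B)$ with
  unstructured $B$ shared across classes (an optional proportional
  class-specific scaling $\omega_g$ exists but is off by default).
* $\varepsilon_{ij} \sim N(0, \sigma_\varepsilon^2)$ independent measurement
  noise.

The observed score is tied to the latent process through a strictly
increasing parametric link, $h(y_{ij}; \eta) = \Lambda_{ij}$, whose Jacobian
$\sum_j \log h'(y_{ij})$ enters the likelihood. Because the random effects
are Gaussian and enter linearly, they integrate out exactly: subject `i`'s
contribution is a log-sum over classes of multivariate-normal densities with
covariance $Z_i B Z_i^\top + \sigma^2 I$. No numerical integration is used in
the estimation path; Gauss–Hermite quadrature appears only in the test suite
as an independent oracle. The implementation reduces each subject–class term
to 2×2 algebra via the Woodbury identity, in compiled code.

## Link families and identifiability

Four families are provided:

* **linear** — used as the identity at estimation time; all `G` class
  intercepts and $\sigma_\varepsilon$ are free.
* **splines (equidistant / quantile knots)** —
  $h(y) = \eta_0 + \sum_k \eta_k^2 I_k(y)$ over monotone I-splines. Squaring
  the coefficients enforces monotonicity without constraints. With
  `n_knots` total knots (boundary knots at the observed minimum and maximum)
  the basis has `n_knots + 1` members, i.e. `n_knots + 2` link parameters;
  the basis is built as right partial sums of cubic B-splines, the standard
  identity linking B-splines to integrated M-splines. The default
  "5-equi-splines" therefore carries 7 link parameters.
* **beta** — the outcome is affinely rescaled to the open unit interval
  (margin $10^{-4}$) and passed through a Beta CDF with two positive shape
  parameters, then located/scaled: 4 parameters.

When the link is estimated, the latent scale must be pinned: we fix
$\sigma_\varepsilon = 1$ and the class-1 latent intercept to 0, letting
$\eta$ carry location and scale. This is the usual latent-process convention
and makes free-parameter counts agree across families for the same `G`
(checked in the tests), so SABIC comparisons across links are fair.

## Estimation, convergence, grid search

The likelihood is maximized by BFGS ascent followed by damped-Newton
(Marquardt) refinement on the numerical gradient and Hessian. Convergence is
declared only when, on an accepted step, all three of the following hold with
tolerance $10^{-4}$ (at most 500 iterations): largest parameter change;
log-likelihood change; and the scaled gradient criterion
$g^\top H^{-1} g / \mathrm{npar}$. Non-convergence is reported, not raised —
the selection layer filters such fits.

Mixture likelihoods are multimodal, so multi-class fits are started from a
converged one-class fit and run as a grid search: each of `n_departures`
(default 15) random departures jitters the class-specific intercepts and
slopes around the one-class solution with Gaussian noise scaled to half the
latent-outcome SD (slope jitter at a quarter of that — slopes live on a
smaller scale), runs a short burn-in fit (default 30 iterations), and the
best interim log-likelihood is optimized to full convergence. Departure
seeds are derived deterministically from the user seed and logged, making
every fit reproducible bit-for-bit.

For transfer to an independent cohort the favored link/class configuration is
refit with `n_repeats` (default 10) independent grid searches and the *most
frequent* solution is kept. "Same solution" is not defined upstream; we
define it as identical modal partitions up to label permutation (pairwise
adjusted Rand index of 1), with frequency ties resolved toward the higher
log-likelihood and flagged.

## Model selection and labelling

Candidates (default 4 link families × 2–7 classes) are filtered to converged
fits whose smallest modal class holds at least 5% of the sample, ranked by
SABIC $= -2\ell + \mathrm{npar}\,\log((N+2)/24)$, and the lowest-SABIC
candidate with relative entropy above 0.5 is favored. Relative entropy is
$1 - \frac{-\sum_{i,g} p_{ig}\log p_{ig}}{N \log G} \in [0, 1]$. The
published procedure also weighed *theoretical plausibility* (trajectory
shapes, plausible resilience prevalence); that criterion is not
operationalizable, so the full ranking is retained in the report for human
review rather than automated — the entropy gate is hard, SABIC is the sole
ranking key.

Three-class fits are labelled by rule: predicted class slopes are compared
first — the class whose slope falls below the others by more than a margin
(default 0.05 latent units/year) is *Declining*; of the remainder the higher
baseline level is *Resilient*, the lower *Normal*. Keying on slope first
matters because in transfer cohorts the declining class can have the lowest
baseline level. Ties within tolerance yield generic labels plus a warning
rather than a silent guess. Modal assignments break posterior ties toward
the lower class index, for determinism.

## Preprocessing conventions

* **Hippocampal volume**: `adj_hv = raw_hv − b (eTIV − mean eTIV)`, with `b`
  the OLS slope of raw volume on eTIV estimated *within the cohort being
  processed* (the estimation sample is not specified upstream; external
  coefficients can be injected). Adjusted volume is exactly uncorrelated with
  eTIV in the fitting cohort, a tested invariant.
* **Cognitive composite**: mean of five test z-scores referenced to cohort
  baseline means/SDs; lower-is-better components are sign-flipped. The
  missing-component policy (all five required, relaxable with a logged
  minimum) is ours; the source is silent.
* **Inclusion**: the analysis baseline is the first cognitive visit within
  365 days (inclusive) of the subject's first tau-PET scan; earlier
  (retrospective) visits are dropped because tau burden before the scan is
  unknown; at least 2 retained visits and complete covariates are required.
  Filtering is idempotent and every exclusion is logged with a reason.
* **Resilience residual**: baseline cognition regressed on age, sex, amyloid,
  tau, adjusted hippocampal volume; the residual (observed − predicted) is
  divided by the residual SD (denominator $n - p - 1$). "Standardized
  residual" admits several readings; we chose residual-SD standardization
  over internal studentization.
* **Thresholds**: amyloid positivity strictly above 1.185 DVR, hippocampal
  atrophy strictly below 6,723 mm³ — boundary values are negative, matching
  the printed strict inequalities.
* **Activity, occupation, deprivation**: past/current cognitive activity are
  means of 25/11 items on a 1–5 frequency scale (computed when ≥ 80% of
  items are answered); occupational complexity reverses Data (0–6),
  People (0–8), Things (0–7) ratings and sums to 0–21; national
  area-deprivation percentiles are cut into tertiles of a reference
  distribution.
* **Progression**: event at the first of two consecutive visits with nonzero
  global CDR, or at a final nonzero visit; otherwise censored at the last
  CDR assessment.

## Subgroup characterization

Continuous factors are compared by tie-corrected Kruskal–Wallis tests with
Dunn's post-hoc pairwise z tests (two-sided), Hochberg-corrected within each
variable's pairwise family; categorical factors by Pearson's χ² switching to
Fisher's exact test when any expected cell count is below 5 (a conventional
rule; the source lists both tests without one). Regional tau is analyzed by
per-region OLS of SUVR on subgroup with Benjamini–Hochberg FDR across the
regions. The published table prints a single estimate per region, so the
subgroup enters as a Resilient-versus-rest indicator by default, with factor
coding available behind a flag — the upstream coding is ambiguous. A
packaged copy of that published 33-region table lets the FDR machinery be
validated against printed adjusted p-values: the largest raw p is preserved
exactly, 31 regions share one step-up value, and the smallest-p region
reproduces to within raw-p rounding. Trajectory separation is confirmed by a
one-class mixed model (the G = 1 reduction of the same engine) with subgroup
dummies and subgroup × time interactions, Wald-tested with numerical-Hessian
standard errors.

## The synthetic cohort generator

Real cohorts of this design are access-restricted, so the generator is a
first-class module emulating the study conditions: three trajectory classes
mixed 71 / 22.5 / 6.5%, latent intercepts (0, 0.7, 0.9) composite units and
slopes (−0.02, −0.02, −0.30) per year; 2–10 visits per subject (truncated
Poisson with mean 6, matching a median of 6) spaced ~1.05 years with jitter,
follow-up capped at 10 years; baseline age N(71.89, 9.41²), 59% women,
amyloid N(1.17, 0.19²) truncated above 0.9 DVR, entorhinal tau
N(1.33, 0.28²) truncated above 1, and raw hippocampal volume regressing on
intracranial volume (slope 0.003) so the head-size adjustment is
non-trivial; covariate effects on the latent process of realistic sign and
size (e.g. −0.4 per DVR of amyloid). Resilience-related factors are drawn
class-conditionally around published group means (verbal IQ
120.77/126.09/124.00; past activity 2.97/2.83/2.44), with a null mode for
type-I checks; progression times are exponential with class hazards
(0.030/0.046/0.067 per year) chosen to reproduce roughly 16/24/33%
progression over a ~6-year exposure.

Two generator choices deserve comment. First, the random-effect SDs (0.22
intercept, 0.05 slope) and residual SD (0.18): together with the covariate
effects they give within-class observed baseline SDs near the published
0.55–0.71 and a three-class discriminability (relative entropy ≈ 0.85)
matching the published favored model (0.847). Substantially larger
within-class heterogeneity would make the two stable classes statistically
non-identifiable, contradicting that published discriminability. Second,
covariates are independent of class by default — mirroring the finding that
subgroups did not differ on age, sex or pathology — with a confounded mode
for stress-testing. An optional monotone cubic warp distorts the observed
scale to exercise the spline links.

What passing tests on these data do *not* show: robustness to non-Gaussian
random effects, informative visit schedules or dropout, measurement
non-invariance over time, or covariate-dependent class membership — none of
which the generator produces.

## Numerical choices and problem sizes

Continuous covariates are z-scored internally for optimizer conditioning and
estimates are back-transformed (class intercepts absorb the centering
shift). Spline coefficients are squared rather than constrained;
$\sigma_\varepsilon$ is estimated as $|s|$. Degenerate inputs fail loudly:
zero eTIV variance, exact collinearity in the residual regression, all-censored
survival input, G = 1 entropy. Posterior computations run in log space.

Recovery and enumeration experiments in the tests use cohorts of 300
subjects with mixing 0.70/0.22/0.08 — the smallest class then holds ~24
subjects, large enough for the 5% admissibility rule to be meaningful — with
8 (recovery) or 6 (enumeration over G = 2–4, 20 replicate cohorts) random
departures; slope recovery is judged against two Monte-Carlo standard errors
from 10 replicate cohorts. The end-to-end determinism check runs a reduced
candidate grid on a 120-subject cohort twice and compares output bytes.
These sizes are the package's own choices balancing statistical resolution
against test-suite turnaround.

## Known limitations

* Point estimation and classification only: no Wald/likelihood inference on
  class parameters, no bootstrap likelihood-ratio test for the number of
  classes.
* The membership model is intercept-only; covariate-dependent membership is
  out of scope.
* Single (univariate) longitudinal outcome; no joint survival–longitudinal
  modelling — progression is analyzed separately by Kaplan–Meier.
* The beta link's boundary rescaling makes its tails insensitive to extreme
  outcomes; spline links require outcomes within the knot span (callers must
  clamp or reject at read time).
* SABIC-based enumeration is consistent but not infallible at modest N; the
  enumeration test asserts a majority preference across replicates, not
  certainty.
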