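---
title: "Modelling perinatal connectivity growth with penalized splines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling perinatal connectivity growth with penalized splines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcgrowth)
```

## The scientific setting

Seed-based resting-state fMRI summarises a scan of a fetus or neonate as a
handful of Fisher-z connectivity strengths: the mean z over the node pairs
inside the default mode (DMN), frontoparietal (FPN) and salience (SN)
networks, and over the pairs between each network pairing. Tracked against
postmenstrual age (PMA) from 30 to 44 weeks, these strengths describe how
the networks synchronise and segregate across the fetal-to-neonatal
transition. The design this package targets combines a longitudinal
fetal–neonatal cohort (scans near 31, 35 and 43 weeks), a cross-sectional
neonatal cohort (~44 weeks) and a dHCP-style neonatal cohort (~40 weeks),
so the data are unbalanced, repeated within subject, and heterogeneous
across acquisition protocols.

## The growth model

`pspline_growth()` fits

$$y_{ij} \sim N\!\big(B(t_{ij})\beta + \delta_{c(i)} + a_i + b_i(t_{ij}-t_0)
+ \gamma x_i,\ \sigma^2_{c(i)}\big)$$

* **Mean curve.** $B(t)$ is a cubic B-spline with a knot at every week
  from 30 to 44 and replicated boundary knots, giving $K = 17$ basis
  functions that form a partition of unity. Cubic degree is the standard
  choice for smooth growth curves; the degree is configurable through
  `growth_basis()`.
* **Roughness penalty.** The second differences of $\beta$ carry a
  Gaussian prior with SD $\tau$; $\tau$ itself gets a half-Cauchy prior
  (scale 1) and is estimated, so the data decide how nonlinear the curve
  is. As $\tau \to 0$ the curve degenerates to a straight line — the two
  directions the penalty cannot see (overall level and slope) are made
  proper by a diffuse $N(0, 10^2)$ prior on the coefficients, essentially
  flat for Fisher-z values, which are of magnitude 0.3 or less here.
* **Repeated measures.** Subject random intercepts $a_i$ and slopes $b_i$
  (independent, SDs with half-Cauchy priors of scale 1 and 0.25 — per-week
  slopes on the Fisher-z scale are small). Slopes are centred at
  $t_0 = 37$ weeks, the mid-range of the data, to decorrelate them from
  the intercepts. A correlation between $a_i$ and $b_i$ is deliberately
  not modelled; with at most three scans per subject it is unidentifiable
  in practice.
* **Cohorts.** Each cohort has an additive offset $\delta_c$ (Gaussian
  prior, SD 1) and its own residual SD. The reference cohort's offset is
  fixed at zero; by default the reference is the cohort spanning the
  widest age range (the longitudinal fetal–neonatal cohort), since it is
  the only one anchoring the whole curve, and the fitted mean curve is
  therefore that cohort's trajectory. A sum-to-zero constraint would just
  shift the curve by a constant.
* **Covariate extension.** An optional subject-level covariate (the
  maternal mental-health composite) enters linearly after
  standardization; scans of subjects without covariate data are excluded
  from that fit and counted.

### Sampling and inference

All full conditionals are conjugate once half-Cauchy priors are written as
inverse-gamma scale mixtures, so the model is fitted by Gibbs sampling.
Two implementation details matter:

* the spline coefficients, cohort offsets and covariate slope are updated
  *jointly* in one Gaussian block — updated separately, the curve level
  random-walks against the offsets and mixing collapses;
* rows and subjects are internally reordered by their data content before
  sampling, which makes every posterior summary exactly invariant to
  subject relabelling and row permutations at a fixed seed.

Split R-hat and a Geyer effective-sample-size estimate are computed for
every stored scalar, and a fit warns (class
`fcg_convergence_warning`) when any R-hat exceeds 1.01 or any ESS falls
below 400 rather than failing silently. The variance components
$\sigma_a, \sigma_b$ mix the slowest (a funnel that is intrinsic to
Gibbs updates of hierarchical scales); the curve estimands, which are what
the analysis reports, typically reach ESS in the hundreds-to-thousands at
the default 4 × (2000 + 2000) layout.

Estimands follow the anchored reporting convention: the curve at 32, 36,
40 and 44 weeks, consecutive changes, and the overall 32→44 change, each
with posterior mean, empirical 2.5/97.5 percentiles (R's type-7
linear-interpolation quantiles), and the probability of a sign error —
the fraction of draws strictly opposite in sign to the posterior mean.
Draws exactly at zero count toward neither side, and a posterior mean of
exactly zero maps to 0.5 by convention. Significance is declared when the
sign-error probability is strictly below 0.025. No multiplicity
correction is applied across measures.

Comparing two measures (`compare_measures()`) refits the full model to
per-scan differences rather than differencing two fitted curves, so the
within-scan correlation of the two measures is respected. The degenerate
self-comparison (a measure minus itself) leaves the model without response
variation and is rejected.

## The connectivity pipeline

`compute_measure_table()` turns multi-run node time series into the six
measures. Conventions, in pipeline order:

* **Run exclusion** removes runs with mean frame-to-frame displacement
  strictly greater than 0.2 mm; a run at exactly 0.2 is kept.
* **Frame censoring** keeps a frame iff SNR and registration quality are
  within 1 SD below, and motion within 1 SD above, the means pooled over
  all the subject's retained runs. Comparisons are non-strict, so constant
  metrics censor nothing. Censoring is applied once: because the pooled SD
  shrinks after removal, re-censoring the retained frames would censor
  more, so the rule is defined as a single pass.
* **Confound regression** (intercept, linear and quadratic drift by
  default; any full-rank confound matrix is accepted) and **temporal
  smoothing** with a unit-sum Gaussian kernel whose width is solved
  numerically so the *discrete* kernel's transfer function equals 0.5 at
  the cutoff (0.12 Hz) — "cutoff" is taken as the half-amplitude
  frequency. Edges are handled by reflection.
* **Correlation** over frames concatenated across retained runs
  (per-run correlation with z-averaging is available as an option; which
  of the two a given study used is often unstated, and for i.i.d. frames
  they estimate the same quantity). Scans retaining fewer than 100 frames
  are omitted — a permissive floor chosen for synthetic tests; observed
  studies retain several hundred.

Voxel-to-node reduction is a plain region mean (`seed_timecourse`).
Image-space processing — motion correction, registration, template
warping, masking — is out of scope; the pipeline's contract starts at
node-level series with scalar QC metrics, and frame-to-frame displacement
is consumed as a precomputed per-run scalar.

## The synthetic-data generator

The generator exists so every stage is testable without restricted data,
and its defaults are the emulated study's conditions: cohorts of 29
(three visits at 31.2 ± 0.7, 35.3 ± 0.8, 43.4 ± 1.3 weeks), 31 (44.4 ±
1.3) and 24 (40.2 ± 2.1), visit ages truncated to [28, 48] weeks by
resampling. True mean curves interpolate anchor values with a
shape-preserving monotone cubic (constant beyond the anchor span), so
synthetic truths are smooth without invented wiggles; the bundled
reference anchor estimates for the six measures make convenient presets.
Noise scales are not stated by any source and were fixed once at values a
connectivity researcher would call realistic for Fisher-z network
strengths: subject intercept SD 0.05, slope SD 0.01/week, cohort offsets
0 / +0.02 / −0.02, residual SDs 0.10 / 0.08 / 0.08 (the fitted residual
SDs on such data come back near 0.1, matching the credible-interval
widths real tables show).

Time-series generation inverts the summary direction: the six strengths
at a scan's age define a block-patterned node correlation target
(projected to the nearest positive semi-definite correlation matrix), and
frames are drawn i.i.d. multivariate normal. That reproduces the
estimation noise of finite scans but deliberately not autocorrelation,
physiological artefacts or scanner drift — so passing recovery tests
demonstrates correctness of the estimators, not robustness to real fMRI
artefacts. QC metrics are scalar draws with planted outliers; planted
outliers are extreme by construction so the 1-SD rule must catch them.

The mental-health generator is a one-factor model over EPDS, PSS and
STAI state/trait, rescaled to the emulated cohort's instrument means and
SDs, clamped into legal ranges and rounded. The factor strength is
calibrated deterministically — numerical integration over the latent
factor with closed-form clamped-normal moments — so the large-sample PC1
variance-explained of the scaled data hits the requested target (default
0.73) despite the attenuation clamping causes; rounding attenuation
(~10⁻³) is ignored. Equal loadings are an assumption: no source states
the full inter-instrument correlation structure, only PC1's share.

## Numerical and design choices

* Ages up to 4 weeks outside the knot span are clamped to the boundary
  (constant extrapolation) rather than rejected: the emulated neonatal
  visit schedule itself produces scans past 44 weeks, and with replicated
  boundary knots the clamped value is the natural limit of the basis.
* All generators take an explicit integer seed and restore the caller's
  RNG state; chain and replicate seeds are derived from the master seed
  below 2³¹.
* `sigma` / `tau` can be fixed (`fix =`) to produce degenerate conjugate
  models whose posteriors have closed forms — used to validate the
  sampler against a generalized-ridge oracle.
* PCA for the composite uses the correlation matrix (scaling + centering),
  with the loading sign fixed so the loading sum is positive; listwise
  deletion with an explicit report, no imputation.

## Problem sizes in the tests

The shipped tests run replicate studies at the full 84-subject design but
with short chains (2 × (500 + 750) draws) — enough for anchor estimands,
whose Monte Carlo error is a few thousandths of a Fisher-z unit, while
keeping the whole suite under a minute of sampling; the convergence
warning those short chains trigger for the variance components is
expected and suppressed explicitly in tests. Production analyses should
use the defaults (4 × (2000 + 2000)), which take a few seconds per
measure on one core.

## Known limitations

* Correlated random intercepts and slopes are not modelled.
* The Gibbs variance components mix slowly (honestly flagged via the
  convergence warning); a gradient-based sampler would do better on
  $\sigma_a, \sigma_b$ but adds heavy dependencies for no change in the
  reported estimands.
* The generator's multivariate-normal frames understate real fMRI noise
  complexity (see above).
* Between 35 and 43 weeks the reference cohort has no scans, so the curve
  there is informed by the other cohorts *through* their offsets plus the
  smoothness penalty; anchor-40 estimates consequently carry the widest
  intervals, exactly as the interval widths in published anchored tables
  suggest.
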