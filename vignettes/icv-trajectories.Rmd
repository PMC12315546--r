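---
title: "Robust Laplace aging trajectories and ICV normalization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust Laplace aging trajectories and ICV normalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icvnorm)
```

## The problem

Brain ROI volumes scale strongly with head size. Because mean intracranial
volume (ICV) differs between sexes by roughly 12% in every racial group —
and between racial groups by a few percent within each sex — raw ROI
comparisons across demographic groups largely re-measure head size.
`icvnorm` provides the machinery to quantify this: normative aging
trajectories per group, fitted robustly, before and after four ICV
correction schemes, summarised by pooled-scale effect sizes.

Since clinical cohorts of this kind cannot be redistributed, the package
ships a synthetic cohort generator whose demographic and ICV structure is
calibrated to the published group table of a reference cohort (N = 5977
adults, 18–90 years, three racial groups by two sexes); every stage of the
pipeline is exercised and tested against it.

## The trajectory model

For one ROI in one group, volumes are modelled as Laplace-distributed with
age-varying location and scale:

$$\mathcal{L}(\theta_\mu, \theta_b) = \sum_{n=1}^{N}
  \log p\!\left[v_n;\, \mu(a_n, \theta_\mu),\, b(a_n, \theta_b)\right],
\qquad p(x; \mu, b) = \frac{1}{2b} e^{-|x-\mu|/b}.$$

Both curves are B-splines with four control points anchored at ages 27,
45, 63 and 81. The Laplace location is the conditional *median*, so the
fitted trajectory resists segmentation failures and mislabeled pathology;
the scale $b(a)$ is the conditional mean absolute deviation, and the band
$\mu(a) \pm 3\,b(a)$ covers $1 - e^{-3} \approx 95.0\%$ of the population
(the exact 95% multiple is $-\log 0.05 = 2.9957$ — "3" is accurate to half
a percent). This band describes population spread, not the standard error
of the curve; no curve-level uncertainty is computed.

### Basis construction

The model is stated with four control points at equally spaced anchor
ages. With exactly four cubic basis functions, the only clamped knot
vector whose basis is a nonnegative partition of unity over the full
18–90 domain places all knots at the domain ends, making the curve a
single cubic segment. We adopt that construction and treat 27/45/63/81 as
*anchor ages*: generator trajectories are specified by their values at
those ages and converted to coefficients through the (invertible) 4×4
collocation system, so simulated truths always lie inside the fitted
family. The degree is configurable; degree 0 with one control point
reduces the model to a constant location/scale, whose maximum-likelihood
solution is the sample median and the mean absolute deviation about it —
used as a closed-form check of the optimizer.

### Positivity, smoothing and optimization

- **Scale positivity.** $\theta_b$ parameterizes the spline of $\log b$,
  so the scale is positive for any coefficient vector.
- **Smoothed objective.** $|x|$ is smoothed to $\sqrt{x^2+\varepsilon^2}$
  during optimization so plain gradient ascent is valid; the final
  log-likelihood is reported unsmoothed. The target width is
  $\varepsilon = 10^{-6}$ of the volume scale. Because the smoothed
  objective becomes stiff near interpolated points as
  $\varepsilon \to 0$, the ascent anneals $\varepsilon$ over decades from
  $10^{-2}$ down to the target, warm-starting each stage; the objective
  trace is monotone nondecreasing across all accepted steps *and* stage
  boundaries (shrinking $\varepsilon$ can only raise the objective at
  fixed parameters).
- **Ascent.** Plain gradient ascent with Armijo backtracking line search
  on the mean log-likelihood of an internally standardized problem
  (volumes centred at the median and scaled by the MAD; coefficients are
  mapped back exactly, so fits are affine-equivariant by construction and
  unit-free in their tolerances). Initialization is deterministic: an L2
  spline fit for the location, a constant log-scale at the mean absolute
  L2 residual. Stopping: gradient sup-norm $\le 10^{-6}$, or relative
  objective change $\le 10^{-8}$ sustained over five consecutive accepted
  steps (a single short zigzag step must not stop the ascent); maximum
  5000 iterations, after which the fit is returned flagged
  `converged = FALSE` with a warning, never silently.

## Effect sizes

Between two fitted groups, at any age,

$$d(a) = \frac{2\,\lvert \mu_1(a) - \mu_2(a)\rvert}{b_1(a) + b_2(a)},$$

the absolute median difference over the pooled (average) scales. `d_max`
maximizes $d$ over a 1-year age grid on 18–90 (the grid the package uses
throughout; a 10× finer grid changes `d_max` only at grid-resolution
order) and over group pairs — by default sexes within race and races
within sex, matching the usual figure panels. The correction factor
reported for a normalization is $d_{\max}^{\text{raw}} /
d_{\max}^{\text{corrected}}$ per pair; when both are zero the factor is 1,
and a zero corrected maximum with a nonzero raw one is flagged infinite
rather than raised as an error.

## ICV correction schemes

- **Division** (primary): $v' = (v / \mathrm{ICV}) \times
  \overline{\mathrm{ICV}}$, with the unweighted grand mean over the
  analysis cohort — a group-stratified mean would reintroduce group
  offsets by construction. Division preserves units and approximately
  preserves the mean volume (exactly only under independence of $v/ICV$
  and $ICV$; tested as approximate). A second application is the
  identity.
- **Residual**: $v' = v - \hat\beta(\mathrm{ICV} -
  \overline{\mathrm{ICV}})$ with $\hat\beta$ the least-absolute-deviation
  slope on a reference subset. The L1 slope (rather than least squares)
  keeps the correction coherent with the Laplace model; it is computed by
  convex line search over the slope with the median as profiled
  intercept, and tested against a brute-force grid.
- **Covariate**: a token routes ICV into the fit itself as a linear
  location term with one coefficient shared across ages — head size as a
  nuisance variable rather than a pre-correction.
- **Matching**: greedy 1:1 nearest-neighbour matching without
  replacement on ICV within a caliper, deterministic (first group
  processed in subject-id order). Volumes are never altered; the output
  is a subset plus a balance report (standardized mean ICV difference).
  On a scalar, rank-wise pairing of sorted values is the optimal
  assignment, which serves as the test oracle.

**Ventricles** are modelled on the log scale, since their cross-sectional
distribution at any age is strongly right-skewed. Order of operations:
division correction is applied to raw volumes first, then the
log-transform, because the model is fit to the corrected volume; a
log-first order can be obtained by composing the exported functions in
the other order for sensitivity analysis.

## QC aggregation

Scans with QC score strictly above 0.75 are analysed; if a session has
more than three passing scans, the three with the highest scores are kept
(ties at the cut broken by scan id for determinism — the rule is applied
per session, as it is stated in the context of a single MRI session).
Volumes are averaged over a visit's retained scans, then volumes and ages
are averaged over visits with *equal weight per visit*, making the
estimate independent of the number of visits and of each visit's scan
count; a pooled-scans alternative is available behind a flag. A visit
whose scans all fail contributes nothing; a subject with no passing scan
in any visit is excluded and logged, never silently dropped.

## The synthetic cohort

The generator emulates exactly the structure the analysis assumes:

- **Demographics.** Per race-by-sex cell, subject counts, age mean/SD and
  ICV mean/SD default to the published group table; ICV is drawn normal
  (truncated at zero — a formality at these parameters, roughly 13 SDs
  from the boundary) and age truncated-normal on 18–90. Only the ICV
  statistics are calibrated targets; per-ROI group medians are not
  published, so the eight default ROI trajectories (whole brain, white
  matter, cortex, thalamus, hippocampus, amygdala, brainstem, ventricles)
  are plausible adult aging shapes expressed as fractions of ICV at the
  anchor ages, with Laplace residual scales of 3.5–6.5% of the median
  (30% on the log scale for ventricles, giving the right skew).
- **Structure.** 1–3 visits per subject, 0.5–2 years apart; 1–4 scans
  per session; small multiplicative Gaussian scan jitter (SD 0.2%),
  deliberately small next to between-subject spread. The subject-level
  Laplace deviate is shared across that subject's scans, so the
  cross-sectional law at any age is exactly Laplace.
- **QC scores.** Beta(8, 1.5) for analysis subjects (about 20% of
  individual scans fall below 0.75, exercising the filter); the first
  scan of each analysis subject is drawn from the same Beta truncated
  above 0.75 so that every intended analysis subject survives
  aggregation. On top of the requested group sizes, a fraction 23/5977
  of extra subjects is planted whose scans all score below the threshold,
  so the default aggregated cohort reproduces both the published cell
  counts and the published exclusion count (23 of 6000).
- **Guards.** Volumes are clamped to (0, 0.99 × ICV); at the default
  residual scales the clamp binds with negligible probability.

What passing tests on this cohort do *not* show: robustness to spatially
correlated segmentation failure, scanner/protocol batch effects, non-random
visit timing, or misspecified trajectory shapes. A piecewise-linear truth
can be emulated by passing degree-1 anchors to the generator while fitting
cubic, but no claim about real-data misspecification is made.

## Problem sizes and numerical choices

The test suite and the acceptance script run the calibration checks at
the sizes where their statistical guarantees are sharp but cheap: 10⁵
draws for distributional facts (Laplace MAD, band coverage), n = 4000
observations for parameter recovery (fitted location within 2% and scale
within 10% of truth at ages 30/50/70), n = 2000 per group for the
ICV-correction effect-size experiment, and reduced cohorts (80–500 per
group) for pipeline smoke and determinism checks. The closed-form
degree-0 equivalence is checked at odd n, where the L1 location optimum
is a unique order statistic; at even n any point between the two middle
order statistics minimizes the L1 loss and "the" sample median is a
convention, not an optimum.

Degenerate inputs are defined, not rejected: zero group SDs collapse the
corresponding draws to their mean; zero residual scale gives exactly
ICV-proportional volumes; an empty QC-filter result, an empty matched
set (warning) and missing ratio cells (NA, never zero) are all legal.

## Known limitations

- The residual/covariate/matching schemes follow their standard forms
  (reference group = whole cohort, 1:1 matching); published details of
  the supplementary comparison they mirror are not reproduced here.
- The ±3b band is a population spread band; no bootstrap or asymptotic
  uncertainty for the fitted curves is provided.
- Race labels are treated as closed categorical inputs; nothing in the
  package addresses their provenance or measurement quality.
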