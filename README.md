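# coxradius

Radial image-based data mining for radiotherapy outcomes: map where around
a lung tumour CT **density** and delivered **dose** interact to predict
distant failure, with no prior assumption on location.

## The problem and the method

After lung SABR, distant metastasis is thought to be seeded by microscopic
disease just outside the visible tumour (GTV) that received only
incidental dose. Whether low incidental dose raises risk should depend on
whether such disease is present — and pretreatment CT density in the
tumour and peritumour carries information about that. Both the informative
radial location for density and the relevant radial location for dose are
unknown a priori.

`coxradius` quantifies both signals in 1-mm annuli around the GTV using a
signed Euclidean distance transform on the anisotropic CT grid:

* density (from the most motion-stable 4D-CT phase, chosen by SSIM of
  radial cross-histograms): per-annulus mean, SD and 90th percentile over
  −0.5…2 cm (25 annuli);
* dose (motion-blurred, converted to EQD2 with α/β = 10): per-annulus SD,
  generalised mean `(Σ vᵢ Dᵢᵃ)^{1/a}` with a = −3, and fraction of volume
  below 30 Gy, over 0.5…4 cm (35 annuli).

For every pair of annuli (i, j) and each of the nine metric combinations,
two Cox proportional-hazards models are fitted:

```
ln h(t) = ln h₀(t) + b₁·Dose_j + b₂·Density_i + b₃·(Density_i × Dose_j) + Σ bₖ·clinical_k
```

with and without the interaction term. The likelihood-ratio p-value of b₃
fills cell (i, j) of a 25 × 35 significance heatmap (875 cells per map,
nine maps). Maps are post-processed into candidate rectangular regions
(8-connected components → 3-mm thin-row pruning → box averaging → size and
near-zero-variance screens), and each surviving region is evaluated with
500 bootstrap resamples: LR-significance frequency, C-index on the
original cohort, and same-sign-CI stability of b₃, against a clinical
baseline model.

Because no clinical imaging can ship with the package, a first-class
synthetic-cohort generator produces phased CT-like volumes, SABR-like dose
fields (uniform core, sigmoidal penumbra, incidental tail, cold sectors),
masks, motion, clinical tables and survival outcomes whose log hazard
contains a planted interaction between *pipeline-extracted* statistics —
so recovery tests exercise the entire chain.

## Worked example

```r
library(coxradius)

# a 150-patient synthetic cohort with a planted interaction:
# mean density at 0 cm x dose SD at 2 cm (reduced windows keep this quick)
cfg <- cohort_config(
  n_patients = 150, dims = c(40L, 40L, 30L), spacing = c(1, 1, 3),
  volume_range_cc = c(0.3, 3), n_phases = 1,
  density_window = c(-0.5, 0.5), dose_window = c(1.5, 2.5),
  planted = list(density_stat = "mean", density_cm = 0.05,
                 dose_stat = "dose_sd", dose_cm = 2.05,
                 b1 = 0.24, b2 = 0.19, b3 = 0.9))
cohort <- simulate_cohort(cfg, seed = 42)
print(cohort)

res <- suppressWarnings(run_pipeline(
  cohort, run_config(n_bootstrap = 200, min_events = 5, seed = 42)))
print(res)

m <- res$maps[["mean.x.dose_sd"]]
ij <- which(m$p_values == min(m$p_values, na.rm = TRUE), arr.ind = TRUE)[1, ]
cat(sprintf("min p = %.2g at density %.2f cm, dose %.2f cm (planted: 0.05, 2.05)\n",
            min(m$p_values, na.rm = TRUE),
            m$density_distances[ij[1]], m$dose_distances[ij[2]]))
print(res$accepted[[1]])
```

Output (verbatim):

```
synthetic_cohort: 150 patients, 22 events (15%), seed 42
pipeline_result: baseline C = 0.641; 9 maps; 2 evaluated regions; 2 accepted
min p = 0.0016 at density 0.05 cm, dose 2.05 cm (planted: 0.05, 2.05)
region_model (mean x dose_sd): status accepted, n = 150
bootstrap_summary: 200 resamples; C-index 0.758 (0.695-0.790); LR sig 84%; b3 CI [0.002, 0.011] (stable)
```

Reading it: the cohort hit a 15% event rate (target 17%); the clinical
baseline model alone reaches C = 0.641; the interaction map for
(mean density × dose SD) attains its minimum p-value exactly at the
planted pair of radial locations; the extracted region survives all
screens, the interaction is significant in 84% of bootstrap resamples, its
coefficient is stable (95% CI strictly positive, matching the planted
sign), and the interaction model improves the C-index over the baseline —
so the region is accepted.

`run_pipeline(..., out_dir = "out/")` additionally writes the nine map
CSVs with distance headers (plus JSON sidecars), the regions and region
models as JSON, the resolved configuration, and a per-stage timing log.
A minimal CLI wrapper lives at `inst/cli/coxradius`
(`coxradius simulate|run --n N --seed S --out DIR`).

## Package layout

| Area | Files |
| --- | --- |
| Geometry (EDT, annuli) | `R/radial_geometry.R`, `src/edt.cpp` |
| Radial histograms | `R/radial_histograms.R` |
| Phase selection (SSIM) | `R/phase_selection.R` |
| Dose model (blur, EQD2, metrics) | `R/dose_model.R` |
| Summary curves, smoothing | `R/summary_curves.R` |
| Cox-per-radius maps | `R/cox_per_radius.R` |
| Map post-processing | `R/region_postprocess.R` |
| Region evaluation, bootstrap | `R/model_evaluation.R` |
| Contrast curves, confounding | `R/interpretation.R` |
| Synthetic cohorts | `R/synthetic_data.R` |
| Orchestration, I/O | `R/cli_io.R`, `inst/cli/coxradius` |

Methodological background, parameter defaults with their rationale, the
synthetic world's assumptions, and known limitations are documented in
`vignettes/cox-per-radius.Rmd`.
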