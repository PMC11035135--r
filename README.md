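# aqpquant

Quantification pipeline for aquaporin-based diffusion-MRI reporter studies.

Aquaporin-1 (Aqp1) is a membrane water channel used as a genetically encoded
MRI reporter: its expression raises cellular water diffusivity, so
reporter-expressing cells stand out in diffusion-weighted images.
Establishing such a reporter — and showing it is safe — rests on a chain of
quantitative analyses, each of which this package implements as tested,
reusable R functions:

* **Diffusion MRI** — apparent diffusion coefficient (ADC) estimation from
  the mono-exponential decay `S(b) = S0·exp(−b·D)` over multi-b-value
  magnitude series (log-linear, nonlinear, and Rician forward-model fits,
  with noise-floor handling and background noise estimation); voxel-wise
  diffusion maps with median-filtered 8-bit rendering; the reporter
  contrast statistic `ΔD/D0 = 100·(D − D0)/D0`.
* **QPI morphometry** — dry mass from refractive-index tomograms via
  optical path length, `m = ∬OPL dx dy / α` with `α = 0.18 µm³/pg`; volume,
  iso-surface-mesh surface area, and sphericity
  `Ψ = π^(1/3)(6V)^(2/3)/S`.
* **qRT-PCR** — relative expression by `2^(−ΔΔCt)` with housekeeping
  normalization, primer efficiency from dilution-series slopes, and
  Student's t-tests on per-sample ΔCt values.
* **Assay formulas** — T-cell stimulation %, phagocytic index, Matrigel
  invasion area (fraction × 113.5 mm²), viability-normalized caspase fold
  changes, and quadratic ELISA standard-curve inversion for insulin
  secretion.
* **Synthetic data** — seeded generators for every input (Rician-noise
  pellet phantoms, ellipsoidal-cell tomograms, Ct tables, assay fixtures),
  each carrying its ground truth, so the whole pipeline is verifiable by
  parameter recovery.

## Worked example

```r
library(aqpquant)

# a two-compartment cell-pellet phantom at the study acquisition settings:
# control cells D0 = 1.0, reporter cells D = 1.794 um^2/ms, four b-values
# in 1-3 ms/um^2, 5 averages, Rician noise at SNR 50
spec <- pellet_phantom_spec(
  compartments = list(
    list(center = c(20, 32), radius = 12, D = 1.0,   S0 = 1000),
    list(center = c(46, 32), radius = 12, D = 1.794, S0 = 1000)),
  snr = 50, averages = 5, noise = "rician", seed = 20260101)
ph <- make_pellet_phantom(spec)

sigma <- estimate_noise_sigma(ph$series, ph$truth$label == 0)
fit <- function(lab) fit_adc(roi_mean_signal(ph$series, ph$truth$label == lab),
                             method = "rician", sigma = sigma)$D
percent_delta_diffusivity(fit(2), fit(1))
#> [1] 79.56674
```

The recovered contrast, 79.6%, matches the planted 79.4% increase (the
scale measured in hippocampal HT22 cells) to 0.2 percentage points; the
Rician forward-model fit is what keeps the high-b points — which sit near
the magnitude noise floor — from biasing the estimate.

The numbered scripts under `analysis/` run each assay family end to end and
write their tables under `results/`:

```sh
Rscript analysis/01_dwi_adc.R          # ADC recovery + contrast + map PNG
Rscript analysis/02_qpi_morphometry.R  # dry mass / volume / sphericity + folds
Rscript analysis/03_qpcr_expression.R  # ddCt fold changes, efficiency QC
Rscript analysis/04_assay_panel.R      # stimulation/invasion/phago/caspase/insulin
Rscript analysis/05_full_report.R      # orchestrated run + determinism audit
```

`vignettes/methods.Rmd` documents the models, estimators, parameter
defaults, numerical choices, and limitations.

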