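---
title: "Methods: quantifying an aquaporin diffusion-MRI reporter and its safety panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying an aquaporin diffusion-MRI reporter and its safety panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aqpquant)
```

# The scientific problem

Aquaporin-1 (Aqp1) is a passive water channel. Expressed as a transgene it
accelerates water exchange across the cell membrane, raising the cell's
apparent water diffusivity, which diffusion-weighted MRI measures directly.
That makes Aqp1 a genetically encoded MRI reporter: cells expressing it
light up in diffusion maps without any exogenous contrast agent. Deciding
whether such a reporter is *safe* requires a battery of quantitative
analyses — reporter contrast from multi-b-value MRI, cell morphometry from
refractive-index tomograms, ER-stress gene panels by qRT-PCR, and a set of
per-assay formulas for immune activation, phagocytosis, invasion, viability
and secretion. This package implements each of those computations together
with seeded synthetic-data generators so that every estimator can be
validated by recovering planted ground truth.

Nothing in the package depends on proprietary acquisitions: all inputs are
either standard files (NIfTI, TIFF, CSV) or phantoms produced by the
generators.

# Diffusion MRI

## Signal model and estimators

A pulsed-gradient (here stimulated-echo, diffusion time $\Delta = 300$ ms)
acquisition at effective b-value $b$ measures magnitude signal

$$S(b) = S_0 \, e^{-b D},$$

with $b$ in ms/µm² and the apparent diffusion coefficient $D$ in µm²/ms, so
$bD$ is dimensionless. `effective_bvalue()` evaluates the standard
Stejskal–Tanner expression $b = \gamma^2 G^2 \delta^2 (\Delta - \delta/3)$.
The acquisition emulated by the pellet phantom uses four b-values in the
1–3 ms/µm² range, 5 averages, and a 128×128-style axial slice; because only
the range of the four b-values is prescribed by the protocol, the default
schedule $\{1.0, 1.67, 2.33, 3.0\}$ is an even spacing of that range and is
configurable.

`fit_adc()` offers three estimators:

* `"ols"` (default): ordinary least squares of $\ln S$ on $b$; $D$ is minus
  the slope. This is the "slope of the logarithmic decay" estimator and is
  exact on noiseless data for any two or more distinct b-values.
* `"nls"`: Levenberg–Marquardt fit of $S_0 e^{-bD}$ in signal space,
  initialized from the log fit. On clean data the two agree to machine
  precision; they differ only in error weighting under noise.
* `"rician"`: a forward-model fit described next.

## Rician noise and the noise floor

Magnitude MRI noise is Rician: the measured value is the magnitude of the
true signal plus complex Gaussian noise with per-channel sd $\sigma$. Its
mean is

$$E[M] = \sigma\sqrt{\pi/2}\; L_{1/2}\!\left(-\frac{A^2}{2\sigma^2}\right),$$

which approaches $\sqrt{A^2 + \sigma^2}$ at high SNR but flattens to the
Rayleigh floor $\sigma\sqrt{\pi/2}$ as the underlying amplitude $A \to 0$
(`rician_mean()`). At the emulated conditions (SNR $S_0/\sigma = 50$, b up
to 3 ms/µm²) a strongly diffusion-enhanced compartment with
$D \approx 1.8$ µm²/ms has $S(3) \approx 0.0046\,S_0$ — a quarter of the
noise floor. A log-linear fit of the raw decay then underestimates $D$ by
~10%, which is not an implementation artifact but a property of magnitude
statistics. The package therefore provides:

* `estimate_noise_sigma()`: $\hat\sigma$ from signal-free background voxels
  (Rayleigh mean $= \sigma\sqrt{\pi/2}$; arithmetic averaging of repeated
  acquisitions leaves that mean unchanged).
* `fit_adc(..., method = "rician", sigma)`: least squares of the observed
  ROI decay against $E[M]\left(S_0 e^{-bD}; \sigma\right)$. On the phantom
  conditions this recovers ROI $D$ to well under 2% even where the highest-b
  point is below the floor.
* `fit_adc_map(..., sigma, method)`: voxel-wise maps, either log-linear
  after inverting the Rician mean per voxel (`"ols"`; voxels clipped at the
  floor become invalid rather than erroring) or the per-voxel forward-model
  fit (`"rician"`), which stays essentially unbiased in the strongly
  enhanced regime at the cost of a nonlinear fit per voxel.

The contrast statistic is `percent_delta_diffusivity()`,
$100\,(D - D_0)/D_0$, with `delta_diffusivity_summary()` aggregating
biological replicates as mean ± s.e.m. (sample sd, $n-1$ denominator).

## Rendering

`render_diffusion_map()` reproduces the display convention for absolute
diffusivity maps: an NA-aware median filter (default 3×3; invalid voxels
are excluded from each neighborhood and stay invalid) followed by a linear
map of $[\mathrm{lower}, \mathrm{upper}]$ µm²/ms onto 0–255 with clamping.
Rendering is invariant under joint affine rescaling of the map and the
scale limits.

## What the pellet phantom does and does not emulate

`make_pellet_phantom()` renders disk compartments of uniform true $D$,
applies seeded Rician (or Gaussian, for analytic tests) noise independently
per acquisition, and averages magnitudes — the semantics of a scanner's
"number of averages". It does not simulate k-space, eddy currents, partial
volume, or motion, so recovery tests validate the estimators, not the
acquisition chain. SNR defaults to 50 (the recovery-test condition; the
protocol itself does not state per-pellet SNR).

# QPI morphometry

## Dry mass

A refractive-index tomogram $n(x,y,z)$ with surrounding-medium index
$n_{surr}$ yields the optical path length by integrating along the optical
axis,

$$\mathrm{OPL}(x,y) = \int_0^h \left[n(x,y,z) - n_{surr}\right] dz,$$

and dry mass via the specific refractive increment
$\alpha = 0.18\ \text{µm}^3/\text{pg}$ (the standard value for eukaryotic
cells):

$$m = \frac{\iint \mathrm{OPL}\, dx\, dy}{\alpha}.$$

`project_opl()` restricts the integral to one labeled cell so neighbors
cannot leak into a column; `dry_mass()` discretizes the outer integral as
sum × pixel area. Mass is linear in index contrast and in thickness, which
the tests exercise directly. Default voxel dimensions are the tomographic
resolution 0.202 × 0.202 × 0.363 µm; anisotropy is honored everywhere.

## Volume, surface area, sphericity

Volume is voxel count × voxel volume. Surface area is measured on a
triangulated iso-surface: the binary label indicator is padded, smoothed
with a separable Gaussian (default $\sigma = 1$ voxel), and meshed at the
0.5 level by marching tetrahedra (six tetrahedra per grid cube, triangle
vertices by linear interpolation along crossing edges). Counting exposed
voxel faces instead would overestimate the area of any smooth surface by a
direction-dependent factor (up to ~1.5) and bias sphericity low; the
smoothed mesh is accurate to ≲1% for a ball of radius 20 voxels and
converges as resolution increases. Sphericity is

$$\Psi = \frac{\pi^{1/3} (6V)^{2/3}}{S},$$

1 for a sphere (a cube gives $\pi^{1/3}6^{2/3}/6 \approx 0.806$), and may
exceed 1 by a small discretization tolerance on digitized balls.

The segmentation provided (`segment_cells()`: contrast thresholding,
26-connected components, minimum size, boundary-touching cells flagged
excluded) is intended for synthetic scenes and well-separated cells; real
data are expected to arrive with an externally produced label mask
(`cell_mask()`). The boundary-exclusion rule mirrors standard practice of
dropping cells clipped by the field of view; measuring an excluded cell
requires an explicit `allow_excluded = TRUE`.

Ground truth for ellipsoidal phantom cells uses the analytic volume
$\tfrac{4}{3}\pi abc$ and the Knud Thomsen surface-area approximation
($p = 1.6075$, max error ≈ 1.06%), which is accurate enough for the
tolerance-based tests it serves. Group ratios (`morphometry_fold()`) are
mean(case)/mean(control) with the standard error propagated from the two
group s.e.m.s; when several images are available, image means are treated
as the replicates (the nesting convention adopted here, since per-image
aggregation into s.e.m. is otherwise ambiguous).

# qRT-PCR

`relative_expression()` implements $2^{-\Delta\Delta C_t}$: technical
replicates are averaged within a sample, $\Delta C_t = \bar{C_t}(\text{target})
- \bar{C_t}(\text{housekeeping})$ per sample, $\Delta\Delta C_t$ is the
case-minus-control difference of group means, and the fold change is
$2^{-\Delta\Delta C_t}$ exactly. Averaging replicates before $\Delta C_t$
(rather than after) is a deliberate choice; s.e.m. is computed across
biological samples only. The per-sample $\Delta C_t$ values feed a
Student's t-test (pooled variance by default, Welch by flag); all tests are
two-sided except comparisons whose direction is known a priori — e.g.
drug-induced ER stress — where the one-sided option applies. Two fold-error
conventions are reported and labeled: the delta-method propagation
$f \ln 2 \cdot \mathrm{se}(\Delta\Delta C_t)$ and the s.e.m. of per-sample
folds. No multiple-testing correction is applied across a gene panel —
per-gene tests are reported as such, a documented caveat.

`primer_efficiency()` converts the OLS slope of $C_t$ vs
$\log_{10}(\text{dilution})$ to $(10^{-1/\text{slope}} - 1)\times 100$;
$-1/\log_{10} 2 = -3.3219$ cycles/decade is exactly 100%. A non-negative
slope is flagged invalid rather than silently converted.

The generator (`make_ct_table()`) plants fold changes by shifting the case
group's target $C_t$ by $-\log(f)/\log(1 + E/100)$ (i.e. $-\log_2 f$ at
100% efficiency), adds per-sample loading shifts common to target and
housekeeping (which $\Delta C_t$ must cancel — a tested invariant), and
Gaussian replicate noise. Defaults mirror the study design: 3 biological
samples per group, triplicate wells, 0.2-cycle noise.

# Assay formulas

* `stimulation_pct()`:
  $100\cdot\mathrm{CD3^+CD25^+} / (\mathrm{CD3^+CD25^+} + \mathrm{CD3^+CD25^-})$;
  CD3⁻ quadrants are ignored by construction, and the value is invariant to
  scaling all counts.
* `invasion_area()`: escaped-pixel fraction × total imaged area, default
  113.5 mm² (a 10 × 10 tiled confocal field); additive over disjoint
  regions and bounded by the imaged area.
* `phagocytic_index()`: background-subtracted bead-channel fluorescence
  summed over cell regions, divided by the number of cells. Background
  defaults to the median of non-cell pixels (the protocol says only that
  background was subtracted; the median is robust and configurable).
* `plate_fold()`: mean(case)/mean(control) of per-well readouts, with
  caspase-3/7 signals first divided per well by the viable-cell readout
  (ATP or MTT) so changes in cell number cancel — a tested invariant.
* `fit_standard_curve()` / `invert_standard_curve()`: quadratic ELISA
  calibration over the assay's dynamic range (0.1–12.8 ng/mL by default).
  The fitted quadratic must be strictly monotone over the calibrated
  concentration range; inversion selects the in-range root of the quadratic
  formula, refuses signals outside the calibrated signal range (no
  extrapolation), and treats two in-range roots as an error since they
  would contradict monotonicity. `insulin_secretion()` normalizes inverted
  concentrations to total cellular protein.

# Orchestration, I/O, determinism

`run_pipeline()` executes simulate → estimate → compare for the four assay
families from a single config (`default_config()`), with per-stage seeds
derived from the master seed; `write_report()` serializes stage tables as
CSV with fixed formatting plus a provenance JSON (seed, stages, config
hash, package version). Determinism is a tested contract: the same config
run twice yields byte-identical tables.

File formats: diffusion series and maps as NIfTI (double precision — the
round trip is bit-exact) with JSON sidecars whose keys carry units
(`bvalues_ms_per_um2`, `voxel_mm`); tomograms as multi-page TIFF storing
$n - 1$ in 32-bit samples (the TIFF container quantizes at ~2.3×10⁻¹⁰
refractive-index units, far below reconstruction noise; the NIfTI path is
the bit-exact option) with `voxel_um`/`n_surr` sidecars; Ct tables as wide
CSV (`ct_rep1..N` columns) converted to the long in-memory form.

# Numerical and design choices

* Rician noise is implemented as the magnitude of a complex Gaussian
  perturbation; a Gaussian option exists for analytic tests. Averages are
  combined by arithmetic means of magnitudes.
* All generator randomness comes from one seeded generator per call
  (`withr::with_seed`), leaving the caller's RNG state untouched.
* Non-positive intensities (possible under noise) invalidate a voxel in
  maps but are hard errors in scalar fits naming the offending b-value:
  maps must be robust, scalar fits explicit.
* No b≈0 reference image is assumed (the schedule starts at 1 ms/µm²); the
  fit intercept absorbs $S_0$.
* Median-filter default kernel 3 with NA-aware neighborhoods (the protocol
  states neither kernel nor boundary rule).
* Synthetic segmentation threshold defaults to half the nominal index
  contrast of the scene.
* Degenerate t-tests (zero within-group variance) return p = 1 for equal
  means rather than erroring, so noiseless regression fixtures remain
  usable.
* Problem sizes in tests and the analysis scripts (64–128 voxel grids,
  500–900-voxel ROIs, 2000-replicate Monte-Carlo nulls) were chosen as the
  smallest sizes at which the statistical claims are meaningful.

# Limitations

* Phantoms validate estimators, not acquisition physics: no k-space,
  partial-volume, motion, or diffraction effects are simulated, so passing
  recovery tests does not certify behavior on artifact-laden real data.
* The voxel-wise map of a strongly enhanced compartment (b·D ≈ 5 at the
  top of the schedule) is noise-floor limited even with correction; ROI
  fits are the quantitative readout there, maps are display.
* The Thomsen ellipsoid area oracle carries its own ≤1.06% error; surface
  tests use tolerances well above it.
* Real-data segmentation is out of scope: masks from dedicated tools are
  consumed as-is, and the built-in thresholding is for synthetic scenes.
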