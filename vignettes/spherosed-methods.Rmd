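---
title: "Spheroid biophysics from sedimentation velocimetry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spheroid biophysics from sedimentation velocimetry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spherosed)
```

# The measurement problem

Tumor spheroids — self-assembled, roughly spherical aggregates of cultured
cancer cells — are routinely characterized by 2D projections (area,
roundness), which say little about the quantity that most directly reflects
the compactness of the aggregate bulk: its mass density. `spherosed`
implements a fluidic alternative: a single spheroid is released into a
vertical channel filled with quiescent buffer, bright-field frames record
its free fall, and the terminal velocity it reaches — together with its
radius measured from the same frames — determines the mass density, mass
and buoyant weight of the aggregate. The package also implements the two
companion analyses such an experiment needs: a cohort statistics pipeline
for treated-vs-control comparisons, and a 3D nuclei quantification pipeline
for cleared-spheroid confocal stacks that provides the morphological
counterpart (nuclei count, spheroid volume, volumetric nuclear density,
bright-field optical density).

Because real device videos and raw confocal data are rarely shareable, the
package carries first-class synthetic generators for every input kind, each
returning its ground truth, so the whole chain is testable end-to-end.

# The physical model

A rigid sphere of radius $r$ and density $\rho_s$ settling in a fluid of
density $\rho_f$ and dynamic viscosity $\mu$ reaches, in the creeping-flow
(Stokes) regime, the terminal velocity

$$ v_\infty = \frac{2}{9}\,\frac{(\rho_s - \rho_f)\, g\, r^2}{\mu}, $$

the balance of net gravity $(\rho_s-\rho_f)Vg$ against Stokes drag
$6\pi\mu r v$. The density inversion used by `invert_density()` is the
exact algebraic inverse,

$$ \rho_s = \rho_f + \frac{9 \mu v_\infty}{2 g r^2 K}, $$

where $K \le 1$ is an optional wall-correction factor (below). From
$\rho_s$ and $r$ follow the mass $\rho_s \tfrac43 \pi r^3$ (reported in
µg) and the buoyant weight $(\rho_s-\rho_f)\tfrac43\pi r^3 g$ (reported in
nN). Cohort tables label the mass as "weight" in µg, the convention most
natural for a fixation-stable readout.

Model assumptions, and how they are policed:

* **Stokes regime.** The particle Reynolds number
  $Re = \rho_f |v| 2r/\mu$ must be small; Stokes drag degrades by roughly
  5% near $Re \approx 0.5$. Measurements above that threshold are flagged
  `stokes_regime_violated` rather than refused, since the bias is modest
  and the flag leaves the decision to the analyst.
* **Unbounded fluid vs a finite channel.** A sphere settling on the axis
  of a cylindrical tube is slowed by the wall. The package implements the
  standard on-axis polynomial correction
  $K(\lambda) = 1 - 2.104\lambda + 2.089\lambda^3 - 0.948\lambda^5$ with
  $\lambda = r/R$, clamped to $(0,1]$. The correction is **off by
  default**: the device's own calibration is not public, the synthetic
  loop is self-consistent either way, and turning it on rescales absolute
  densities by $1/K$. It is a config switch (`wall_correction`), and the
  forward and inverse maps always use matching flags.
* **Rigid sphere.** Spheroids of very irregular shape violate this; the
  radius estimator (median equivalent-circle radius across frames) is
  robust to moderate non-ideality but nothing in the package models
  non-spherical drag.
* **Operative range.** Diameters outside 50–500 µm get an
  `outside_operative_range` QC flag, mirroring the working range of the
  fluidic instrument this analysis style comes from.

The transient is modeled too: `settle_ode()` integrates
$m_{\rm eff}\,\dot v = (\rho_s-\rho_f)Vg - 6\pi\mu r v/K$ with
$m_{\rm eff}=\rho_s V$ (deSolve/lsoda, tolerances $10^{-12}$). Its steady
state is the closed form above — the two are mutually consistent to
better than $10^{-6}$ relative, which the test suite checks on a 5×5
parameter grid — and the generator uses it so synthetic videos contain a
physically correct start-up transient. The relaxation time
$\tau = \tfrac29 \rho_s r^2 K/\mu$ is milliseconds for typical spheroids,
which is why real cameras never see the transient but a fast synthetic
camera does.

Fluid defaults: the suspension buffer is modeled as water-like with
$\rho_f = 1005\ \mathrm{kg/m^3}$ at 25 °C (a DPBS-like value; override in
config when the buffer density is known) and viscosity from a Vogel-type
water curve $\mu(T) = A\,e^{B/(T_K - C)}$ anchored within 2% of
$1.002\times10^{-3}$ Pa·s at 20 °C. Gravity defaults to standard gravity
9.80665 m/s² and is overridable.

# Fall tracking

`detect_spheroid()` segments each frame with a global Otsu threshold
(honoring polarity: the spheroid is normally darker than the bright-field
background), keeps the largest connected component, and rejects detections
touching the frame border or smaller than 20 px. Image coordinates are
origin top-left, x right, y down; "falling" means increasing y; pixel
centers sit at integer coordinates and centroids are sub-pixel.

Two estimator choices matter for accuracy:

* **Centroid**: contrast-weighted (weight $\propto I_{bg} - I$ within a
  narrow ring around the mask), which is exactly the partial-coverage
  weighting of an anti-aliased disk edge; on synthetic disks it recovers
  centers to better than 0.05 px.
* **Radius**: the equivalent-circle radius $\sqrt{A/\pi}$, with $A$ the
  *coverage-weighted* area (sum of estimated per-pixel coverage rather
  than a hard pixel count). A hard mask count biases the radius by a
  sizeable fraction of a pixel depending on where the threshold cuts the
  anti-aliased edge; since the density inversion scales with $r^{-2}$ and
  the density *excess* $\rho_s-\rho_f$ is only a few percent of $\rho_s$,
  that bias would dominate the error budget. The per-spheroid radius is
  the median across valid frames, which suppresses single-frame failures.

`track_spheroid()` links detections by nearest-neighbor continuity (gate:
3× the running median frame-to-frame displacement), interpolates interior
gaps of at most 2 frames (flagged), and fails with a tracking error below
3 valid detections.

`fit_velocity()` finds the terminal plateau before fitting: the steady
window is the longest suffix of the track whose local 3-point slopes all
lie within a tolerance of the suffix median slope. The tolerance is
$\max(5\%\ \text{of the median slope},\ 3.5\,\hat\sigma_{\rm slope})$:
the 5% rule alone is exact for noiseless tracks but rejects most frames
once centroid noise enters (a 3-point slope of a 0.3 px-noisy track
fluctuates by several percent), so a noise floor is added, with
$\hat\sigma_{\rm slope}$ estimated robustly from second differences of
the positions (second differences annihilate any linear trend, isolating
measurement noise). In the noiseless limit the floor vanishes and the
rule reduces to the plain 5% criterion; on transient-resolving videos the
window provably starts after the first relaxation time, which the suite
asserts. Ordinary least squares of position against the (authoritative,
not assumed-uniform) timestamps over the window gives $v_\infty$, its
standard error, and $R^2$; $R^2 < 0.99$ earns a `poor_plateau` flag.

Repetitions of the same spheroid are averaged arithmetically
(`aggregate_repetitions()`), the velocity SE pooled as
$\sqrt{\sum se_i^2}/k$, QC flags unioned.

# Cohort statistics

The statistical pipeline reproduces a fixed normality-gated workflow over
long-format tables keyed by condition (`CTRL`, `CZB250`, `CZB500` — a
control and two doses of a kinase inhibitor), state (`live`, `fixed`) and
parameter (`density` g/cm³, `weight` µg, `diameter` µm):

1. **Shapiro–Wilk** per cell (`stats::shapiro.test`, Royston
   approximation; valid for $3 \le n \le 5000$).
2. If non-normal at $\alpha = 0.05$: one round of **Tukey-fence outlier
   removal** — quartiles by linear interpolation (R's default type-7
   convention, fixed and documented so the worked example
   `c(1,2,3,4,100)` with $Q_1=2$, $Q_3=4$, upper fence 7 is stable),
   fences at $Q_1 - k\,\mathrm{IQR}$ and $Q_3 + k\,\mathrm{IQR}$ with
   $k = 1.5$, values strictly outside removed. The whisker coefficient is
   the conventional reading of "K > 1.5"; with $\mathrm{IQR}=0$ nothing
   is ever removed.
3. **Shapiro–Wilk again** to confirm; `converged` records whether the
   final p reached $\alpha$. One removal round is the default
   (`max_iter = 1`): re-testing is iterated, removal is not.
4. **Student t-tests** (equal-variance, two-tailed, unpaired;
   $df = n_a + n_b - 2$) of each dose against control on the cleaned
   values; means ± SD reported. Equal-variance rather than Welch is
   deliberate, matching the workflow being reproduced. Zero pooled
   variance with equal means returns $p = 1$ by convention; with unequal
   means it is a `degenerate_variance` error.
5. **Pearson dose–response r** of the cleaned per-concentration cell
   means against (0, 250, 500) nM.
6. **Fixation one-way ANOVA**: per-(condition × state × parameter) cell
   means are z-scored within parameter (making g/cm³, µg and µm
   commensurable) and a classical one-way ANOVA with state as the single
   factor is applied to the standardized cell means. The grouping that
   produced the published F-ratio for this design is not recoverable from
   prose, so this layout is *declared*, fixed, and brute-force-verified;
   with three conditions and three parameters it has $df = (1, 16)$.

No multiple-testing correction is applied, matching the reproduced
workflow. `calibrate_standard_curve()` fits fluorescence on concentration
by OLS and `apply_curve()` inverts the line — the protein-quantification
companion step.

Outlier elimination is applied per (condition × state × parameter) cell,
not pooled: cells differ in mean by design, so pooling would flag
treatment effects as outliers.

# 3D nuclei quantification

The imaging pipeline mirrors a commercial GA3-style nuclei-counting recipe
with open, declared equivalents (the proprietary operators are not
published, so each step is mapped to a standard algorithm with the same
role and the same parameter names where the recipe printed them):

| Step | Implementation |
|---|---|
| Denoise | Gaussian, physical sigma converted per-axis to voxels |
| Z-alignment | per-slice FFT cross-correlation, DFT-upsampled sub-pixel peak, cumulative shifts, low-confidence pairs (normalized correlation < 0.3) get zero shift |
| Deconvolution (optional) | Richardson–Lucy, multiplicative updates, Gaussian PSF parameterized by NA 1.05 / DAPI emission (no measured PSF is available) |
| "Bright-spot detection 3D" | scale-matched Laplacian of Gaussian ($\sigma = r_{\rm nuc}/\sqrt3$), 26-connected local maxima above a threshold, greedy minimum separation 0.7 diameters |
| "GrowRegions" | seeded watershed: descending-intensity level flooding from the seeds, restricted to an Otsu foreground mask, so touching nuclei split at the intensity valley |
| "Smooth" (radius 0.332 µm) | per-label morphological opening then closing with a ball of that physical radius (per-axis voxel conversion, minimum 1 voxel); labels processed independently, so the count cannot rise |
| "SeparateObject, 2 counts" | 2 rounds of 6-neighborhood erosion per label; if the core splits, components re-grow within the original footprint as separate labels ("2 counts" is read as 2 erosion iterations — a declared interpretation) |
| "ObjectCount" | labels with volume ≥ 5 µm³ (a conservative debris floor) |

Numerical details worth knowing:

* The LoG detector thresholds at
  $\max(\texttt{threshold\_rel}\times\max \text{response},\ 6\times\mathrm{MAD})$.
  The relative part alone is scale-free (robust to bit depth), but in a
  blob-free stack the global maximum is itself a noise fluctuation and
  every local maximum would become a seed; the MAD floor makes the empty
  field yield zero seeds.
* The erosion-split step ignores eroded cores smaller than 4 voxels:
  single-voxel cores are noise specks, and splitting on them inflates
  counts by a few percent.
* All thresholds are Otsu-derived or relative, so 8/12/16-bit inputs
  behave identically; all geometric parameters are in micrometers and
  converted through the voxel size, so anisotropic voxels (e.g. 0.21 µm
  lateral / 1 µm z-step confocal sampling) get anisotropic kernels.

Spheroid-level readouts: `spheroid_volume()` offers a 3D mask method
(strong Gaussian smoothing so nuclei blur into the body, Otsu, then a
half-maximum refinement — the threshold is re-placed midway between the
modal inside and outside intensities, which puts the surface where the
smoothed profile crosses 50% and is exact for a binary ball — largest
component, morphological closing) and an equivalent-sphere method
$\tfrac{\pi}{6}d^3$; both are provided because published volumes rarely
state which was used. `nuclei_density()` is the exact ratio
count/volume. `optical_density()` reproduces the bright-field readout:
largest dark Otsu component, per-pixel absorbance
$A = -\log_{10}(I/I_{bg})$ against the modal background intensity, OD =
modal absorbance inside the mask divided by the mask area in µm².

# Synthetic data: what it emulates, and what it does not

Generators are pure functions of (scenario, seed): the RNG state is
localized and restored, identical calls are bit-identical, and every
generator returns the ground truth needed to score the downstream stages.

* **Fall videos** (`gen_fall_video`): trajectory from the transient ODE,
  anti-aliased dark disk rendered at the true sub-pixel position
  (area-weighted edge coverage, so sub-pixel centroid truth is
  meaningful), optional per-frame Gaussian centroid jitter and pixel
  noise, 16-bit quantization. The frame rate, if unspecified, advances
  the disk ~2.5 px per frame but is capped so the sequence spans at least
  25 relaxation times — otherwise large, dense spheroids would never
  reach terminal velocity inside the clip.
* **Nuclei stacks** (`gen_nuclei_stack`): centers rejection-sampled in
  the sphere at a minimum separation; nuclei as anti-aliased solid balls
  over a dim spheroid body (0.08 of nucleus peak, emulating residual
  stain/autofluorescence — absent when the scenario has zero nuclei, a
  background-only field); Gaussian PSF blur; Poisson photon noise scaled
  to the stated peak SNR plus Gaussian read noise; a matching 2D
  bright-field absorbing disk. Default sampling: 0.7 µm lateral (a
  binned-confocal compromise that keeps test stacks small), 1 µm z-step.
* **Cohorts** (`gen_cohort`): Gaussian cells for 3 conditions × 2 states
  × 3 parameters. The default scenario encodes the treatment pattern the
  assay is designed to resolve — density rising (1.048 → 1.056 → 1.060
  g/cm³), weight falling (4.4 → 3.6 → 3.2 µg), diameter falling (200 →
  185 → 175 µm) with dose, identical in live and fixed states — with
  per-parameter SDs (0.003 g/cm³, 0.35 µg, 8 µm) chosen so every dose
  effect is ≥ 2 SD. That spread level is what makes a cohort of 15
  spheroids per cell produce uniformly significant comparisons, the
  regime the reproduced study reports; wider spreads would instead
  emulate an underpowered study. Injected outliers are one-sided high
  values (doublet/debris-like artifacts): symmetric contamination
  largely cancels skewness and halves the power of the Shapiro–Wilk
  gate, which is itself an instructive property of the pipeline.
* **Standard curves** (`gen_standard_curve`): a line plus Gaussian noise.

Not emulated — and therefore not demonstrated by passing tests: optical
aberrations and depth-dependent signal loss in thick samples, clearing
artifacts and refractive-index mismatch, non-spherical or deforming
spheroids, flow disturbances in the channel, camera vignetting or
fixed-pattern noise, and nucleus shape/intensity heterogeneity beyond
radius jitter. Results on real data depend on those factors; the synthetic
loop validates the *algorithms*, not the instrument.

# Problem sizes and determinism

The test suite and the acceptance script size their simulations to run
comfortably on a single CPU: 16 noiseless videos on the (density ×
diameter) design grid, 200 noisy-video replicates, 10 nuclei stacks at
20/50/100 nuclei (stack extents ~44–54 µm, i.e. ~300k voxels), 200
null-cohort replicates, and exhaustive small-integer enumerations for the
statistics oracles. These sizes were chosen as the smallest at which the
checked quantities (maximum errors, coverage fractions, type-I rates)
are stable across seeds. All randomness flows through explicit seeds;
two runs with the same configuration are byte-identical, including CSV
outputs.

# Known limitations

* The watershed flood quantizes intensity into 64 levels; sub-level
  valleys between near-equal touching nuclei can land the split a voxel
  off the true valley.
* The wall-correction polynomial is an on-axis result; off-axis settling
  and particle–wall hydrodynamic lift are not modeled.
* Tukey fences at small n are noisy: legitimate ~3σ draws are
  occasionally removed along with true outliers (measured: the removed
  set equals the injected set in ~88% of seeded cohorts, while the
  injected points themselves are removed in ~99.5%).
* `read_stack()` stores intensities in [0, 1] at 16 bits; inputs already
  on that grid round-trip exactly, arbitrary floats are quantized.
* The fixation ANOVA layout is one declared resolution of an ambiguous
  published design; alternative groupings give different F values on the
  same data.
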