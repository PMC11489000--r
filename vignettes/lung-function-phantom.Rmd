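---
title: "Regional lung function mapping with a digital phantom: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional lung function mapping with a digital phantom: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungmap)
```

# What the package computes

`lungmap` implements a single-slice functional lung MRI analysis chain and a
digital phantom that exercises it end to end with known ground truth:

1. **Specific ventilation (SV)** from an oxygen-enhanced image time series,
   by matched-filter correlation against model washin/washout time courses.
2. **Water density** from a dual-echo acquisition, by monoexponential
   back-extrapolation to TE = 0 and calibration against an in-field
   reference phantom of known density.
3. **Perfusion (Q)** from a selective/nonselective arterial-spin-labelling
   (ASL) pair, with surface-coil correction, phantom calibration to
   mL/min/mL, and removal of conduit vessels.
4. **Heterogeneity and clearance metrics**: relative dispersion
   (spatial SD / spatial mean) of the SV and Q maps, and an image-based
   lung clearance index (LCI) synthesised from the SV histogram.
5. **Cohort statistics**: paired and variance-gated independent t-tests,
   rank/linear correlation screens, and exact noncentral-t power analysis.

Human oxygen-enhanced/ASL MRI data of this kind are generally not publicly
distributable, so the package's first-class citizen is a *digital sagittal
lung phantom* (`make_phantom()`): every estimator can be run on simulated
acquisitions whose per-voxel truth is known, which turns the whole pipeline
into a testable object.

# The gas-dilution model behind SV mapping

SV is the regional tidal volume change over the end-expiratory volume,
$s = \Delta V / V_0$. At end expiration a lung unit holds resident gas at
alveolar O$_2$ fraction $f_n$; one breath adds a fraction $s$ of fresh gas
at the inspired fraction $F_n$, giving the dilution recursion

$$ f_{n+1} = \frac{f_n + s\,F_n}{1 + s}. $$

After a step change in $F$, the distance to equilibrium shrinks by
$1/(1+s)$ per breath, so high-SV units equilibrate faster — the washin
*rate*, not amplitude, encodes SV. The breathing protocol alternates room
air (FiO$_2$ 0.21) and 100% O$_2$ in 20-breath blocks repeated three
times, with 20 extra breaths appended to the first O$_2$ block to resolve
slowly equilibrating regions: 140 breaths, one image per breath
(`default_schedule()`). The air block is placed first to provide the
baseline; the alternating cycle counts fix everything else, and starting on
air is the natural reading of a step-change protocol acquired from a
resting baseline.

The estimator (`estimate_sv_map()`) drives the recursion for each of 50
log-spaced SV candidates on $[0.01, 10]$, z-normalises the resulting time
courses, and assigns each voxel the candidate maximising Pearson
correlation with its measured time course. Because correlation is invariant
to affine transformations of the signal, the estimate is independent of
local coil gain, baseline signal and the exact O$_2$ relaxivity — which is
why the simulator only needs a *linear fractional enhancement* model,

$$ S_n = S_{\mathrm{air}}\left(1 + e\,\frac{f_n - 0.21}{0.79}\right), $$

with a default maximal enhancement $e = 0.12$, a magnitude typical of
oxygen-enhanced lung imaging. Ties in the correlation argmax are broken
towards the smaller SV, a deterministic and conservative choice. Voxels
with a flat time course or best correlation below `min_corr = 0.5` carry no
trusted estimate and are excluded from the valid mask (counted in QC)
rather than assigned an arbitrary value.

Grid choice: 50 log-spaced candidates bound the quantisation error at half
a grid step (about 7% in ratio terms) while keeping the template bank
small; recovery on noiseless data is exact for on-grid truth and within one
grid step for off-grid truth, and doubling the (nested) grid density never
increases the per-voxel error. These properties are asserted in the test
suite.

Frame alignment: the phantom emits aligned frames, so registration is a
convenience for real series. `register_series()` implements integer-voxel
phase-correlation alignment to the series median image; the shift log
records each frame's estimated displacement, and applying the inverse
translation reproduces the aligned output exactly. Sub-voxel and deformable
registration are out of scope.

# Density mapping and the coil field

With two echoes at $TE_1 < TE_2$ and monoexponential decay
$S(TE) = S_0 e^{-TE/T_2^*}$, the closed form

$$ T_2^* = \frac{TE_2 - TE_1}{\ln(S_1/S_2)}, \qquad
   S_0 = S_1\,(S_1/S_2)^{TE_1/(TE_2-TE_1)} $$

back-extrapolates the signal to TE = 0 (`extrapolate_s0()`; defaults
$TE$ = 0.82 and 1.8 ms). Non-decaying voxels ($S_1 \le S_2$, typically
noise) are flagged and excluded rather than silently inverted. $S_0$ is
converted to mL H$_2$O/cm$^3$ by the median signal of the reference phantom
ROI of known density (`calibrate_density()`); the median is robust to ROI
edge voxels, and any global scanner gain cancels in the ratio.

The surface-coil sensitivity field is the ratio of torso-coil to body-coil
$S_0$ maps (proton density cancels). We regularise this ratio with a
low-order (order-2) 2D polynomial surface fitted over the lung + phantom
support, then normalise to median 1 over the support
(`estimate_coil_field()`). A masked Gaussian blur is also available
(`method = "gaussian"`, scale 5 voxels), but smoothing within a finite
support is first-order biased wherever the neighbourhood is one-sided (bias
$\approx \sigma \times$ local gradient at the support edge), which
measurably degrades noiseless recovery; receive fields vary smoothly over a
40 cm field of view, making the polynomial bias-field model the better
default. Residual coil structure beyond the fitted order is a known
limitation and is listed below.

# ASL perfusion quantification

The nonselective image carries static tissue signal; the selective image
additionally carries the blood delivered to the slice during one cardiac
cycle (inversion delay 80% of the R-R interval). The pipeline subtracts the
pair (negatives preserved — clipping would bias mean Q upward), divides by
the coil field, converts signal to millilitres via the coil-corrected
phantom-ROI signal per mL of water, and scales per-cycle delivery to
per-minute perfusion with the heart rate:

$$ q = \frac{\mathrm{sub}/c}{\kappa\,V_{\mathrm{vox}}} \times \mathrm{HR}
   \quad \left[\tfrac{\mathrm{mL\ blood}}{\mathrm{min\ \cdot\ mL\ lung}}\right], $$

where $\kappa$ is the phantom-derived signal per mL. The full constant
chain of absolute ASL quantification (blood T1, inversion efficiency) is
deliberately folded into the phantom calibration: within the simulator this
closes the loop exactly (noiseless round trips recover truth to $10^{-6}$
relative), and on real data it is the honest contract — everything hangs on
the in-field reference.

Conduit vessels carry blood destined elsewhere, so voxels whose delivered
volume strictly exceeds 35% of the image maximum are removed
(`filter_vessels()`); boundary voxels are retained, a uniform map triggers
a degeneracy warning instead of wholesale removal (outliers cannot exist),
and the filter is applied *after* coil correction, following the
processing order of the subtraction-then-correction-then-quantification
chain. Total delivered signal is conserved across the split into retained
and removed voxels. With realistic parenchymal spread the threshold also
trims the extreme parenchymal tail; that is inherent to a
fraction-of-maximum filter, and the removal count is always reported.

# Relative dispersion and the image-based LCI

Relative dispersion, RD = spatial SD / spatial mean, is computed with the
sample ($n-1$) standard deviation over valid (SV) or retained (Q) voxels.

The image-based LCI treats each SV-map voxel as a washout compartment: its
normalised tracer concentration after $n$ breaths is $(1+s)^{-n}$, and the
composite whole-lung curve is the voxel-frequency-weighted sum over the SV
histogram. `image_lci()` finds the fractional breath count $n_c$ at which
the composite curve reaches 1/40 of its initial value (monotone bracketing
plus bisection to $10^{-6}$ breaths; integer stepping would quantise the
index) and converts breaths to lung turnovers. Two conversions are
reported:

* **VT/FRC** (used as `lci` when tidal volume is known): the physiological
  definition of a turnover per breath;
* **volume-weighted mean SV** (`lci_mean_sv`, also the fallback): summing
  $s_i V_{0,i}$ over voxels gives whole-lung $\Delta V/\mathrm{FRC}$, so
  the map's weighted mean SV *is* the FRC-based turnover per breath when no
  independent tidal volume exists.

For a homogeneous map the index has the closed form
$s \ln 40 / \ln(1+s)$, with limit $\ln 40 \approx 3.689$ as $s \to 0^+$;
heterogeneity at fixed mean SV can only raise the index, which is exactly
what makes it a heterogeneity metric. Voxels with $s = 0$ never clear; they
are excluded with a warning and their weight redistributed, since a single
non-ventilating voxel would otherwise make the index infinite. The
relationship of this image-derived quantity to hardware multiple-breath
washout LCI is untested by construction, and the package makes no claim
about it.

# The digital phantom and the synthetic cohort

`make_phantom()` builds a 64 × 64 sagittal slice (40 cm FOV, 15 mm slice,
voxel 0.586 cm$^3$): an elliptical lung mask; smooth lognormal textures for
SV, Q and density (positive, right-skewed, spatial correlation length
about 4-6 voxels), rescaled so the in-mask mean matches the request
exactly; 2-4 small elliptical conduit vessels at 10× the parenchymal
median delivery (conduit vessels are nearly pure blood, and this keeps the
35% filter's targets unambiguous); an anterior-peaked quadratic coil ramp
(1.0-2.5×); and a reference phantom ROI of density 1 mL/cm$^3$ on the
chest wall. Noise is additive zero-mean Gaussian at a configurable SNR —
Rician effects are negligible at parenchymal SNR and Gaussian noise keeps
the oracles closed-form. SNR is defined against the mean lung signal of
each acquisition, except ASL, where it is defined against the mean
*subtraction* signal: the perfusion-weighted difference is the quantity the
measurement must resolve, and anchoring noise to the (much larger) static
signal would describe a different experiment per density value.

The synthetic cohort (`simulate_cohort()`, `run_pipeline()`) reproduces the
study design the package targets: 6 single-timepoint controls and 14
pre/post vapers. Population defaults are set to the published cohort scale
— control/vaper mean SV 0.15/0.20 (SD 0.05/0.07), RD(SV) 0.31, mean Q
1.43 mL/min/mL (SD 0.65), RD(Q) 0.60, heart rate 68.1 ± 10.5 bpm with a
+3.2 bpm post-exposure shift, BMI 24.6 ± 4.0 kg/m$^2$ — and the
post-exposure change in mean Q depends on BMI with slope
−0.037 (mL/min/mL)/(kg/m$^2$) against a residual SD of 0.15, which gives a
population correlation near −0.7 and matches group-mean changes of roughly
+0.1 (low BMI) and −0.15 (high BMI) mL/min/mL. Group-level SV and Q effects
default to ≈ 0, mirroring the null findings the design emulates. Per-subject
seeds derive from the master seed by a stable hash, so results are
independent of processing order, and one subject's failure is recorded
without aborting the cohort.

What the phantom does *not* emulate: cardiac/respiratory motion and
deformable misalignment, k-space acquisition artefacts, slice-profile and
inflow effects, multi-slice 3D geometry, Rician noise floors, and real
physiological covariance between SV, Q and density beyond their independent
textures. Recovery tests on the phantom therefore validate the estimator
algebra and the pipeline plumbing, not robustness to those real-data
effects.

# Statistics layer

Paired t-tests compare pre/post within vapers; independent comparisons are
gated by Levene's test (mean-centred, as in mainstream statistical
packages): pooled-variance t when Levene's p > 0.05, Welch otherwise, with
the chosen path recorded. Correlation screens use Spearman by default with
Pearson available, pairwise deletion, and explicit flags for constant
columns or n < 4. Raw p-values are the primary report (matching the
many-contrasts reporting style the package mirrors); an optional
Benjamini-Hochberg column is available and clearly labelled as an
extension.

`required_sample_size()` solves for the smallest integer n per group whose
exact noncentral-t power reaches the target (power is monotone in n, so a
doubling-then-bisection integer search is exact); the normal approximation
is reported alongside. Both the per-group and total sample sizes are
returned, since "participants" in a power statement can be read either
way. Degenerate inputs (d = 0, zero-variance differences) produce explicit
errors or flagged results, never silent NaNs.

# Numerical choices and problem sizes

* SV template matching: all correlations computed as one crossprod of
  z-normalised matrices; exact ties broken to the smaller candidate.
* LCI bisection tolerance $10^{-6}$ breaths; bracketing by doubling.
* Coil polynomial order 2 (6 coefficients) fitted by least squares.
* Vessel threshold: strictly-greater-than comparison, so voxels exactly at
  the threshold are retained.
* Default problem sizes: 64 × 64 grids with 140-frame series for recovery
  experiments, the 6 + 14 cohort (34 image sets) for end-to-end runs, 1000
  replicates for type-I calibration and 500 for sign-of-correlation
  checks — sizes chosen so the full suite documents the science while
  remaining quick on a laptop.

# Known limitations

* Registration is integer-shift rigid only, and the phantom emits aligned
  frames; deformable motion is untested.
* The coil model is polynomial; fields with sharper structure than the
  fitted order would be under-corrected (raise `order`, or use the
  Gaussian variant with a scale suited to the data).
* The ASL calibration leans entirely on the reference phantom ROI; there is
  no independent absolute-quantification chain.
* The image-based LCI is a single-slice surrogate assumed representative of
  the whole lung; its mapping to hardware washout LCI is out of scope.
* The vessel filter is a fraction-of-maximum heuristic; with heavy-tailed
  parenchymal perfusion it removes some genuine parenchyma.
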