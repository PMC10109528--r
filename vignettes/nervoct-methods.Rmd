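---
title: "Models and estimators behind nervoct"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and estimators behind nervoct}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`nervoct` analyses polarization-sensitive OCT studies of peripheral nerve
electrostimulation injury. Because no public raw data exist for this kind
of experiment, the package pairs every estimator with a forward simulator
whose ground truth is known exactly; this vignette documents the forward
model, each estimator and its assumptions, the tunable parameters, and
what passing the recovery tests does and does not establish.

## The forward model

Each lateral position of the digital nerve phantom is a column of thin
linear-retarder slabs. A slab at depth $z$ has one-way retardance
$\delta(z)\,\mathrm{d}z$ (deg) at axis $\theta(z)$ (deg, mod 180). The
one-way cumulative Jones matrix is the ordered product
$M(z) = m_z \cdots m_1$, and reciprocity gives the round-trip matrix as
the transpose sandwich $J_{rt}(z) = M(z)^{\mathsf T} M(z)$, which is
symmetric — the standard single-backscatter model for fibre-based PSOCT.
The instrument contributes a unitary $U$ on both passes:

$$J_{meas}(z) = U^{\mathsf T}\, J_{rt}(z)\, U .$$

Two probe states (horizontal and 45° linear; any non-degenerate pair
works and the pair is recorded in the configuration) are interleaved on
alternating A-lines, both sampling the same tissue column. The
backscattered amplitude is
$\sqrt{\beta(z)}\exp(-\int_0^z \mu\,\mathrm{d}z')$, so intensity decays as
$e^{-2\mu z}$; fully developed speckle multiplies each voxel by a complex
circular Gaussian scalar that is frozen across repeated frames for static
tissue and follows an AR(1) process with coefficient $\rho$ inside
vessels. A per-voxel depolarization fraction mixes in an unpolarized
field. Complex Gaussian noise is set by the surface SNR (default 30 dB)
and the field is blurred axially by the source PSF, whose FWHM
$(2\ln 2/\pi)\lambda_0^2/\Delta\lambda$ is 6.88 µm for a 1310 nm / 110 nm
source.

Simulation starts at complex tomograms rather than spectral fringes:
resampling and dispersion compensation are hardware-specific and add
nothing testable to the analysis chain.

Two modelling choices deserve emphasis:

* **Instrument unitary class.** The simulated fibre unitary is a real
  rotation (circular birefringence) times a global phase. For this class a
  single offset-plus-chirality calibration against the reference stripes
  is exact. A fully elliptical fibre unitary would require the
  symmetrization machinery of dedicated catheter-PSOCT processing, which
  is out of scope; the estimators make no claim for that regime.
* **Constant single-scattering albedo.** Backscatter is proportional to
  attenuation across tissue classes. This is the regime in which the
  depth-resolved attenuation estimator is exact; media whose backscatter
  varies independently of µ bias any tail-sum estimator.

## The default phantom

A 192 × 96 × 40 grid (z × x-pairs × y) at 3.5/10 µm pitch: a scattering
bed holding an epineurium ellipse with three disjoint fascicles — L, C, R,
named by proximity to the stimulation lead — plus two birefringent
calibration stripes at exactly 0° and 45° flanking the tissue, and three
epineurial vessels (ρ = 0.3) running along the slow axis. Fascicle
parameters: δ = 0.30/0.25/0.30 deg µm⁻¹, θ = 20°/90°/150°,
µ = 4.5/4.0/5.0 mm⁻¹. The fascicle thickness (~210 µm) keeps the
round-trip retardation below the 180° fold. The grid is deliberately
desk-scale — a full-field volume at this pitch would occupy gigabytes as
complex arrays with no gain in coverage, since every estimator is
translation-invariant; the aspect ratio of a real ~2.5 × 2 mm nerve field
is preserved and everything scales through `default_nerve_geometry(dims)`.

## Estimators

**Attenuation.** $\hat\mu_i = \ln(1 + I_i/\sum_{j>i} I_j)/(2\Delta z)$,
exact for discrete exponentials. Three practical corrections matter: the
mean noise power (estimated from the air gap above the tissue as mean
linear power, not median dB) is subtracted; intensities are averaged over
a 5-pixel lateral boxcar before estimation (halves the Jensen bias of
ln(1+x) under exponential speckle); and the truncated tail is extrapolated
by fitting a log-linear slope to the deepest 15 pixels and adding the
analytic geometric remainder, using the fitted rather than raw intensity
at the last pixel. The deepest 20 pixels are masked.

**Retardation and axis.** The surface-relative matrix
$J(z_0)^{-1}J(z)$ cancels the instrument unitary; its eigenvalue phase
split, unwrapped along depth (the fold at 180° is resolved by continuity,
and the eigenvector branch is swapped by 90° past the fold), is the
cumulative round-trip retardation. The axis comes from the leading
eigenvector mapped to Stokes space, masked where the phase split is
within 4° of 0 or 180° (eigenvectors undefined).

Cumulative eigenphases compound non-additively when layers above a
structure have a different axis, so quantitative per-structure readings
use the **segment estimator** `segment_retardation()`:
$N = J(z_1)^{-1}J(z_2)$ is similar to the round-trip matrix of the
segment alone, making its phase split exactly $2\int\delta\,\mathrm{d}z$
over the segment and its eigenvector the segment axis, independent of the
overlayer. Because speckle enters $J$ as a per-voxel scalar it cancels in
$N$ up to a phase; after normalising to unit determinant (sign chosen so
the trace stays positive) neighbouring A-lines are averaged coherently
(5 × 5 default) before the eigendecomposition, which suppresses the
additive-noise bias of that nonlinear step. Retardation is taken
per-column before this averaging: averaging matrices across columns with
varying axes or thicknesses shrinks the phase split.

**Calibration.** The stripe axes are measured with the segment estimator
over each stripe body; the offset zeroes the P0 reading and the sign is
chosen so P45 reads +45° rather than −45°. The same transform applies to
the whole volume and to any segment-estimator output
(`apply_axis_calibration()`). Stripes whose mean axes are closer than 10°
abort with a calibration failure.

**DOPU and validity.** DOPU is the norm of the boxcar-averaged
(3 × 9 default) unit Stokes vector of the first probe state's response.
The polarization-valid region is a **depth limit per A-line** — valid from
the surface down to the first run of three voxels failing
DOPU ≥ 0.6 ∧ reflectance ≥ noise floor + 5 dB — not a voxelwise sieve: a
voxelwise mask would retain only bright-speckle voxels at depth and bias
intensity statistics upward. In the default phantom ~60% of tissue voxels
are polarization-valid, consistent with the fraction of nerve depth
usable in practice.

**Angiography.** First-order pairwise complex decorrelation over adjacent
repeats with a 3 × 3 correlation kernel (an intensity-variance variant
is deliberately not provided; the complex form is analytically tractable
and its independent-speckle limit is checked against a Monte-Carlo
oracle). Registration is integer-shift only, by exhaustive normalized
cross-correlation with crop-to-overlap — rotation and tissue stretch are
known limitations of rigid tiling and are not corrected. The vessel FWHM
background is the mean of the outer 20% of profile samples, robust to
sloped backgrounds. Vessel-fraction filter defaults (1–99 percentile
rescale, Otsu threshold, radius-1 opening and closing) are chosen so the
synthetic-truth coverage is recovered within 2 percentage points; a study
would pin them per dataset.

**Group statistics.** Region values are averaged per animal and
timepoint; each animal contributes D7 − baseline; groups are summarised by
mean ± SD. The percent-versus-sham column
$100(\Delta_g - \Delta_{SC})/|\Delta_{SC}|$ is one defensible
normalisation and is labelled as derived — it is not asserted to equal any
particular published normalisation. Two-way (group × fascicle) ANOVA runs
on per-animal deltas with Tukey-adjusted group contrasts within each
fascicle; vessel timecourses use the balanced within-subject equivalent
(animal as block), which keeps the Tukey machinery on an lm-type fit.
Degenerate all-equal inputs report F = 0, p = 1 by contract.

**Dosing.** $k = \log_{10} Q + \log_{10} (Q/A)$ with $Q = I \cdot PW$ in
µC and $A = \pi d L$ the full lateral cylinder area of the 0.2 mm
positive lead — the unique simple geometric reading that reproduces both
study arms' k values (2.57, 3.17) from the printed current, pulse width
and electrode dimensions. Frequency does not enter k and is kept only for
waveform synthesis.

**SFI/TFI.** Coefficient sets (−38.3, 109.5, 13.3, −8.8) and
(−37.2, 104.4, 45.6, −8.8) follow the rodent walking-track literature and
are configuration constants, so alternative published sets can be swapped
in. The gait simulator maps deficit d = 1 to +40% print length and −60%
toe spreads, landing the SFI near −100 (complete injury), and d = 0
reproduces the normal side exactly (SFI = −8.8).

## The synthetic cohort and what it shows

`run_cohort()` images each animal at baseline and day 7 on a reduced
128 × 64 × 15 grid (single repeat, 30 dB, three analysis regions of three
frames — the reduced counterpart of five regions × 25 frames at full
field size), with 2% between-animal variation in fascicle birefringence
and attenuation and an injected day-7 effect multiplying one truth
parameter of one fascicle in one arm. One global seed fans out to
per-animal, per-stage substreams (`derive_seed`), so any stage can be
replayed in isolation; failures quarantine the animal and the cohort
continues, and the manifest records seeds, configuration and exclusions.

Statistical power and type-I behaviour are quantified at the
metric-record level: per-animal deltas are drawn from a Gaussian at the
noise scale measured from a full imaging null cohort, the injected effect
is added to the target cell, and the ANOVA + Tukey chain is run on each
replicate (200 for power, 20 for the null). Re-imaging hundreds of
cohorts would add hours of compute without exercising any code path the
single full cohorts do not already cover; the record-level replicates
exercise exactly the inferential chain whose operating characteristics
are in question.

What passing all of this establishes: the estimators invert the stated
forward model at realistic SNR, the calibration makes axis maps
instrument-independent within its class, and the statistics chain detects
a localised 20% demyelination-scale effect in a 14-animal design without
false flags. What it does not establish: behaviour under multiple
scattering, elliptical fibre birefringence, bands of Fontana, bulk motion
beyond single-row artifacts, or real biological effect sizes — real nerve
data remain the only test of those.

## Numerical conventions

Depth index 1 is the shallowest pixel; the tissue surface is the first
depth where reflectance exceeds the noise floor by 10 dB for three
consecutive pixels; the retardation reference sits 2 pixels below it, and
pixels between surface and reference read 0. Axis angles live on
[0, 180) and are averaged in the doubled-angle representation; the
coherent frame mean masks pixels whose resultant length falls below 0.3.
ROI pixels count when their centres fall inside the polygon; records with
fewer than 50 valid pixels are flagged invalid and excluded from
statistics. Volumes are written as 32-bit scaled TIFF with a JSON sidecar
(value 0 reserved for NA); tables as CSV with a schema-versioned sidecar.
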