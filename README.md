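# nervoct

Quantitative polarization-sensitive OCT (PSOCT) analysis of
electrostimulation-induced peripheral nerve injury, as a tested, fully
synthetic-data-driven R pipeline.

Electrical overstimulation of a peripheral nerve damages myelin before any
gross structural change is visible. PSOCT sees this label-free: myelin is
birefringent, so its degradation shows up as a drop in tissue phase
retardation, alongside changes in attenuation, depolarization and
perfusion. `nervoct` implements the full analysis chain for such a study —
from raw polarization-diverse tomograms to fascicle-level injury statistics
— together with a forward simulator that generates every input with known
ground truth, so each stage is verified by parameter recovery rather than
by eye.

## What the package computes

**Channel reconstruction.** A Jones-matrix PSOCT system probes tissue with
two polarization states interleaved on alternating A-lines. Per voxel the
measured matrix is `J = [E₁|E₂]·[e₁|e₂]⁻¹`; the package reconstructs six
channels from it:

- reflectance `R = 10·log₁₀ Σ|Jᵢⱼ|²` (dB);
- depth-resolved attenuation `µ̂ᵢ = ln(1 + Iᵢ/Σ_{j>i} Iⱼ)/(2Δz)` (mm⁻¹),
  with noise subtraction and a tail-extrapolation correction;
- cumulative round-trip phase retardation: the eigenvalue phase split of
  the surface-relative matrix `J(z₀)⁻¹J(z)`, unwrapped along depth
  (instrument-fibre invariant by construction);
- optic axis from the leading eigenvector, calibrated against two rigid
  reference stripes whose axes are 0° and 45°;
- DOPU, the norm of the kernel-averaged unit Stokes vector;
- BwOA, an HSV composite (hue = axis, saturation = local retardance,
  value = reflectance).

**Angiography.** Inter-repeat decorrelation
`1 − mean_r |⟨E_r E*_{r+1}⟩|/√(⟨|E_r|²⟩⟨|E_{r+1}|²⟩)` over five repeated
frames, en-face projection below the detected surface, motion-line
suppression, integer-shift co-registration, vessel FWHM diameters and the
vessel coverage fraction.

**Injury metrics.** Five-region frame averaging (coherent for the axis),
manual-style fascicle ROI means, the baseline-referenced group statistic
`Δmetric = avg_grp(D7 − D1)` per fascicle and channel, and two-way
ANOVA with Tukey-adjusted contrasts (repeated-measures variant for vessel
timecourses).

**Stimulation dosing.** The Shannon safety model
`k = log₁₀(Q) + log₁₀(Q/A)` with `Q = I·PW` and the positive-lead
cylinder area `A = π·d·L`; plus the cathodic-first charge-balanced
waveform itself.

**Histology and function.** Presence/absence pixel counting of RGB
immunofluorescence inside ROI polygons with myelin/axon ratios; sciatic
and tibial function indices (SFI/TFI) from footprint geometry and Von Frey
withdrawal summaries.

## Worked example

```r
library(nervoct)

# Shannon dose of the strong stimulation arm
shannon_k(stim_spec("SL2"))
#> $Q_uC 0.68   $A_cm2 0.000314   $D_uC_cm2 2164.5   $k 3.168

# phantom -> acquisition -> channels -> recovery
truth <- build_nerve_truth(seed = 1)
raw   <- simulate_tomogram(truth, acq_config(
           n_repeats = 5, snr_db = 30,
           system_unitary = random_system_unitary(13), seed = 7))
cs    <- reconstruct_channels(raw, stripe_rois = stripe_masks(truth))
print(cs)
#> channel_set: 192 x 96 x 40 | noise floor -28.2 dB | 57.9% voxels polarization-valid
#>   axis calibration: offset 141.5 deg, chirality +1 (P0 -> 0.00, P45 -> 45.85)
```

The calibration line is the 0°/45° stripe contract: after removing the
instrument-fibre offset, the two reference stripes read back 0° and ~45°.
Running `analysis/02_phantom_recovery.R` prints the per-fascicle recovery
table; at these settings the three fascicles' retardance comes back within
2.5% of `2·δ·thickness`, the calibrated axes within ~1° of the ground
truth (20°/90°/150°), and attenuation within 2% of the simulated µ.

The `analysis/` directory holds the numbered study drivers
(`01_stimulation_dose.R` … `05_histology_gait.R`); each writes its tables
under `results/`. `04_cohort_statistics.R` images a 14-animal cohort with
a −20% day-7 retardance injury confined to (SL2, fascicle R) and shows
that exactly that cell — and no other — exceeds three null-cohort standard
deviations, with the SL2-vs-SC Tukey contrast flagged in 100% of 200
record-level replicates and a 0/20 null flag rate.

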