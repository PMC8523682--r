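---
title: "Methods: seed-based resting-state connectivity mapping with seedconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seed-based resting-state connectivity mapping with seedconn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Overview

`seedconn` implements a seed-based resting-state functional-connectivity
analysis for small two-group fMRI cohorts, together with a synthetic cohort
generator with analytically known ground truth. The pipeline produces one
standardized connectivity z-map per subject from a 9-voxel posterior
cingulate (or any user-placed) seed, then group-average and group-difference
maps with voxel plus cluster-extent thresholding, and ROI/group summary
tables.

The single-subject chain is, in fixed order:

1. **Physiological nuisance regression.** Cardiac and respiratory phases,
   sampled once per volume, enter a Fourier (RETROICOR-style) design:
   intercept plus `m` sine/cosine harmonic pairs per signal
   (`K = 1 + 4m` columns; default `m = 2`, i.e. 8 physiological regressors).
   Each in-mask voxel series is replaced by its least-squares residual.
2. **2D in-plane Hamming spatial filtering.** Each axial slice's 2D spatial
   spectrum is multiplied by a separable Hamming window
   `w(k) = 0.54 + 0.46 cos(pi k / k_max)` per in-plane frequency axis, unity
   at DC. This is k-space apodization: a mild in-plane smoothing that
   improves functional contrast-to-noise while preserving slice means.
3. **Temporal low-pass filtering.** All fluctuations above 0.08 Hz are
   removed by hard DFT-bin projection: bins with `|f| <= 0.08` Hz (and DC)
   are kept, all others zeroed, and the series inverse-transformed.
4. **Seed and reference.** The seed is the 3×3 single-slice voxel block
   around a user-given center; the reference time series is the linearly
   detrended arithmetic mean of the nine voxel series.
5. **Correlation, t, z.** Zero-lag Pearson correlation of every in-mask
   voxel with the reference; conversion to Student's t via
   `t = r sqrt(dof / (1 - r^2))`; then whole-brain standardization
   `z = (t - mean) / sd` over in-mask voxels, yielding a map with zero mean
   and unit variance. This per-subject standardization absorbs individual
   differences in global signal amplitude.

Group analysis averages the subject z-maps per group, forms the difference
of group means (first group minus second), optionally standardizes it by its
null standard deviation `sqrt(1/n_a + 1/n_b)`, thresholds voxels at the
normal critical value for `alpha = 0.05` (two-sided, `|z| >= 1.96`), and
retains only connected components of more than 30 voxels.

## Design choices

Several aspects of this kind of analysis are conventionally underspecified;
the package fixes them as follows and records each in output sidecars.

**Hard spectral projection for the temporal filter.** "Remove all
fluctuations above 0.08 Hz" is implemented literally as a DFT-bin mask
rather than an FIR/IIR design. The projection is zero-phase, idempotent and
linear, which makes the filter's contract exactly testable (passband bins
preserved to 1e-10 relative power, stopband bins annihilated).

**Hamming window parameterization.** The literature names the filter but
not its parameterization. We define the window at DC-centered spatial
frequencies, separable per in-plane axis, with unit DC gain, so constant
slices and slice means are invariant. The impulse response (the spatial
kernel) is the inverse transform of the window and is verified in tests.

**Degrees of freedom.** The t conversion defaults to the nominal
`dof = T - 2` (130 for a 132-volume series). Temporal filtering reduces the
*effective* degrees of freedom (only about 45% of the spectrum survives a
0.08 Hz cutoff at TR 2.8 s), so a `fixed` policy lets the user supply a
smaller value. Because the subsequent whole-brain standardization is
affine-invariant and the t conversion is monotone, the choice of dof does
not change the rank order of the final z-map, only its tails.

**Standardization convention.** The whole-brain distribution is treated as
the population of interest, so the default is the population SD (divide by
N) over in-mask voxels; the sample convention is available and recorded in
the sidecar. For report tables of per-subject scalars the *sample* (n-1) SD
is used — the convention identified by recomputing published group rows: the
sample SD of (2.62, 2.83, 3.00) prints as 0.19 while the population SD would
print as 0.16.

**Cluster rule.** "Cluster requirement > 30" is read strictly: surviving
components must have at least 31 voxels. Connectivity defaults to face
adjacency (6-neighborhood), the most conservative standard choice;
18- and 26-neighborhoods are available. Positive and negative suprathreshold
voxels are labeled separately so oppositely signed adjacent regions are
never merged. Components are found with `igraph` over the voxel adjacency
graph.

**Difference-map modes.** How a single-voxel "p < 0.05" maps onto a
difference of mean z-maps is ambiguous. `naive_diff` thresholds the raw
difference at the normal critical value; the default `standardized_diff`
first divides by `sqrt(1/n_a + 1/n_b)` — the null SD of a difference of
means of unit-variance maps — so the threshold has its nominal calibration.
With two groups of three, the raw-difference null SD is `sqrt(2/3) ≈ 0.82`,
so the naive mode is conservative.

**ROI summaries.** Per subject and region, the mean, sample SD and count
are computed over voxels whose z exceeds a floor (default 2.3). Published
per-participant tables of this layout have per-region minima clustering near
2.4–2.5, implying some suprathreshold restriction whose exact value is
unstated; the floor is therefore an explicit, required-to-confirm parameter.

**Voxel indexing.** All voxel coordinates are 1-based (R convention), axis
order X, Y, Z, T, stated once on the package help page and used everywhere.

## The synthetic cohort generator

Real resting-state data for a six-subject case series of this design are not
publicly available, so validation rests on simulation with known ground
truth. `generate_subject()` builds each voxel time series as

    a * n(t) * [voxel in a node]  +  physio_amp * (sin phi_c + sin phi_r)
      +  drift_slope * t  +  s * eps(t)

where `n(t)` is a single unit-variance latent source shared by all node
voxels, band-limited strictly below the 0.08 Hz cutoff (random-phase DFT
bins 2–29 for a 132-volume series at TR 2.8 s, so the temporal filter
preserves the signal by construction), `phi_c, phi_r` are the per-volume
cardiac/respiratory phases also written to the physio file (so the
downstream Fourier regression can remove the confound exactly at harmonic
1), `t` is the volume index, and `eps` is white Gaussian noise. The
theoretical correlation of a node voxel's signal-plus-noise component with
the source is `a / sqrt(a^2 + s^2)` — e.g. `1/sqrt(2) ≈ 0.707` at
`a = s = 1` — which makes parameter recovery a closed-form check.

Defaults emulate the study conditions: 132 volumes at TR 2.8 s,
1.2 × 1.2 × 1.5 mm voxels, two groups of three subjects. The remaining
parameters are the package's own choices, fixed a priori:

* **Grid 24 × 24 × 16** — a desk-scale grid (9,216 voxels), not a full
  brain, so a full cohort analysis runs in seconds; dimensions are
  configurable.
* **Three nodes of radius 2 voxels** (33 voxels each; seed node first). The
  node fraction (~1% of the grid) is kept small so whole-brain
  standardization is not dominated by the planted signal, while a 33-voxel
  node can clear the >30-voxel cluster rule once its immediate neighbors
  join.
* **Group amplitudes 0.3 (head-trauma) vs 0.8 (no-head-trauma), noise SD
  1.** No effect-size estimate exists for the group difference, so these
  planted amplitudes are arbitrary by necessity; they are chosen to give
  node-voxel correlations of ~0.29 and ~0.62 — moderate, realistic seed-map
  strengths — and their direction (controls higher) matches the published
  ROI tables. All other parameters are shared between groups, so any
  detected contrast is attributable to connectivity amplitude alone.
* **Drift 0.01 units/volume and physiological amplitude 0.5** — confound
  sizes comparable to the noise SD over a run (the drift accumulates to
  ~1.3 units across 132 volumes), typical of uncorrected EPI drift and
  pulsatility.
* **Phase jitter SD 0.1 rad/increment** — physiological rhythms are not
  metronomes; the jitter prevents the confound from being an exact DFT bin
  while keeping it phase-locked, which is what the Fourier regression
  assumes.

What the generator does *not* emulate: head motion, spatial registration
error, susceptibility artifacts, spatially correlated physiological noise,
multiband reconstruction physics, or anatomical structure. Passing recovery
tests therefore show the pipeline's statistics behave as designed under its
own signal model — not that the pipeline is robust to every artifact of real
acquisitions.

## Numerical details

* Detrending and nuisance regression use QR least squares; residual
  orthogonality to the design (max relative inner product < 1e-8) is the
  tested contract.
* Correlations are clipped to `|r| <= 1 - 1e-12` before the t conversion so
  perfect correlations give huge finite t rather than infinities, keeping
  the standardization well-defined.
* In-mask voxels with zero temporal variance get `r = 0` and a QC count in
  the map's provenance rather than aborting the run.
* A rank-deficient nuisance design is an error that names the dependent
  columns.
* Report tables round half away from zero to 2 decimals.
* All simulation outputs are pure functions of `(config, seed)`; per-subject
  seeds derive deterministically from the base seed.

## Problem sizes used in validation

The bundled validation suite exercises the full acquisition envelope (132
volumes, TR 2.8 s, 3 + 3 subjects) on the default 24 × 24 × 16 grid. The
stochastic group-contrast checks use 20 simulated cohorts for the planted
difference (expecting a surviving cluster overlapping a planted node in at
least 80% of replicates) and 20 equal-amplitude cohorts for false-positive
control (expecting zero surviving clusters in at least 90%). Oracle
comparisons (naive Pearson loops, normal-equation detrending, FFT kernels)
run on grids of at most 8^3 voxels, where exhaustive looping is cheap.

## Known limitations

* No motion correction: inputs are assumed motion-free or already
  corrected, and the generator does not simulate motion.
* No spatial normalization: all inputs must share one grid; only axis
  orientation is canonicalized on load.
* Single-seed maps only; combining left/right hemisphere seed maps is left
  to the user.
* The nominal dof overstates effective dof after filtering; use a fixed
  policy for calibrated t tails if absolute t values matter.
* No family-wise error correction beyond the cluster-extent rule, matching
  the analysis the package reproduces; the false-positive property above is
  an empirical calibration under the generator's null, not a formal
  guarantee.
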