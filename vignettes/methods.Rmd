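---
title: "Methods: source-level EEG band power and brain amyloidosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: source-level EEG band power and brain amyloidosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The analysis problem

Elevated cortical amyloid-beta burden in cognitively normal seniors is
associated with subtle changes in resting-state brain rhythms, notably a
mid-frontal increase of theta-band (4–8 Hz) power. `amypower` implements a
complete analysis chain for testing such effects at the source level:
sensor-space EEG cleaning, linearly constrained minimum-variance (LCMV)
beamformer projection onto a volumetric grid, normalized band-power maps,
and nonparametric group statistics contrasting amyloid-positive (A+)
against amyloid-negative (A−) subjects defined by an amyloid-PET SUVr
threshold of 0.79. Because no public cohort accompanies the protocol, the
package ships a synthetic-data generator that reproduces the statistical
structure the analysis assumes, so every stage is testable end to end.

## The pipeline, stage by stage

### Sensor-space cleaning

1. **Broadband filtering.** A windowed-sinc (Hamming) linear-phase FIR
   band-pass at 1–80 Hz, applied in one forward pass with group-delay
   compensation so the net phase is zero. The filter order follows the
   Hamming rule of thumb (order ≈ 3.3·fs/transition). The default
   transition width is 1 Hz: with a 1 Hz low edge, a wider transition
   would leave DC inside the transition band and a constant offset would
   survive filtering.
2. **Channel rejection.** For every scalp channel three metrics are
   computed over the whole time series — variance, amplitude range
   (max − min) and the signed minimum sample value — and z-scored across
   scalp channels. A channel with |z| ≥ 2.5 on any metric is excluded from
   all downstream analysis (not interpolated). The signed minimum is the
   literal reading of "minimum value"; an absolute-minimum variant is
   available (`use_abs_min`). Rejection is single pass: one thresholding,
   no iterative re-z-scoring.
3. **Common-average reference** over the retained scalp channels only; at
   every sample the retained-channel mean is exactly zero afterwards.
4. **Ocular ICA.** A whitened symmetric fixed-point ICA (logcosh
   contrast) is fit to the retained channels; components are correlated
   with the peri-orbital (EOG) channels and any component with
   max |r| ≥ 0.8 is subtracted from the data. The 0.8 default makes the
   qualitative rule "highest correlation with the EOG plane" into a
   deterministic criterion and is configurable. Because symmetric ICA
   whitens the data, removed and kept components are exactly
   uncorrelated, so the energy removed equals the input-minus-output
   energy. When most sources are (band-limited) Gaussian — true of the
   synthetic cohorts and approximately true of resting EEG — part of the
   unmixing rotation is unidentifiable and the fixed point cannot reach a
   strict tolerance; after the configured restarts the implementation
   proceeds with the final decorrelated unmixing (a warning), because the
   EOG-correlated direction, which is strongly non-Gaussian, does
   converge. `strict = TRUE` turns this into an error instead.

Visual inspection of residual artifact segments has no place in an
automated pipeline; an optional amplitude-threshold segment mask is the
replacement and is off by default.

### Source localization

Recordings are decomposed by a seven-band FIR filter bank (delta 2–4,
theta 4–8, alpha1 8–10, alpha2 10–13, beta1 13–20, beta2 20–30, gamma
30–40 Hz). Per band, the sensor covariance is computed from the merged
eyes-closed (EC) and eyes-open (EO) data (demeaned concatenation), and a
single common LCMV filter set is built and applied to both conditions:
with leadfield `L_v` (channels × 3) and regularized covariance
`C' = C + λ·(tr C / n)·I`,

    W_v = (L_v' C'^-1 L_v)^-1 L_v' C'^-1        (3 × channels)

which satisfies the unit-gain constraint `W_v L_v = I₃` exactly when
λ = 0. The three-orientation filter is reduced to a scalar filter along
the dominant orientation — the leading eigenvector of the voxel's 3 × 3
source covariance `W_v C' W_v'` — which is the standard scalar-beamformer
choice and yields the single power value per voxel the maps require.
Defaults: λ = 0.05 (keeps desk-scale covariances invertible), one
covariance and filter set per band (the per-band reading of the
protocol; a single broadband covariance is also defensible and can be
had by passing one band).

The forward model is an analytic three-shell concentric-sphere volume
conductor (brain/skull/scalp, conductivities 0.33/0.0042/0.33 S/m, radii
80/85/92 mm) rather than a BEM mesh: it is closed-form, needs no MRI,
and its Legendre-series solution is verified in the tests against the
exact infinite-medium dipole potential and the analytic
homogeneous-sphere harmonic gains. Sources sit on a regular lattice
offset by half a spacing (so no voxel coincides with the sphere center),
with face-neighbour (6-connected) adjacency — the most conservative
standard choice for cluster formation. The desk-scale default spacing is
20 mm; the protocol's 5 mm grid is reachable by configuration at
proportionally higher cost.

### Spectral power maps

Per voxel and band, power is estimated by a Hann-tapered FFT on
non-overlapping 2 s windows (0.5 Hz resolution — the coarsest that still
resolves the 2 Hz delta edge), averaging squared magnitudes over windows
and over the bins inside `[f_lo, f_hi)`. A "multi-taper with a Hanning
taper" is a contradiction in terms; the implementation follows the named
taper (a single Hann window per segment). Relative power divides each
band by the seven-band sum (so fractions sum to one per voxel), and each
band map is z-scored across voxels (mean 0, SD 1) to make maps
comparable between subjects and bands. Outlier subjects are excluded on
global power — the mean absolute band power over voxels and bands —
using a one-sided upper 95% bound (mean + 1.96 SD across subjects):
excess global power is the artifact signature of interest; a two-sided
option exists. EC is the default analysis condition (configurable); the
protocol leaves the analyzed condition unstated.

### Group statistics

*Cluster-based Monte-Carlo permutation test.* Voxel-wise two-sample
pooled-variance t maps (A− minus A+, so a theta increase in A+ appears
as a negative cluster), thresholded at the two-tailed critical t at
cluster-alpha = 0.05 with n−2 degrees of freedom. Suprathreshold voxels
form sign-consistent 6-connected clusters scored by their summed t. The
null distribution collects, per label permutation, the maximum |sum t|
over that permutation's clusters, pooling both signs — the max-statistic
construction that controls the two-tailed family-wise error rate
regardless of voxel count. p-values use the +1-corrected Monte-Carlo
estimator, so they are never exactly zero and are valid at any
permutation count. Defaults: 5000 permutations, alpha 0.05. Because the
maps are relative power z-scored across voxels, a genuine focal
increase necessarily produces compensatory clusters of the opposite
contrast elsewhere (the normalization is sum- and scale-constrained);
the downstream dose-response analyses therefore operate on the most
significant cluster of the effect's expected sign — negative, i.e.
ampler power in A+ — rather than the most significant cluster overall.

*Bootstrap equalization.* With 230 A− versus 88 A+ the groups are
unbalanced and have unequal variances; following the subsample-
equalization idea, the larger group is repeatedly (100×) subsampled
without replacement down to the smaller group's size, the cluster test
is re-run, and the proportion of repeats reproducing a significant
cluster of the same sign overlapping the target region (≥ 1 voxel by
default; the overlap fraction is configurable) estimates the
reliability of the effect. Each repeat uses an independently derived
seed from one master seed, so runs are reproducible yet repeats are
independent. Unequal variance is handled solely by this wrapper, as in
the protocol; Welch t is available as an option but not used by it.

*SUVr vincentiles.* SUVr values are rank-partitioned into 7 equal-count
quantile bins (sizes differing by at most one; 272 subjects give bins of
38–39), and cluster-mean power is submitted to a between-subjects ANOVA
over the 7 bins with Bonferroni-corrected (×21) pairwise t tests.

*Cognition and genotype.* Cluster-mean power is regressed on the memory
score (FCSRT total recall), overall and within each amyloid group, and
modelled by a general linear model with amyloid status, APOE ε4 status,
their interaction, and sex and age as covariates (Type-II F tests).

## The synthetic cohort generator

The generator emulates the cohort's recording protocol — 250 Hz sampling,
two runs of 30 s EC + 30 s EO, a configurable scalp montage (default 32
channels; the real cohort's 256-channel net is out of desk scope) plus
two synthetic EOG channels — and its statistical structure. The source
amplitudes were calibrated once against physiological targets — a
moderate mid-frontal theta fraction, a dominant-but-not-saturating
posterior EC alpha fraction, and a visible EC alpha peak in the sensor
spectrum (the last is asserted by the tests):

- **Shared anatomy.** Source positions and dipole orientations are drawn
  once from a dedicated anatomy stream (`anatomy_seed`) and reused for
  every subject: the emulated cohort lives in one normalized anatomical
  space, where cortical geometry — hence each source's projection to the
  sensors — is common to all subjects, and only the activity time courses
  are individual. Per-subject random orientations would add
  between-subject variance with no counterpart in the emulated protocol.
- **Background activity** at every grid voxel: independent band-limited
  Gaussian noise in each of the seven bands with 1/f power weighting and
  a fixed dipole orientation per voxel. Band-limited noise rather
  than sinusoids matches the variance structure resting-state statistics
  assume. Distributed background is what keeps the across-voxel z-scores
  meaningful: early calibrations with only a few focal sources produced
  relative-power compositions (e.g. >0.9 posterior alpha fraction) far
  outside the physiological range and let a planted focal effect inflate
  its own map's standard deviation, normalizing itself away.
- **Posterior alpha** (8–13 Hz) sources at all posterior-ROI voxels,
  stronger in EC than EO (amplitudes 2.5 vs 1.25 in background units),
  strong enough that the EC sensor spectrum shows the physiological
  posterior alpha peak above the 1/f background.
- **Mid-frontal theta** sources at all mid-frontal-ROI voxels with
  amplitude `baseline × (1 + effect_size × max(0, SUVr − 0.79))`,
  baseline 0.7 — the planted dose–response: flat below the positivity
  threshold, linear above it.
- **Blinks**: Poisson arrivals (0.15/s) of a stereotyped biphasic
  transient projected from a fixed anterior-inferior dipole, carried at
  high gain by the two EOG channels.
- **Aberrant channels**: a configured number of scalp channels replaced
  by 50× high-variance noise.
- **Metadata**: SUVr from two truncated Gaussians split exactly at 0.79
  (N(0.70, 0.06) below, N(0.92, 0.10) above), so requested group counts
  are reproduced exactly and the quantile analysis sees continuous
  spread on both sides of the threshold; APOE ε4 carriage at the
  group-specific cohort rates (25/230 in A−, 33/88 in A+); 58% female;
  age truncated-normal 76.1 ± 3.5 within 70–85; FCSRT total recall
  ≥ 41 (the cohort's inclusion floor), independent of SUVr — the
  generator plants no power–cognition link, so the regression stage has
  a known null.

Runs are treated as independent (the protocol states no ordering or
break effects). One master seed determines everything; identical
configurations are bit-identical.

What the generator does *not* emulate: realistic electrode geometry,
volume-conduction errors from non-spherical anatomy, 1/f slope
variation, non-stationarity within blocks, muscle or line-noise
artifacts, or any tau/neurodegeneration biology. Passing tests therefore
demonstrate the correctness and calibration of the *statistical
machinery* under the planted model, not clinical validity on real
recordings.

## Numerical choices and degenerate inputs

- Forward series: 60 Legendre terms (sources stay ≥ half a grid spacing
  below the inner shell, where the series converges rapidly); solved per
  harmonic by a 5 × 5 boundary-value system instead of a closed-form
  attenuation factor.
- A z-scored metric with zero spread across channels is defined as all
  zeros (no channel is "extreme" on a flat metric).
- Zero pooled variance at a voxel gives t = 0 with a warning.
- `(L' C'^-1 L)` singular at a voxel raises an error naming the voxel
  and suggesting a larger λ.
- Ties in vincentization keep original order (stable rank); bins are cut
  at `round(seq(0, n, length.out = k + 1))`.
- EDF output quantizes to 16 bits over a per-channel symmetric physical
  range; the round-trip error is bounded by half a digital step,
  (2 × range)/65535/2, which the tests assert exactly.

## Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen so
the full suite and script complete on one CPU: 16–32 channel montages,
20–24 mm grids (≈ 150–250 voxels), 10 × 10 × 10 map lattices for the
statistical calibrations, 200–1000 permutations and 20–100 bootstrap
repeats depending on the check, and demo cohorts of 12–40 subjects for
the end-to-end runs (map-level cohorts of 318 for the unbalanced
reliability checks). The end-to-end demo plants a deliberately
supra-threshold dose (effect_size 5): an effect sized for detection at
the cohort's n = 318 cannot be expected to reach significance at a
40-subject demo, so the demo validates recovery of a clearly present
effect rather than statistical power. The statistical calibrations (type-I error,
planted-effect recovery, reliability) are Monte-Carlo estimates and are
reported with their simulation sizes.

## The end-to-end monotone-trend check

The planted dose–response is *thresholded*: below SUVr 0.79 every
subject has the same expected theta power, so the sample means of
quantile bins that lie entirely below the threshold are exchangeable,
and demanding a strictly non-decreasing sequence of bin means would fail
with probability ≈ 1 − 1/m! for m sub-threshold bins even when the
pipeline is perfect. The package therefore defines the quantile-trend
check to match the planted model: no adjacent bin-mean decrease larger
than 3 standard errors of that difference, together with a clearly
positive bin-7 minus bin-1 contrast. This is the appropriate
monotonicity statement for a flat-then-increasing dose–response
observed with sampling noise.

## Known limitations

- The spherical forward model cannot represent individual anatomy; with
  user-supplied leadfields the pipeline runs unchanged.
- The scalar-beamformer orientation choice discards genuinely
  multi-orientation sources.
- Desk-scale grids (20 mm) blur focal effects across few voxels; cluster
  sizes are not comparable to 5 mm-grid results.
- The ICA step assumes ocular artifacts are the dominant non-Gaussian
  component; muscle artifacts would need additional criteria.
- M0/M24 visits are carried as labels; no longitudinal (paired)
  statistics are implemented, matching the cross-sectional protocol.
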