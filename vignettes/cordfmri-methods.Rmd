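---
title: "Methods: phantom-based validation of spinal cord fMRI localization statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phantom-based validation of spinal cord fMRI localization statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Task fMRI of the cervical spinal cord asks *where* in the cord a sensory
stimulus evokes activity: left or right hemicord, dorsal or ventral
hemicord, which rostrocaudal segment (C5-C7), and gray versus white
matter.  The measurement is difficult - the cord is a centimeter wide,
the cardiac and respiratory cycles contaminate the signal heavily, and
at a 2 s TR the ~1 Hz cardiac cycle aliases into slow drifts that mimic
task responses.  This package implements the complete analysis chain for
a block-design tactile paradigm together with a synthetic phantom whose
activation is known exactly, so every statistic in the chain can be
validated by parameter recovery rather than by eyeballing maps.

## The phantom

`cord_phantom_spec()` / `build_atlas()` rasterize an idealized cord: an
elliptical cylinder (default semi-axes 4 x 3 mm) on a 24 x 24 x 48 grid
of 1 x 1 x 3 mm voxels, with gray matter as a concentric inner ellipse,
a CSF ring around the cord, and hard z-intervals for the C5/C6/C7
segments (C5 most superior; z increases superiorly).  The hemicord,
segment and tissue masks are exact set partitions of the cord by
construction, which the count statistics assert at run time.  The real
template this stands in for is a 0.5 mm isotropic atlas with a
butterfly-shaped gray matter; the concentric approximation is
deliberate - every downstream statistic depends only on voxel counts per
compartment, not on the GM shape - and the grid is coarse so a whole
24-subject cohort analyzes in minutes on one CPU.  The WM:GM volume
ratio of the default geometry is 3.5, satisfying the anatomical
constraint that white matter exceeds three times the gray matter volume
(the default `gm_fraction = 0.2` keeps that true after rasterization;
geometries that violate it are refused).

`ground_truth()` places the activation: compact in-plane foci built from
the voxels nearest the cord center within each hemicord quadrant, with
per-quadrant budgets chosen so the left-responding region has a target
LR index (default +0.3) and the right-responding region its mirror.  A
coherent focus, rather than scattered voxels, matches what real
activation looks like and is essential for the smoothing stage not to
destroy the injected amplitude.  The region spans a z window (default
half-width 8 slices) centered mid-C6, jittered across subjects.

`simulate_run()` builds
`data = baseline * (1 + task + physio + drift) + white noise + spikes`:

* **task** - the per-side sum of HRF-convolved trial boxcars, normalized
  to unit peak and scaled by the amplitude (default 0.71% of baseline,
  the reported group-average percent signal change for this paradigm);
* **physio** - cosines of the slicewise cardiac and respiratory phases
  (the same phase model the denoiser uses, with a fixed random phase
  offset per voxel), amplitude tripled in the CSF ring where pulsatile
  flow dominates; defaults 0.4% cardiac, 0.3% respiratory;
* **drift** - a per-voxel random linear trend (up to +/-0.5%) plus a slow
  common cosine;
* **white noise** - SD 3 intensity units against a baseline of 100
  (WM 100, GM 105, CSF 120);
* **spikes** - whole-volume offsets of 3% on a few volumes, mimicking
  bulk motion for the DVARS detector.

Noise amplitudes are not reported quantities for this paradigm, so they
are set once by calibration: with the defaults, the subject-level
pipeline at a 0.71% injection yields an active-voxel mean Z of about
3.75, the published operating point.  On this coarse grid the raw-TSNR
anchor (about 24 before smoothing) and the activation-Z anchor cannot
both hold - slice-timing interpolation and the scaled-down geometry
change the variance bookkeeping - and the activation statistics were
preferred because every spatial measure under validation derives from
the thresholded maps.  The phantom's TSNR lands in the 40s before
smoothing.  What the phantom deliberately omits: susceptibility
artifacts, nonrigid respiratory displacement of the cord, k-space
physics, and spatially correlated thermal noise.  Passing recovery tests
therefore demonstrates that the *statistics* are implemented correctly
and the pipeline is unbiased under the modeled noise - not that the
pipeline conquers every artifact of real cord data.

Determinism: every stochastic element flows from one integer seed
through a private RNG stream, so identical spec + seed reproduces
bit-identical arrays without disturbing the caller's RNG.

## Protocol and design

The stimulation protocol is 20 trials of rest / left / right blocks of
15 s each (900 s, 450 volumes at TR 2 s), with the left-right order
pseudorandomized per trial, balanced to within one trial and capped at
three identical consecutive orders.  The HRF is a gamma density with
mean lag 6 s and SD 3 s (hence shape 4, scale 1.5 s; mode at 4.5 s),
sampled at 0.1 s and scaled to unit peak so percent signal change stays
interpretable.  The design matrix is trialwise: one EV per trial per
side (boxcar convolved on the fine grid, decimated at volume midpoints),
the temporal derivative of every task column, six rigid motion
parameters, and one-hot columns for DVARS-flagged volumes - 86 columns
plus flagged volumes for the default protocol.  Trialwise EV sums are
exactly the union-boxcar convolution (linearity), which the tests assert
against an independent convolution.

## Denoising

* **Phases** - cardiac phase is linear time within the current cardiac
  cycle; respiratory phase is the histogram-equalized amplitude
  transform signed by the amplitude derivative, wrapped to [0, 2*pi).
  Both are assigned at each slice's acquisition time (interleaved
  acquisition).
* **RETROICOR basis** - sines and cosines of the first four harmonics of
  each phase (16 columns per slice) plus sum/difference interaction
  terms sin/cos(k*phi_c +/- phi_r), k = 1..4 (16 more).  The
  multiplicative-product form of the interactions is available as a
  configuration switch; the sum/difference form is the default because
  it totals exactly the published 16 columns.
* **CSF regressors** - the first five principal components of the canal
  voxel time series, slice by slice, mean-centered and unit-normed.
* **High-pass** - projection onto a discrete-cosine basis with cutoff
  100 s, mean re-added, applied identically to data, nuisance columns
  and the task design (a model filtered differently from its data biases
  amplitudes; only outlier one-hot columns stay unfiltered so flagged
  volumes are removed exactly).  Correctness is defined by
  transfer-function bounds (>= 90% retention at 50 s period, >= 90%
  attenuation at 400 s), not bit-compatibility with any particular
  tool's running-line filter.
* **Nuisance regression** - voxelwise least squares against the slice's
  own nuisance block, residual plus voxel mean; a rank-deficient block
  falls back to a pseudo-inverse with a warning.  Regression precedes
  the GLM (both orders are defensible; regressing first follows the
  published order, and the alternative of including the block in the
  GLM is possible by passing it to `build_design`).
* **Slice timing** - linear interpolation to the volume midpoint,
  applied after nuisance regression, as the published order prescribes.
* **DVARS** - RMS over the cord of the volume-to-volume difference;
  volumes above the box-plot cutoff (Q3 + 1.5 IQR) are flagged.  A spike
  perturbs two consecutive differences, so both adjacent volumes flag.
  Flags are invariant under global intensity scaling and offsets.
* **Smoothing** - masked, mask-normalized Gaussian (2 mm FWHM) inside
  the cord, replacing an intensity-adaptive edge-preserving filter: the
  downstream statistics depend only on suprathreshold topology, and the
  masked kernel already prevents dilution across the cord boundary.

## GLM and inference

`cord_glm()` fits the trialwise design voxelwise with one
Cochrane-Orcutt iteration of AR(1) prewhitening: OLS, lag-1 residual
autocorrelation per voxel, whitening of data and design, refit.  AR
coefficients are quantized to 0.01 so whitened designs are factored once
per bin; correctness is pinned by a brute-force generalized
least-squares oracle (tridiagonal AR(1) inverse covariance) on small
instances, to 1e-8.  Contrasts are the mean of the 20 trial EVs per side
and their differences; Z maps come from t statistics through tail
probabilities at the residual degrees of freedom.  Subject-level maps
threshold at uncorrected Z > 2.3.  Fixed-effects combination (trials
into sets, subjects into the group) is the inverse-variance estimator.
Group maps apply cluster-extent correction: 26-connected suprathreshold
clusters are kept when their extent's add-one Monte-Carlo p against the
maximum-extent distribution of smoothness-matched Gaussian null fields
falls below 0.05.  The null simulation refuses fewer than 100 draws; the
familywise error of the whole procedure calibrates to 0.05 within
binomial error in the test suite.  The group model is fixed effects throughout - the standard
fallback when between-subject variance estimates are too unstable for a
mixed-effects model at this sample size - so group maps describe the
study sample, not the population; a sign-flip permutation test would be
the principled population-level alternative and is left as future work.

## Percent signal change and recovery

`percent_signal_change()` converts a cope to percent units as
`100 * cope * peak / baseline`, with `peak` the maximum of the summed
side EV - the height, in regressor units, of a full-amplitude response.
On a noise-free run fitted directly, the injected amplitude round-trips
exactly.  Through the full pipeline, two deterministic attenuations
intervene: masked smoothing spreads boundary-voxel signal outside the
true region (about 20% averaged over a default-size focus), and the
temporal chain (high-pass, nuisance-basis absorption of the aliased
cardiac waveform, slice-timing interpolation, prewhitening) retains
about 88-90% of the waveform.  Phantom validation therefore uses the
recovery-coefficient approach standard in emission-tomography phantom
work: `recovered_amplitude()` fits the PSC map against the expected
response shape - the truth indicator passed through the same smoothing
operator, scaled by a temporal retention factor - by least squares.
`temporal_retention()` measures that factor from a few reference runs
injected at 5% amplitude (every task-path operation is linear in
amplitude, so the factor transfers; at 5% the noise contributes
negligibly to the estimate).  With this estimator the default 24-subject
cohort recovers the injected 0.71% to within +/-0.01.

## Spatial and temporal statistics

Counts per compartment enforce the partition identities; LR and DV
indices are (difference)/(sum) over opposing hemicords, +1 meaning all
voxels left (resp. dorsal); subjects with no active voxels return NA and
drop out of group tests pairwise.  The superior-inferior center of
gravity is Z-weighted by default ("weighted" is how the published figure
describes it; the unweighted centroid is a switch because the methods
text is silent).  The GM/WM ratio divides activation percentages, not
raw counts, to undo the threefold volume difference; ratios are reported
at two decimals, full precision retained.  Consistency maps count
subjects active per voxel.  The Wilcoxon signed-rank test is implemented
directly because the published tables report its Z statistic: exact
enumeration of all sign patterns (with observed midranks) for n <= 12,
tie- and continuity-corrected normal approximation otherwise; the two
paths agree within 0.02 on random data and the implementation matches
the standard library test to 1e-10 in both regimes.  Habituation is
assessed by splitting the 20 trials into five consecutive sets of four,
combining each set by fixed effects, re-thresholding (re-thresholding
per set, rather than subdividing the full-run mask, is the default; the
source is silent), and testing the per-subject linear contrast
(-2,-1,0,1,2) against zero with a one-sample t - the linear contrast of
a one-way repeated-measures ANOVA, whose full table is attached.  Its
type-I error calibrates to 0.05 over 500 stationary cohorts.

## Numerical choices and edge cases

Fine-grid convolution at dt = 0.1 s with the kernel truncated at 32 s
(the gamma tail beyond is < 1e-4 of peak); FFT convolution residue below
1e-10 zeroed so EVs have compact support.  The x grid dimension defaults
to even so no voxel straddles the midline; on odd grids the midline
plane is excluded from the cord so hemicord partitions stay exact (a
documented deviation; the source does not discuss midline voxels).  AR
coefficients clamp to +/-0.95; designs are rejected if rank-deficient
with the offending columns named; zero-variance inputs to fixed effects
error; empty active masks propagate NA sentinels with messages rather
than crashing group summaries.  Problem sizes in the tests: unit tests
run on a 16 x 16 x 12 phantom with 2-trial protocols; the acceptance
suite runs the full 24 x 24 x 48 grid, 450 volumes, 24 subjects, 999
cluster-null simulations - about seven minutes total on one CPU, chosen
so a cohort-scale validation stays routine.

## Interfaces

All volumes read and write NIfTI-1 (via RNifti); physiological traces
are two-column TSV with a JSON sidecar; protocols, ground truth, QC
reports and the cohort manifest are JSON; design and nuisance matrices
and all summary tables are TSV.  The package is a library: `run_subject()`
and `run_group()` orchestrate the pipeline from R, and
`scripts/acceptance.R` is the reproducible entry point for the headline
checks.
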