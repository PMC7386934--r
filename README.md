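# cordfmri

Spinal cord fMRI analysis with a ground-truth phantom: trialwise
prewhitened GLM, physiological denoising, and the spatial localization
statistics used to quantify where in the cervical cord a tactile
stimulus evokes activity.

## Who this is for

Block-design spinal cord BOLD studies ask whether activity lateralizes
to the hemicord ipsilateral to a stimulus, whether it sits dorsally or
ventrally, which segment (C5-C7) it occupies, and whether it prefers
gray matter.  The statistics that answer those questions — hemicord and
segment voxel counts, laterality indices, the superior-inferior center
of gravity, GM/WM activation ratios, consistency maps, habituation
trends — are simple, but they sit downstream of a long pipeline
(RETROICOR-style physiological regression, CSF principal components,
DVARS outlier removal, high-pass filtering, smoothing, a prewhitened
trialwise GLM, cluster correction), and errors anywhere in the chain
bias them silently.  `cordfmri` implements the whole chain **and** a
synthetic spinal-cord phantom with known activation, so the chain is
validated end to end by parameter recovery.

## The core statistics

For a thresholded activation map with voxel counts per compartment, the
laterality indices are

    LR = (left − right) / (left + right)
    DV = (dorsal − ventral) / (dorsal + ventral)

(+1 = all active voxels left / dorsal, −1 = all right / ventral).  The
superior-inferior center of gravity is the Z-weighted mean voxel-z of
the active voxels, Σ z_i Z_i / Σ Z_i (greater = more superior), and the
gray/white specificity is the ratio of activation *percentages*,
(GM_active/GM_total)/(WM_active/WM_total), which corrects for white
matter's more than threefold larger volume.  Group inference on the
indices uses exact/corrected Wilcoxon signed-rank tests; habituation is
the linear contrast (−2,−1,0,1,2) across five sets of four consecutive
trials.

The voxelwise model is a trialwise GLM — one gamma-HRF-convolved EV per
15 s stimulation block (mean lag 6 s, SD 3 s), temporal derivatives,
motion and outlier covariates — fitted with AR(1) prewhitening
(Cochrane–Orcutt), contrasted (L, R, L>R, R>L), and combined across
trials and subjects by inverse-variance fixed effects.  Group maps are
cluster-corrected by Monte-Carlo simulation of smoothness-matched
Gaussian null fields (26-connectivity, p < 0.05 on maximum cluster
extent).

## Worked example

Simulate one subject at the study's conditions (450 volumes, TR 2 s, 20
trials, 0.71% left-lateralized activation over C6, realistic cardiac /
respiratory / drift / spike noise) and analyze it:

```r
library(cordfmri)

atlas    <- build_atlas()                      # 24 x 24 x 48 phantom cord
protocol <- generate_protocol(seed = 1)        # (rLR | rRL) x 20, 450 vols
truth    <- ground_truth(atlas, amplitude = 0.71, lr_index = 0.3)
run      <- simulate_run(atlas, protocol, truth, seed = 42)
bundle   <- run_subject(run, atlas, subject = "sub-01")
print(bundle)
```

```
Subject bundle sub-01: 4 contrasts, 92 design columns, dof 357
  TSNR 45.2 (pre-smoothing) / 114.7 (post); 6 DVARS outlier(s)
    subject contrast total   lr_index     dv_index    cog_z gmwm_ratio   mean_z
L    sub-01        L   335  0.2298507  0.008955224 23.76813  2.2195122 3.578456
R    sub-01        R   322 -0.2173913  0.031055901 24.68077  2.1069652 3.653398
L>R  sub-01      L>R   112  0.5178571 -0.196428571 21.43492  0.5412371 2.899498
R>L  sub-01      R>L    98 -0.6122449 -0.061224490 23.83317  0.5833333 2.850346
```

The left-sided stimulation map (`L`) has LR index +0.23 against a
ground-truth +0.33: activity lateralizes to the ipsilateral hemicord
(somewhat diluted by smoothing spillover across the midline), recovered
from data in which the injected signal is ~0.7% of baseline under
cardiac noise aliased to near-DC.  The lateralization contrasts (`L>R`,
`R>L`) lateralize more strongly (+0.52 / −0.61), the DV indices hover
near 0 (the truth is dorsoventrally balanced), the centers of gravity
sit near the injected mid-C6 slice (z ≈ 24), the single-side maps favor
gray matter (ratios > 2: the injected focus is central, where the GM
compartment lies), and the inserted spike volumes are among the flagged
DVARS outliers, entering the design as one-hot covariates.  `run_group()` aggregates bundles into the group
fixed-effects maps, the per-contrast index statistics (median, IQR,
Wilcoxon Z and p), GM/WM tables, consistency maps and the habituation
trend report; `generate_cohort()` + `run_cohort()` produce the bundles.

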