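Package: cordfmri
Title: Spinal Cord fMRI Phantom Simulation, Denoising, and Spatial
    Localization Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for block-design spinal cord BOLD fMRI analysis on a
    template-space voxel grid: a synthetic spinal-cord phantom with known
    activation ground truth and realistic cardiac, respiratory, drift and
    spike noise; RETROICOR-style physiological noise regressors, slicewise
    CSF principal components, DVARS outlier detection, high-pass filtering
    and masked Gaussian smoothing; a trialwise voxelwise general linear
    model with AR(1) prewhitening, contrast Z maps, fixed-effects
    combination and Monte-Carlo cluster-extent correction; and the spatial
    localization statistics used in spinal cord somatotopy studies -
    hemicord and segment voxel counts, left-right and dorsal-ventral
    laterality indices, superior-inferior center of gravity, gray/white
    matter activation ratios, across-subject consistency maps, and
    habituation trend tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
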