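Package: atrophynet
Title: Adversarial Simulation of Longitudinal Brain MRI with Monotone Atrophy Constraints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Slice-wise conditional adversarial autoencoders for simulating
    subject-specific longitudinal structural brain MRI in ageing and dementia.
    A per-slice encoder/generator pair, conditioned on an age bin and a
    diagnosis code, is trained jointly with two discriminators and with
    biologically motivated losses that enforce monotonically non-increasing
    tissue intensity at voxel and regional scales; regional decline rates are
    supplied by pre-fitted sigmoid-link regressors. Training stability across
    slices is obtained through shared initialisation, mean-reverting
    per-loss weight schedules, and Gaussian cross-slice smoothing, with an
    optional same-grid 3D restoration network recovering detail lost to
    smoothing. Includes a synthetic longitudinal brain-phantom generator with
    known diagnosis-dependent atrophy trajectories, personalisation by
    transfer learning from a single baseline scan, age-interpolated 4D
    sequence synthesis, and a volumetric-error evaluation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    EBImage,
    yaml,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
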