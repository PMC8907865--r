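---
title: "Methods: adversarial simulation of longitudinal brain MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: adversarial simulation of longitudinal brain MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`atrophynet` simulates subject-specific longitudinal T1-like brain MRI from
a single baseline scan, an acquisition age and a diagnosis code. This
vignette is the package's account of the method: the model and its
assumptions, the parameters that matter, what the synthetic phantoms do and
do not emulate, and the numerical and design choices made where the design
was genuinely open.

## The progression model

Volumes are modelled slice-wise: for each of the T central axial slices an
independent model is trained, consisting of four networks. An encoder E
maps the normalized slice to a latent code z (tanh output, so codes live in
[-1,1]^latent, the support of the uniform prior). A generator G decodes
(z, one-hot age bin, one-hot diagnosis) back to a slice in [0,1]. An image
discriminator Db scores slice realism on overlapping patches, and a latent
discriminator Dz scores codes against the uniform prior — pushing encoded
codes toward the prior is what makes the latent space, and hence the
generated progression, smooth across ages.

Ages are discretized into A equal-width bins over the observed range. The
bin centre m_i is the mean age of the scans falling in the bin, its spread
delta_i the maximum age difference inside the bin, and the fuzzy Gaussian
membership mu_i(theta) = exp(-(theta - m_i)^2 / (2 sigma_i^2)) with
sigma_i = c * delta_i weights the reconstruction loss: the generated
sequence must resemble the input most strongly at bins near the scan's true
age. Binning (rather than conditioning on scalar age) prevents the encoder
from memorizing age as an identity feature. Only proportionality of
sigma_i to delta_i is inherent to the scheme; the constant c is exposed
(`width_factor`, default 1).

The core biological assumption is monotone atrophy: normalized tissue
intensity, a proxy for tissue density, does not increase with age. It is
enforced at two scales:

- voxel scale: the output at the input's own bin a must lie between the
  element-wise minimum of earlier outputs and the element-wise maximum of
  later ones (at the sequence ends the missing term, and the 1/2 factor,
  are dropped);
- regional scale: for fixed, overlapping region masks r_{n,q}, the ratio of
  summed generated intensity between two bins must match the ratio
  predicted by a pre-fitted regional regressor LR_{n,q}(o, a, d). Residuals
  are weighted by region size s_{n,q} — large regions are measured more
  reliably — and averaged over regions and time pairs. A guard eps = 0.1 is
  added to numerator and denominator sums, identically at regressor-fitting
  and loss-evaluation time.

Region masks come from an atlas: every label contributes its base mask plus
one eroded and one dilated variant per configured radius (empty variants
are dropped). The deliberate overlap acts as jitter on region boundaries
and makes the regional loss robust to small misalignments.

## Regional regressors

The regressors predict a bounded ratio in (0,1], so they are sigmoid-link
regressions, not classifiers: ratio = plogis(beta0 + beta1*o +
beta2*(a - o) + beta3*d), fitted by least squares on the logit of observed
ratios (clipped to [1e-4, 1 - 1e-4]) over all ordered scan pairs of each
training subject. Pairs whose regional intensity increased are removed
first — under the monotone-atrophy assumption they are outliers. The
zero-gap constraint predict(o, o, d) = 1 is enforced exactly in prediction
(a == o returns 1) rather than in the linear predictor, where a finite
sigmoid cannot reach 1; with fewer than 4 filtered samples the regressor
falls back to the identity predictor and carries a warning flag. The
functional form is the package's own choice — a bounded, saturating link
matched to a bounded, monotone target; the parameter-recovery tests (mean
absolute error below 0.02 against the phantom's generative ratios on a
noiseless 200-subject cohort) are what justify it.

## Loss schedule (profile weight functions)

Training five partially conflicting losses jointly is unstable, and
per-slice instabilities become 3D artefacts. Each loss weight therefore
follows a mean-reverting exponential schedule

    f(t) = rho^t * b + (1 - rho^t) * b * v^d,    d in {-1, +1},

which starts at the shape parameter b at epoch 0 and converges to the
asymptote b * v^d; v (default 10) fixes the ratio of final to initial
weight, rho (default 0.99) the convergence speed. With the default best
parameters (b_reg = b_vox = 1.25, b_b = 0.002, b_z = 0.05, b_rec = 100;
d_rec = -1, all others +1) training starts dominated by reconstruction and
hands over to the biological and adversarial terms — learn to copy first,
then learn to progress. The shape/direction parameters are selected by
seeded random search over a grid (`pwf_default_grid()`, ranges chosen so
each weight times its typical loss magnitude is order 1), scored by the
total loss of a short training run on a held-out validation fraction
(`pwf_validation_eval()`).

3D coherence across the independently trained slice models rests on three
mechanisms: a common initialization (a model pre-trained for
`common_init_iters` = 100 mini-batch iterations on central slices, from
which every slice model starts), the shared schedules, and Gaussian
cross-slice smoothing of the generated slices (sigma = 1.5 slice units over
the +-2 nearest neighbours, weights renormalized at the stack boundary).
Smoothing is applied to generated outputs at inference; that is the
testable reading of smoothing "slice-wise models", and it is what the
restoration stage consumes.

## Restoration ("super-resolution") and personalization

Smoothing buys coherence at the cost of detail. A small densely connected
3D convolutional network with a zero-initialized residual head (identity
map before training) learns to undo that loss on the same voxel grid — no
upsampling is involved. Its training pairs are self-generated: the target
is the preprocessed input volume, the input is the progression model's own
reconstruction of that volume at its own age bin, smoothing included. It is
trained separately (patch-based, voxel MSE, Adam) and never updated again.

At inference the model is personalized: all four networks of every slice
model are fine-tuned for `personalize_iters` = 50 iterations on the single
baseline scan, with all losses active and the weights at their final-epoch
schedule values (the schedule's fixed point is the natural choice for
post-convergence fine-tuning; the alternative of restarting the schedule
would undo the hand-over). The restoration network is frozen. The full
sequence is then generated, smoothed, restored, and mapped back to the
input's intensity scale by inverting the recorded per-slice normalization;
intermediate ages are weighted linear interpolations of the two nearest
generated time points, with extrapolation outside the bin-centre range an
error. The input's age bin is the bin whose interval contains theta, ties
to the lower bin; diagnosis is held fixed along the sequence.

## The phantom generator

The synthetic cohorts emulate the statistical skeleton of a large
ageing/dementia MRI study: ages 63–87 years; diagnosis mix 28/4/54/14%
across CN/SMC/MCI/AD codes 0–3; 4–5 visits about 0.75 years apart (roughly
4.7 scans spanning three years); 95 axial slices of 128x128 voxels at full
scale. Each subject's brain is an ellipsoidal tissue region tiled per slice
into `n_regions_per_slice` contiguous grid sectors with per-region base
intensities drawn from a seeded uniform range; regional mean intensity
declines logistically in age, g(theta) = 1 - kappa_d / (1 +
exp(-(theta - tau)/s)), with maximal decline kappa non-decreasing in
diagnosis severity (defaults 0.05/0.08/0.15/0.30, inflection tau = 75 y,
slope s = 5 y), plus optional additive Gaussian noise. The logistic form
makes regressor parameter recovery a meaningful test, and the grid atlas
keeps regions addressable without distributing an anatomical atlas.

One geometric feature is load-bearing: a bright, non-declining rim
(intensity 1) surrounds the tissue ellipse. Slice-wise standardisation
followed by min-max rescaling — the package's normalization, which removes
scanner gain and offset — maps each slice affinely onto [0,1] using its own
extremes. If *all* foreground declined uniformly, that normalization would
divide the decline out entirely and no regional signal would survive
preprocessing. The rim pins the slice maximum (as non-degenerating bright
structures do in real T1 slices), so regional intensity ratios measured on
normalized slices equal the generative ratios up to noise and the eps
guard.

What the phantoms deliberately do not emulate: anatomy, cortical topology,
bias fields, scanner and site effects, registration error, skull, motion,
or tissue deformation (intensity declines in place; volumes do not deform).
Passing tests therefore demonstrate that the machinery — losses, schedules,
regressors, training loop, restoration, personalization, evaluation — is
implemented correctly and recovers known ground truth, not that the model
produces radiologically plausible human MRI; that claim would need real
cohorts and segmentation tooling outside this package's scope.

## Numerical choices

- The L2 image distance is the mean squared error over pixels, keeping loss
  weights comparable across image sizes.
- In the reconstruction loss the membership weights the *error term*
  mu_i * MSE(X, G_i), not the image: scaling the image by mu_i would
  corrupt intensities rather than express "nearer ages matter more".
- The adversarial objectives are the standard non-saturating binary
  cross-entropy pair (discriminator: real -> 1, fake -> 0; generator/
  encoder: fake -> 1); probabilities are clamped to [1e-7, 1 - 1e-7]
  inside the logs. The stored adversarial values are the discriminator
  cross-entropies entering the weighted total.
- Min/max in the voxel loss are element-wise across the sequence
  prefix/suffix; their subgradients route residuals to the first
  element-wise argmin/argmax on ties.
- The conv/backprop core expresses every convolution through a precomputed
  sparse gather operator, so the transpose convolution is the exact adjoint
  of its matching convolution; all gradients are verified against finite
  differences in the test suite.
- Optimisation is Adam (alpha = 2e-4, beta1 = 0.5) with global
  gradient-norm clipping at 10 as an engineering safety; a non-finite total
  loss aborts training with the last finite-loss weights retained in the
  error condition.
- Per-batch update order: Db step, Dz step, then one joint E+G step on the
  weighted total. The order is a package choice; discriminators see the
  current generator before it moves.
- Determinism: every stage seeds R's Mersenne-Twister explicitly; a single
  global seed fans out to per-stage seeds via a stable derivation
  (`derive_seed`), so any slice model or stage reproduces in isolation.

## Desk-scale configurations

The defaults are the full-scale configuration (T = 95 slices of 128x128,
latent 200, A = 10 bins, 300 epochs, batch 100). The shipped tests and
examples run the same code at desk scale, the package's chosen validation
sizes: 16x16 slices, T = 3–6, A = 3–4, latent 8–16, 8–40 subjects, up to 30
epochs for the training-property checks and a 200-subject noiseless cohort
for regressor recovery. The toy training runs complete in about a minute on
one CPU; capacity scales with image size, so the same architecture code
builds both configurations.

## Known limitations

- Pure-R training: full-scale training (95 slices, 128x128, 300 epochs) is
  feasible in principle but slow on a single CPU; the per-slice models are
  independent given the shared initialization and can be trained
  concurrently by any scheduler.
- The regional regressors are linear in baseline age, age gap and a scalar
  diagnosis code on the logit scale; strongly nonlinear diagnosis effects
  or long extrapolation horizons will misfit.
- Diagnosis is held fixed along a simulated sequence; conversion dynamics
  are out of scope.
- Evaluation on phantoms uses atlas masks plus an intensity threshold in
  place of a segmentation pipeline; for real data, externally produced
  segmentation masks can be supplied through the same interface.
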