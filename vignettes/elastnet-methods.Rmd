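---
title: "Unsupervised displacement and strain estimation for quasi-static ultrasound elastography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unsupervised displacement and strain estimation for quasi-static ultrasound elastography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Quasi-static ultrasound elastography images tissue stiffness by applying a slow
axial compression with a hand-held probe and measuring the induced deformation.
Under roughly uniform stress, stiff tissue strains less than soft tissue, so
the axial strain map (the depth derivative of the axial displacement) acts as a
qualitative stiffness image. The computational core is speckle tracking:
estimating a dense displacement field between two frames of radio-frequency
(RF) echo data. RF data is used rather than B-mode because the phase of the
carrier (here 0.25 cycles/sample, a 5 MHz pulse sampled at 20 MHz) carries
sub-sample displacement information.

`elastnet` implements two convolutional displacement estimators trained
*without ground-truth labels*, a least-squares strain estimator, a
speckle-phantom simulator with exact closed-form ground truth, and the
elastographic evaluation metrics (NRMSE, SNRe, similarity, consistency,
landmark TRE).

## Networks

Both networks share an encoder of four down-sampling residual blocks
(conv–batch-norm–leaky-ReLU twice, a 1×1 projection on the identity path, 2×2
max-pooling after each block). The input is the pre/post-compression frame
pair stacked as two channels, each frame standardised to zero mean and unit
variance. Input dimensions must be divisible by 16 (four pooling stages).

* **USENet** (feed-forward): the decoder mirrors the encoder. Each level
  up-samples with a learned 2×2-stride-2 transpose convolution summed with a
  parameter-free bilinear-additive upsampling (2× bilinear, channel groups
  averaged or repeated), adds the symmetric encoder skip, and refines with a
  two-convolution residual unit (with batch normalisation, mirroring the
  encoder — the unnormalised variant amplifies feature magnitudes ~50× through
  the decoder and destabilises training).
* **ReUSENet** (recurrent): the decoder levels are convolutional LSTM units.
  All four gates are computed by one convolution over the input stacked with
  the previous hidden state (kernels 3×3, forget-gate bias initialised to 1);
  the cell and hidden state of every level persist across the consecutive
  frame pairs of a sequence, so the network can integrate evidence from
  intermediate frames when the accumulated compression between distant frames
  is large.

Every decoder level (bottleneck + four levels) emits a two-channel
displacement head (3×3 convolution, zero-initialised so the untrained model
predicts the identity transform). The per-level fields are resized to the
input grid and summed. A field expressed on a 1/2^k grid carries a 2^k value
scale when brought to sample units at full resolution; that scale is folded
into the head weights rather than applied explicitly, so every level's
parameters have equal leverage on the output — with the explicit scaling,
per-coordinate adaptive optimisers take equal-sized parameter steps that move
the field 16× harder through the coarsest head, which we found sufficient to
destroy training.

Reference channel widths are encoder (16, 32, 64, 128) and convLSTM hidden
(64, 64, 32, 32, 32), calibrated so the trainable parameter counts land on the
published model sizes: 813,898 (≈0.8 M) for USENet and 1,490,186 (≈1.5 M) for
ReUSENet. The `tiny` preset (encoder 4, 8, 16, 32; hidden 16, 16, 8, 8, 8) is
used for CPU-scale experiments and tests.

## Training objective

For a pair (Pre, Post) and predicted field T,

    L_total = L_sim + alpha * L_reg + beta * L_cons

* `L_sim = -LNCC(Pre, Post ∘ T)`: local normalised cross-correlation over
  sliding windows (default 15×15, stride 1, box-filtered moments), windows
  fully inside the image; windows touching an invalid warped pixel
  (clamped-out-of-bounds) or with local standard deviation below 1e-5 are
  skipped. LNCC is invariant to affine intensity changes, which matters for RF
  data whose gain varies.
* `L_reg`: the L1 norm of the strain spatial gradient, i.e. the mean absolute
  second derivatives of the axial displacement (`d²/dx²`, `d²/dy²`, and the
  mixed partial counted twice, matching the four-term form; with central first
  differences the two mixed orders coincide exactly). It vanishes on affine
  fields (constant strain). We average rather than sum over pixels so `alpha`
  transfers across image sizes.
* `L_cons = -LNCC(S_{t-1}, S_t ∘ T)`: successive strain images must depict the
  same stiffness pattern once motion-compensated. `S_t` is the least-squares
  strain of the current prediction; `S_{t-1}` is treated as a fixed target
  (gradients flow into the current step through both the warp and the strain
  estimator's adjoint; temporal credit assignment still flows through the
  convLSTM state, which is backpropagated through the whole sequence). When a
  strain map is constant — e.g. at the identity-transform start of training —
  the term has no valid NCC window and is skipped for that pair.

Weights default to `alpha = 5` and `beta = 0.2`; `beta` is zero for USENet
(no previous strain exists for an isolated pair) and for the first pair of
every sequence.

## Optimisation

Adam (batch = one training item), initial learning rate 1e-3, reduced by a
factor 0.8 when the best validation loss has not improved for 10 consecutive
epochs, stopping when the difference between consecutive learning rates falls
below 1e-8 (at most 45 reductions from 1e-3). USENet trains on random frame
pairs whose interframe interval is uniform on {1, …, N−1}; ReUSENet trains on
whole sequences with full backpropagation through time (long sequences can be
chopped into consecutive windows, 6 frames being the protocol for free-hand
acquisitions).

Two stabilisers are on by default and matter in practice:

* **Gradient-norm clipping** (global L2 norm ≤ 5). The L1 regulariser's
  subgradient has full magnitude however microscopic the field roughness is,
  so raw gradients can jump by orders of magnitude between steps.
* **Learning-rate warmup** (linear over the first 60 optimiser steps). The
  zero-initialised heads produce very small but spatially coherent first
  gradients; an adaptive optimiser would otherwise take full-size first steps
  whose leverage on the multi-scale field is enormous (we observed the first
  unwarmed Adam step moving the field by tens of samples).

A related caveat: plain fixed-step subgradient descent on the *free-form*
total objective is not monotone — from a rough iterate the negative
(sub)gradient need not be a descent direction for the L1 term. The descent
sanity test therefore optimises a coarse control-grid field with backtracking
line search, which descends monotonically.

## Strain estimation

The least-squares strain estimator (LSQSE) fits, per scan line, an ordinary
least-squares line to displacement over a centred axial window and takes the
slope, negated so compression is positive. It is linear (a banded convolution
along depth; borders use shrunken one-sided windows) and its adjoint is used
during training. The window length is not stated in the original description
of the method; the package default is 43 samples (configurable, echoed into
every run configuration), and 15 samples are used in the small-image
experiments below. A 3-sample window reproduces the central finite difference
(`gradient_strain`), which LSQSE dominates in elastographic SNR on noisy
fields — the stated reason for using it.

## The phantom simulator

`simulate_sequence()` emulates the standard numerical-phantom protocol:
sequences of 10 RF frames under monotonically increasing axial compression
(cumulative average strain 0.5 %–4.5 % in 0.5 % steps) with one or two stiff
inclusions at random positions.

* **Deformation**: local axial strain is the applied strain modulated by
  Gaussian stiffness bumps,
  `eps(y, x) = s (1 - sum_k (1 - c_k) exp(-d_k² / 2 r_k²))`, with
  `c_k ∈ (0, 1]` the inclusion strain contrast (drawn from 0.4–0.7,
  emulating 40–60 kPa inclusions in a softer background). The axial
  displacement is the exact depth integral (an error-function expression), the
  top row is fixed (probe contact), and the lateral motion is probe drift plus
  a Poisson-ratio term (ν = 0.495, near-incompressible). Displacement,
  strain, and the inverse deformation all have closed forms, so the ground
  truth is exact rather than discretised.
* **Speckle**: scatterers (1.5 per pixel, standard-normal reflectivity,
  uniform continuous positions) are bilinearly splatted and convolved with a
  separable cosine-modulated Gaussian PSF (0.25 cycles/sample, σ = 2 axial /
  1.5 lateral samples). Compressed frames re-render *moved* scatterers rather
  than warping frame 1, so genuine speckle decorrelation is present. The
  envelope of a dense frame follows Rayleigh statistics (std/mean ≈ 0.5227).
* **Noise**: additive Gaussian at 5 % of the clean RF standard deviation.

What the simulator does **not** reproduce: full acoustic propagation
(attenuation, phase aberration, reverberation), out-of-plane motion,
physiological motion, depth-dependent PSF, and FEM-accurate mechanics around
inclusions. Passing the recovery tests below therefore shows that the
unsupervised objective recovers deformation from realistic speckle under
controlled conditions; it does not by itself establish in vivo performance.

## Scaled-down study conditions

All training-based checks run on one CPU, so the experiments use the `tiny`
networks on 64×64 phantoms: 20 training sequences and 5 held-out sequences of
10 frames each (strain ramp 0.5 %–4.5 %), LNCC window 15×15, LSQSE window 15,
ReUSENet trained for up to 30 epochs and USENet for up to 15 epochs (4 random
pairs per sequence per epoch). Displacement accuracy is reported as NRMSE
(`100 · RMSE / mean(label)`) of the *cumulative* first-frame-to-frame-t axial
displacement, obtained by composing the consecutive-pair predictions —
mirroring the per-compression-level protocol of the full-scale experiments —
averaged over steps and held-out sequences. The similarity score is the LNCC
between each earlier frame and the motion-compensated later frame.

The recurrence comparison evaluates the largest frame gap (frame 1 → 10,
4.5 % cumulative strain, displacements approaching a carrier wavelength):
ReUSENet accumulates the deformation across intermediate pairs, while USENet
sees the distant pair directly and faces heavily decorrelated, phase-ambiguous
speckle — the mechanism behind the reported failure of feed-forward trackers
at large compression.

## Numerical choices and degenerate inputs

* Bilinear interpolation everywhere (warping, resizing, landmark sampling);
  backward mapping with clamp-to-edge and a validity mask; loss windows with
  any invalid pixel are excluded.
* LNCC variance guard ε = 1e-5 in the denominator (`N σ1 σ2 + ε`) and as the
  σ threshold for skipping flat windows; an error is raised when *no* window
  is usable (degenerate overlap), and metric wrappers report `NA` for such
  steps.
* Batch-norm statistics are per-forward spatial moments (the training unit is
  a single pair/sequence); ε = 1e-5.
* `nrmse` refuses a zero-mean label (undefined normalisation); `snre` refuses
  constant strain.
* All randomness flows from explicit integer seeds (phantoms, initialisation,
  batching); two runs with the same seeds are bitwise identical.

## What the scaled-down experiments can and cannot show

Two properties of the small-image regime are worth stating explicitly,
because they bound what any tracker can achieve on 64×64 phantoms:

* **A sub-sample accuracy floor.** With 0.5 % strain steps over 64 axial
  samples, the mean per-step displacement is only ~0.14 samples. Because
  compressed frames are re-rendered from moved scatterers (genuine speckle
  decorrelation) and the similarity is evaluated through bilinear
  interpolation, the minimiser of the unsupervised objective is displaced
  from the true field by a few hundredths of a sample — the trained network
  can reach a *lower* loss than the exact ground-truth field. An exhaustive
  NCC block-matching oracle with parabolic sub-sample refinement shows the
  same ~0.04-sample floor on the same pairs. Relative to a 0.14-sample mean
  this floor is ~30 % NRMSE, whereas at acquisition scale (a thousand axial
  samples, displacements of tens of samples) the identical absolute floor is
  about 1 %. Displacement NRMSE on tiny phantoms therefore cannot be read on
  the same scale as full-size results.
* **The recurrence advantage needs large deformations.** The failure mode of
  feed-forward trackers appears when the inter-frame displacement exceeds the
  speckle correlation length by a large margin. At 64×64 the *largest*
  cumulative displacement (4.5 % strain) is only ~2.9 samples, which a
  feed-forward network can track directly, while composing nine consecutive
  recurrent predictions accumulates the per-pair floor error (consecutive
  pairs share speckle, so the errors add coherently). At this scale the
  comparison can therefore favour the feed-forward variant; the recurrent
  architecture's benefit is expected to emerge with the deformation ranges of
  full-size data.

## Known limitations

* The convolution speckle model is linear and shift-invariant; real RF data
  is neither. In vivo use requires fine-tuning on real acquisitions.
* The recurrent decoder is trained with full backpropagation through time;
  memory grows linearly with sequence length (windowing mitigates this).
* LSQSE is one-dimensional (axial); no lateral or shear strain.
* The CPU implementation is intended for method study and small images, not
  for the real-time rates achievable with GPU inference.
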