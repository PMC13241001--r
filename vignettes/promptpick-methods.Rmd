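---
title: "Prompt-guided particle picking: models, training and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prompt-guided particle picking: models, training and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Single-particle cryo-EM reconstructs a 3-D density map from many 2-D
projections ("particles") that must first be localized in extremely noisy
micrographs. Raw micrographs commonly sit at negative signal-to-noise
ratios, so pickers either denoise first and detect second — losing
structure to over-smoothing — or detect on raw images and suffer from the
noise. PromptPick implements a coupled alternative: a denoiser and a
particle detector that exchange information while both are trained, with
the detector's output used as *prompts* (points and a coarse mask) for a
promptable segmentation model that produces the final particle mask, from
which coordinates are extracted and written as STAR files.

## Components

### Noise2Noise denoiser

The denoiser is a U-Net (`denoiserForward()`): an encoder of
conv-conv-ReLU blocks whose widths double at each of `n_levels = 3`
levels (16, 32, 64 by default), 2x2 average-pool down-sampling, and a
symmetric decoder with nearest-neighbour up-sampling and skip
connections; a zero-initialized 1x1 output convolution adds a learned
residual to the input. Inputs are standardized per micrograph (zero
mean, unit variance) and destandardized on output; non-dyadic sizes are
reflect-padded and cropped back.

Because clean targets do not exist in cryo-EM, training is unsupervised
in the Noise2Noise sense: two micrographs built from disjoint (even/odd)
movie-frame sums share one signal but carry independent zero-mean noise,
and the MSE minimizer of "predict one from the other" approaches the
clean signal. `trainDenoiser()` samples aligned random patches from the
pairs and uses both orientations of each pair (even-to-odd and
odd-to-even) as training samples — the objective is symmetric and this
doubles the effective data at no cost. Optimization is Adam
(learning rate 2e-3 by default) on 64-px patches.

### Automatic prompt generator (APG)

The detector (`apgForward()`) is a small ConvNeXt-style encoder — per
level a depthwise 7x7 convolution, layer norm, and a pointwise
expand-contract MLP with a residual connection — whose level count
matches the denoiser encoder so the two can be fused one-to-one. A
feature pyramid (1x1 lateral projections to a common width, top-down
nearest-neighbour addition) feeds three heads:

* a **regression head**: for every point of a fixed reference grid
  (stride 8 px, i.e. half the nominal particle diameter), a descriptor is
  built by mapping the point into each pyramid level with the linear
  scaling `(x * Wi/W, y * Hi/H)`, sampling each level bilinearly, and
  concatenating the per-level vectors; an MLP predicts an (x, y) offset,
  zero-initialized so refinement starts from the grid itself. Offsets are
  clamped to one stride by default.
* a **classification head** scoring each refined point with a sigmoid
  confidence.
* a **segmentation head**: the pyramid levels are resampled to a common
  grid at 1/2 input resolution, summed element-wise, and passed through a
  per-pixel MLP to give coarse mask logits. One half was chosen (over a
  coarser 1/4) because the level-1 features already sit at full
  resolution in this desk-scale encoder; the scale is a config knob.

Training (`trainAPG()`) matches ground-truth centres to proposals
one-to-one with a Hungarian assignment on the cost
`D[i, j] = gamma * ||p_i - phat_j|| - chat_j` (`gamma = 0.05`), then
minimizes a weighted sum (`lambda = (2, 1, 1)`) of Smooth-L1 regression
on matched pairs, weighted binary cross-entropy on confidences (matched
proposals are the positives, every unmatched proposal a negative with
weight `alpha = 0.5`), and a focal loss on the coarse mask
(`alpha_f = 0.25`, `gamma_f = 2`, literature defaults). The numeric
values of `gamma`, `alpha` and `lambda` are package choices tuned once on
the synthetic benchmark and exposed in the config.

The in-package Hungarian solver is a successive-shortest-path
implementation for rectangular problems; the public `hungarianMatch()`
additionally refines ties to the lexicographically smallest optimal
assignment (`canonical = TRUE`), which makes results reproducible even on
degenerate cost matrices. The training loop uses the plain solver — with
continuous costs, ties have probability zero.

### Selective feature integrator (SFI)

The exchange block (`sfiForward()`) fuses a main-task feature `f_x` with
the corresponding-level auxiliary feature `f_y`:

1. `f_y` is channel-projected (1x1) and bilinearly resampled to `f_x`'s
   grid; single-head cross-attention (queries from `f_x`, keys/values
   from the projected `f_y`) yields the fused feature `f_Axy`. Attention
   runs on a grid capped at 32x32 tokens and the result is up-sampled —
   this bounds the quadratic cost and is a resolution choice, not part of
   the model's definition.
2. a sigmoid *leaky gate* `r = sigmoid(G1([f_x, f_Axy]))` controls how
   much of the tanh-squashed fused content enters:
   `f~ = f_x + r * tanh(G2(f_Axy))`;
3. a sigmoid *memory gate* `z = sigmoid(G3([f_x, f~]))` mixes convexly:
   `h = z * f_x + (1 - z) * f~`.

This GRU-flavoured parameterization is one concrete realization of the
published gating description (cross-attention fusion, a gate controlling
the incorporation ratio, a gate balancing the main-task feature); the
exact equations are not public, so the package documents its choice and
pins it down with tests. `G2` is zero-initialized, hence a fresh block is
*bitwise* an identity — the convex mixture is implemented as
`f_x + (1 - z) * (f~ - f_x)` precisely so the pass-through case incurs no
rounding. Each encoder level gets two independent blocks, one per
direction.

In the joint configuration the denoiser's blocks consume the raw APG
encoder features computed on the shared noisy input, while the APG —
which runs on the denoised image, exactly as at inference — consumes the
denoiser's raw encoder features from that pass. This ordering resolves
the apparent circularity of bidirectional exchange between two encoders
that feed each other, keeps the APG's input distribution identical
across stages 2, 3 and inference, and makes the stage-3 warm start exact.
The denoised image handed to the APG is treated as data (no gradient
flows through it); the tasks couple through the fusion blocks and the
shared objective.

### Promptable segmenter with Mona adapters

The final mask comes from a small promptable segmenter
(`segForward()`), deliberately SAM-shaped but sized for CPU training:
patch embedding (8-px patches), learned positional embeddings, three
transformer blocks (4-head self-attention, MLP), each followed by a
**Mona adapter** — layer norm with learned scaling, down-projection to 16
channels, three parallel depthwise convolutions with kernels 3, 5 and 7
whose outputs are summed, GELU, and a zero-initialized up-projection with
a residual. Zero initialization makes each adapter an exact identity, so
inserting adapters never perturbs the backbone's function at the start of
fine-tuning. The three kernel sizes realize "different receptive fields"
— the exact published internals are supplementary, so the package states
its concrete choice.

Point prompts are encoded as Fourier features of normalized coordinates
plus a learned per-label embedding; the coarse mask prompt is projected
(zero-initialized 1x1) and added element-wise to the image embedding.
The decoder prepends a learned mask token to the point tokens, runs
token self-attention and two-way cross-attention with the image tokens,
and scores every pixel of the up-sampled feature map against an MLP of
the mask token, plus a learned scalar bias. One mask is decoded per
micrograph (binary particle/background); prompts act as a set, so the
output is invariant to their order. The up-sampling head uses GELU
rather than ReLU: early focal-loss pressure can push the whole head
negative, and ReLU would then stop all gradient flow (an observed
failure mode at some seeds), while GELU recovers.

Fine-tuning (`trainSegmenter()`) minimizes
`lambda_f * focal + dice` (`lambda_f = 20`) and updates only adapters,
prompt encoder and decoder; the backbone is frozen and a parameter
checksum verifies bit-identity before and after. The focal term is
evaluated through a softplus reparameterization of `log sigmoid` so that
saturated logits keep a usable gradient. The backbone here is the
package's own small encoder; `loadEncoderWeights()` is the documented
hook for substituting externally obtained pretrained weights, which
nothing in the package requires.

### Progressive training

`progressiveTrain()` runs four stages: (1) denoiser alone (exchange
disabled — each encoder level passes straight to down-sampling); (2) APG
alone on stage-1 denoised images; (3) exchange blocks activated and both
objectives optimized jointly (1:1 weighting by default, a config knob);
(4) segmenter fine-tuned on denoised images with APG prompts. Because
the fusion blocks start as exact identities, the stage-3 step-0 joint
loss equals the sum of the stage-1 and stage-2 terminal losses on a
fixed audit crop — the package records this decomposition in the
returned bundle and the acceptance suite asserts it to 1e-10. Stages can
be skipped (`stages =`), e.g. omitting stage 1 trains the APG on raw
images as an ablation.

### Picking and post-processing

`pickParticles()` denoises, generates prompts (confidence >= 0.5, at
most 64 points), decodes the mask, and post-processes: binarize at
probability 0.5; drop components smaller than `0.3 * pi * r^2`; take
component centroids; attach to each centroid the maximum prompt
confidence inside its component (1.0 when none); greedy
minimum-distance suppression at `0.8 *` diameter, keeping higher
confidence first with ties broken by (y, x). The thresholds are
reconstruction choices (the published chain's constants are not public)
and are exposed in the config.

## Evaluation metrics

* **Precision/recall/F1** (`evalPicking()`): square boxes of the nominal
  diameter are centred on coordinates; predictions and ground truth are
  matched uniquely, greedily by descending IoU, and a pair counts only if
  IoU strictly exceeds 0.5. The box construction is a package choice (the
  IoU geometry for point picks is not published); a circle-IoU
  alternative is provided. Greedy matching is the standard
  detection-metric convention — the Hungarian matcher is a training-time
  device and is kept out of the metric.
* **Dice** (`diceScore()`): `2|A∩B|/(|A|+|B|)`, defined as 1 for two
  empty masks; reported per micrograph and averaged.
* **SNR**: with synthetic data the oracle
  `10 log10(Var(clean)/Var(residual))` (`oracleSNR()`); without clean
  references, the paired-region estimate (`snrPairedRegions()`): each
  signal/background ROI pair contributes `10 log10(s^2 / v_b)` with `s`
  the background-subtracted signal mean and `v_b` the background
  variance. On synthetic scenes the two track each other closely
  (Spearman rho > 0.9 across noise levels in the test suite).

## The synthetic benchmark

The generator (`generateScene()`, `makeNoisyPair()`) emulates the
statistical structure the method relies on and nothing more: roughly
circular dark particles (radial logistic profile, rim softness 1 px,
contrast -1) scattered by rejection sampling with a minimum
centre-to-centre distance on a flat (or low-order polynomial)
background, observed through two independent additive Gaussian noise
fields — precisely the even/odd assumption. A Poisson-Gaussian mode
exists for robustness experiments but is not part of the benchmark.
It does **not** model CTF oscillations, ice gradients, structured
(pink) noise, particle heterogeneity or orientation; passing the
benchmark therefore demonstrates that the machinery — losses, matching,
fusion, staged optimization — works as specified, not that the trained
weights transfer to EMPIAR data.

Benchmark conditions (also the config defaults): 192x192 px scenes, 20
particles of radius 8 px, minimum distance 2.5 r, raw oracle SNR -3 dB,
100 training and 20 held-out scenes. The image size is the package's
choice: it is the smallest dyadic-friendly frame in which 20 particles
at that spacing place comfortably. The denoiser-recovery experiment uses
200 pairs of 128x128 scenes with 9 particles each (matching the
benchmark's particle density) at raw SNR -5 dB. Problem sizes, step
counts (300/250/40/200 for the four stages) and learning rates were
fixed once against this benchmark and are stated in `defaultConfig()`.

## Numerical choices and degenerate inputs

* Confidences are clipped to `[1e-7, 1 - 1e-7]` inside the
  cross-entropy; the focal loss needs no clipping thanks to the softplus
  form.
* Hungarian costs must be finite; `N > M` (more truths than proposals)
  is an error by construction.
* Empty-set conventions: no predictions with non-empty truth gives
  precision 0; two empty sets give precision = recall = F1 = 1; Dice of
  two empty masks is 1.
* `oracleSNR` refuses a constant clean image and an exactly-clean
  observation; the region-pair SNR refuses zero background variance and
  zero signal amplitude.
* Scene generation fails with the achievable count when rejection
  sampling cannot place the requested particles.
* All file writes are atomic (temp + rename); MRC is mode-2 float32
  with the pixel size in the cell header; STAR output uses plain
  RELION-style loop blocks with `_rlnAutopickFigureOfMerit` for
  confidences.

## Known limitations

* The image-encoder backbone of the segmenter is randomly initialized
  and frozen; fine-tuning relies on adapters and the decoder. This
  mirrors the published freezing contract at desk scale but leaves
  performance on real micrographs to externally supplied weights.
* Gradients do not flow from the APG loss into the denoiser through the
  denoised image (only through the fusion blocks); full end-to-end
  differentiation would require the detector to consume the raw noisy
  image instead, changing its input distribution between stages.
* Cross-attention inside the fusion blocks is single-head and
  resolution-capped; multi-head variants are out of scope.
* The reverse-mode autodiff engine is single-threaded double precision;
  it is exact (finite-difference-checked) but not fast by deep-learning
  standards — the default problem sizes are chosen so every stage trains
  in minutes on one CPU.
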