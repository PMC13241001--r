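# PromptPick

Prompt-guided particle picking for cryo-EM micrographs, fully trainable
on one CPU.

Single-particle cryo-EM needs the pixel coordinates of hundreds of
thousands of particle projections before any 3-D reconstruction can
start, and micrographs routinely sit below 0 dB SNR. PromptPick couples
three models so that denoising and detection help each other instead of
running as independent stages:

1. an **image denoiser** — a U-Net `f_θ` trained unsupervised with the
   Noise2Noise objective on even/odd frame-sum pairs,
   `L_denoise = E ‖f_θ(x_even) − x_odd‖²`, whose MSE minimizer
   approaches the clean signal;
2. an **automatic prompt generator (APG)** — a ConvNeXt-style encoder
   with an FPN that refines a fixed reference grid into particle-centre
   proposals `p̂_j` with confidences `ĉ_j` and a coarse mask. Training
   matches ground-truth centres `p_i` one-to-one to proposals by the
   Hungarian algorithm on the cost `D_ij = γ‖p_i − p̂_j‖₂ − ĉ_j`, then
   minimizes `L_APG = λ₁ L_reg + λ₂ L_cls + λ₃ L_seg` (Smooth-L1 on
   matched points, weighted BCE on confidences, focal loss on the mask);
3. a **promptable segmenter** in the SAM mold with parameter-efficient
   Mona adapters (three parallel depthwise convolutions, identity at
   zero init). It takes the denoised image, the point prompts and the
   coarse mask prompt and decodes the final particle mask, fine-tuned
   with `L_SAM = λ_f L_focal + L_dice` while its encoder backbone stays
   frozen.

Between the two encoders sit paired **selective feature integrator
(SFI)** blocks — cross-attention fusion with a sigmoid leaky gate and a
sigmoid memory gate, `h = z ⊙ f_x + (1−z) ⊙ (f_x + r ⊙ tanh(W f_Axy))` —
zero-initialized so that activating them for joint training is exactly
loss-neutral at step 0. Training is progressive: denoiser alone, APG
alone on denoised images, joint with SFI, segmenter fine-tuning. The
final mask is post-processed (component filtering, centroids, distance
suppression) into RELION-style STAR coordinates.

A synthetic-scene generator with known ground truth (soft-edged disks,
minimum-distance placement, two independent Gaussian noise realizations
of each clean image) makes every stage trainable and testable without
any external data; neural networks are trained by the package's own
reverse-mode autodiff engine (pure R + BLAS with two compiled
convolution kernels), so no deep-learning framework is required.

Intended users: methods developers who want a transparent, fully
inspectable desk-scale implementation of this coupled
denoise-detect-segment architecture, and cryo-EM practitioners who want
to study its behaviour under controlled noise.

## Worked example

Train the full pipeline on ten small synthetic scenes and pick a
held-out one (about two minutes on one CPU):

```r
library(PromptPick)
cfg <- defaultConfig()
cfg$simulate$height <- cfg$simulate$width <- 96
cfg$simulate$n_particles <- 6
cfg$train$denoiser_steps <- 60; cfg$train$apg_steps <- 60
cfg$train$joint_steps <- 8; cfg$train$seg_steps <- 200

sp     <- configSceneParams(cfg, seed = 1)
pairs  <- simulateDataset(10, sp, targetSnrDb = -3)
bundle <- progressiveTrain(pairs, cfg, seed = 1)

spTest <- sp; spTest@seed <- 901
np  <- simulateDataset(1, spTest, targetSnrDb = -3)[[1]]
res <- pickParticles(evenImage(np), bundle)
res$particles
#> ParticleSet: 6 particles, diameter 16 px (micrograph 'scene901_even')

sc <- np@scene
m  <- evalPicking(res$particles, ParticleSet(coords(sc)), diameter = 16)
sprintf("precision %.3f  recall %.3f  F1 %.3f", m$precision, m$recall, m$f1)
#> "precision 1.000  recall 1.000  F1 1.000"
diceScore(res$mask, groundTruthMask(sc))
#> 0.938
oracleSNR(cleanImage(sc), pixels(res$denoised))   # raw input is at -3.0 dB
#> 9.5
```

All six planted particles are recovered (each matched at IoU > 0.5 to a
true centre), the predicted mask overlaps the true footprints at Dice
0.94, and the denoiser lifted the oracle SNR from −3.0 to +9.5 dB.
`writeSTAR(res$particles, "picks.star")` then emits the coordinates with
their confidences:

```
loop_
_rlnCoordinateX #1
_rlnCoordinateY #2
_rlnAutopickFigureOfMerit #3
70.30208333 73.06770833 0.997080
49.53225806 17.11290323 0.909504
...
```

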