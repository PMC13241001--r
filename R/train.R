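#' @title Progressive multi-stage training
#'
#' @description
#' The full pipeline trains in four stages: (1) the denoiser alone with the
#' Noise2Noise objective, feature exchange disabled; (2) the prompt
#' generator alone on stage-1 denoised images, exchange disabled; (3) the
#' exchange blocks are activated — zero-initialized, so step 0 reproduces
#' the stage-1/2 forwards exactly — and both task losses are optimized
#' jointly; (4) the promptable segmenter is fine-tuned on denoised images
#' with prompts from the trained generator, its encoder backbone frozen.
#'
#' In the joint (exchange-enabled) configuration the denoiser's fusion
#' blocks consume the raw prompt-generator encoder features computed on
#' the shared noisy input, and the prompt generator — which runs on the
#' denoised image, as at inference — consumes the denoiser's raw encoder
#' features from that same pass. The denoised image handed to the prompt
#' generator is treated as data (no gradient through it); the tasks couple
#' through the bidirectional fusion blocks.
#'
#' @name train
NULL

# nearest-neighbour downsample of a binary mask to oh x ow
resizeMaskNearest <- function(mask, oh, ow) {
  H <- nrow(mask); W <- ncol(mask)
  ri <- pmin(pmax(floor(((seq_len(oh) - 0.5) * H / oh) + 0.5), 1L), H)
  ci <- pmin(pmax(floor(((seq_len(ow) - 0.5) * W / ow) + 0.5), 1L), W)
  mask[ri, ci, drop = FALSE]
}

# random crop of a training scene; returns image crops, shifted centres
# and the cropped ground-truth mask
cropScene <- function(img, centers, mask, side, img2 = NULL) {
  H <- nrow(img); W <- ncol(img)
  side <- min(side, H, W)
  r0 <- sample.int(H - side + 1L, 1L)
  c0 <- sample.int(W - side + 1L, 1L)
  keep <- if (nrow(centers)) {
    centers[, 1L] >= c0 - 1L + 2 & centers[, 1L] <= c0 - 1L + side - 3 &
    centers[, 2L] >= r0 - 1L + 2 & centers[, 2L] <= r0 - 1L + side - 3
  } else logical(0)
  ctr <- centers[keep, , drop = FALSE]
  if (nrow(ctr)) {
    ctr[, 1L] <- ctr[, 1L] - (c0 - 1L)
    ctr[, 2L] <- ctr[, 2L] - (r0 - 1L)
  }
  list(img = img[r0:(r0 + side - 1L), c0:(c0 + side - 1L)],
       img2 = if (!is.null(img2)) img2[r0:(r0 + side - 1L), c0:(c0 + side - 1L)],
       centers = ctr,
       mask = mask[r0:(r0 + side - 1L), c0:(c0 + side - 1L)])
}

# APG loss for one forward pass against ground truth
apgLossForward <- function(afw, centers, gtMask, lossCfg) {
  pts <- afw$points; conf <- afw$conf
  N <- nrow(centers); M <- nrow(adVal(pts))
  if (N > 0L) {
    D <- costMatrix(centers, adVal(pts), as.numeric(adVal(conf)), lossCfg$gamma)
    asg <- lapSolve(D)
    lr <- regLoss(adRows(pts, asg), centers)
    lc <- clsLoss(conf, asg, lossCfg$alpha, lossCfg$conf_eps)
  } else {
    asg <- integer(0)
    lr <- 0
    lc <- clsLoss(conf, integer(0), lossCfg$alpha, lossCfg$conf_eps)
  }
  dmL <- dim(adVal(afw$maskLogits))
  gtc <- resizeMaskNearest(gtMask, dmL[1L], dmL[2L])
  ls <- segFocalLoss(afw$maskLogits, gtc, lossCfg$focal_alpha, lossCfg$focal_gamma)
  list(loss = apgLoss(lr, lc, ls,
                      c(lossCfg$lambda_reg, lossCfg$lambda_cls, lossCfg$lambda_seg)),
       reg = adVal(lr), cls = adVal(lc), seg = adVal(ls), assignment = asg)
}

#' Train the prompt generator
#'
#' @param items list of `list(img, centers, mask)` training scenes (images
#'   are typically stage-1 denoised micrographs)
#' @param params from [apgParams()]
#' @param config full run configuration (uses `apg`, `loss` blocks)
#' @param steps,lr,crop training hyperparameters
#' @param seed RNG seed
#' @param verboseEvery print smoothed loss every this many steps (0 quiet)
#' @return list(params, lossTrace, finalLoss)
#' @export
trainAPG <- function(items, params, config = defaultConfig(), steps = 250L,
                     lr = 1e-3, crop = 96L, seed = 1L, verboseEvery = 0L) {
  stopifnot(length(items) >= 1L)
  pv <- paramValues(params)
  opt <- adamInit(pv, lr = lr)
  set.seed(as.integer(abs(seed) %% 2147483647))
  losses <- numeric(steps)
  acfg <- config$apg; lcfg <- config$loss
  for (s in seq_len(steps)) {
    it <- items[[sample.int(length(items), 1L)]]
    cr <- cropScene(it$img, it$centers, it$mask, crop)
    adTapeStart()
    w <- wrapParams(pv)
    afw <- apgForward(cr$img, w, gridStride = acfg$grid_stride,
                      coarseScale = acfg$coarse_scale,
                      clampOffsets = acfg$clamp_offsets)
    lf <- apgLossForward(afw, cr$centers, cr$mask, lcfg)
    lv <- adVal(lf$loss)
    if (!is.finite(lv)) stop("APG training diverged (non-finite loss) at step ", s)
    adBackward(lf$loss)
    upd <- adamStep(pv, w, opt)
    pv <- upd$params; opt <- upd$opt
    adTapeStop()
    losses[s] <- lv
    if (verboseEvery > 0L && s %% verboseEvery == 0L) {
      message(sprintf("apg step %d/%d  loss %.4f (reg %.3f cls %.3f seg %.3f)",
                      s, steps, mean(losses[max(1L, s - 24L):s]),
                      lf$reg, lf$cls, lf$seg))
    }
  }
  list(params = pv, lossTrace = losses,
       finalLoss = mean(losses[max(1L, steps - 24L):steps]))
}

#' Create the paired fusion blocks for joint training
#'
#' One block per encoder level and direction: `sfiU` fuses APG features
#' into the denoiser (denoiser is the main task), `sfiC` the reverse.
#'
#' @param denParams,apgParams2 the two models' parameters
#' @param enabled construct in the enabled state
#' @return list(sfiU, sfiC), each a per-level list of [sfiParams()]
#' @export
makeSfiBlocks <- function(denParams, apgParams2, enabled = TRUE) {
  chU <- as.integer(round(adVal(denParams$meta$channels)))
  chC <- as.integer(round(adVal(apgParams2$meta$channels)))
  stopifnot(length(chU) == length(chC))
  L <- length(chU)
  sfiU <- lapply(seq_len(L), function(i) sfiParams(chU[i], chC[i], enabled))
  sfiC <- lapply(seq_len(L), function(i) sfiParams(chC[i], chU[i], enabled))
  names(sfiU) <- names(sfiC) <- paste0("l", seq_len(L))
  list(sfiU = sfiU, sfiC = sfiC)
}

# one joint forward: returns the two losses (nodes when params wrapped)
jointForward <- function(even, odd, centers, gtMask, dp, ap, su, sc, config) {
  acfg <- config$apg; lcfg <- config$loss
  fC <- apgEncoderFeatures(even, ap)
  dfw <- denoiserForward(even, dp, peerFeatures = fC, sfiBlocks = su,
                         maxTokens = config$sfi$attn_max_tokens)
  Ld <- n2nLoss(dfw$out, array(odd, c(dim(odd), 1L)))
  den <- matrix(adVal(dfw$out), nrow(even), ncol(even))
  rawU <- lapply(dfw$raw, adVal)     # detached: coupling is via the SFI blocks
  afw <- apgForward(den, ap, gridStride = acfg$grid_stride,
                    peerFeatures = rawU, sfiBlocks = sc,
                    maxTokens = config$sfi$attn_max_tokens,
                    coarseScale = acfg$coarse_scale,
                    clampOffsets = acfg$clamp_offsets)
  lf <- apgLossForward(afw, centers, gtMask, lcfg)
  list(Ld = Ld, La = lf$loss, denoised = den)
}

#' Jointly train denoiser + prompt generator with fusion enabled
#'
#' @param pairs list of [NoisyPair-class] with synthetic scenes attached
#' @param denParams,apgParams2 stage-1/2 parameters (warm start)
#' @param sfi list(sfiU, sfiC) from [makeSfiBlocks()]
#' @param config full run configuration
#' @param steps,lr,crop training hyperparameters
#' @param seed RNG seed
#' @param verboseEvery progress printing (0 quiet)
#' @return list(denParams, apgParams, sfi, lossTrace)
#' @export
trainJoint <- function(pairs, denParams, apgParams2, sfi,
                       config = defaultConfig(), steps = 40L, lr = 3e-4,
                       crop = 96L, seed = 1L, verboseEvery = 0L) {
  pv <- list(d = paramValues(denParams), a = paramValues(apgParams2),
             su = paramValues(sfi$sfiU), sc = paramValues(sfi$sfiC))
  opt <- adamInit(pv, lr = lr)
  set.seed(as.integer(abs(seed) %% 2147483647))
  wd <- config$train$joint_denoise_weight
  wa <- config$train$joint_apg_weight
  losses <- numeric(steps)
  for (s in seq_len(steps)) {
    pr <- pairs[[sample.int(length(pairs), 1L)]]
    scn <- pr@scene
    cr <- cropScene(pr@even@pixels, scn@centers, scn@gtMask, crop,
                    img2 = pr@odd@pixels)
    adTapeStart()
    w <- wrapParams(pv)
    jf <- jointForward(cr$img, cr$img2, cr$centers, cr$mask,
                       w$d, w$a, w$su, w$sc, config)
    loss <- adAdd(adScale(jf$Ld, wd), adScale(jf$La, wa))
    lv <- adVal(loss)
    if (!is.finite(lv)) stop("joint training diverged (non-finite loss) at step ", s)
    adBackward(loss)
    upd <- adamStep(pv, w, opt)
    pv <- upd$params; opt <- upd$opt
    adTapeStop()
    losses[s] <- lv
    if (verboseEvery > 0L && s %% verboseEvery == 0L) {
      message(sprintf("joint step %d/%d  loss %.4f", s, steps,
                      mean(losses[max(1L, s - 9L):s])))
    }
  }
  list(denParams = pv$d, apgParams = pv$a,
       sfi = list(sfiU = pv$su, sfiC = pv$sc), lossTrace = losses)
}

#' Fine-tune the promptable segmenter
#'
#' Only the Mona adapters, the prompt encoder and the mask decoder are
#' updated; the image-encoder backbone stays frozen (verified by checksum
#' in the return value).
#'
#' @param items list of `list(img, points, labels, coarseMask, gtMask)`
#' @param params from [promptsegParams()]
#' @param config full run configuration (uses `promptseg`, `loss` blocks)
#' @param steps,lr training hyperparameters
#' @param seed RNG seed
#' @param verboseEvery progress printing (0 quiet)
#' @return list(params, lossTrace, finalLoss, backboneChecksumBefore,
#'   backboneChecksumAfter)
#' @export
trainSegmenter <- function(items, params, config = defaultConfig(),
                           steps = 200L, lr = 1e-3, seed = 1L,
                           verboseEvery = 0L) {
  pv <- paramValues(params)
  csBefore <- paramChecksum(pv, "backbone")
  opt <- adamInit(pv, lr = lr)
  set.seed(as.integer(abs(seed) %% 2147483647))
  lcfg <- config$loss
  lf <- config$promptseg$lambda_f
  losses <- numeric(steps)
  for (s in seq_len(steps)) {
    it <- items[[sample.int(length(items), 1L)]]
    adTapeStart()
    w <- wrapParams(pv)
    lg <- segForward(it$img, it$points, it$labels, it$coarseMask, w)
    loss <- samLoss(lg, it$gtMask, lambdaF = lf,
                    focalAlpha = lcfg$focal_alpha, focalGamma = lcfg$focal_gamma)
    lv <- adVal(loss)
    if (!is.finite(lv)) stop("segmenter fine-tuning diverged (non-finite loss) at step ", s)
    adBackward(loss)
    upd <- adamStep(pv, w, opt, trainable = c("mona", "prompt", "decoder"))
    pv <- upd$params; opt <- upd$opt
    adTapeStop()
    losses[s] <- lv
    if (verboseEvery > 0L && s %% verboseEvery == 0L) {
      message(sprintf("seg step %d/%d  loss %.4f", s, steps,
                      mean(losses[max(1L, s - 24L):s])))
    }
  }
  list(params = pv, lossTrace = losses,
       finalLoss = mean(losses[max(1L, steps - 24L):steps]),
       backboneChecksumBefore = csBefore,
       backboneChecksumAfter = paramChecksum(pv, "backbone"))
}

#' Run the full progressive training schedule
#'
#' @param pairs list of [NoisyPair-class] with scenes (the training split)
#' @param config full run configuration
#' @param seed master seed; per-stage seeds are derived from it
#' @param stages integer subset of 1:4; omitting stage 1 trains the prompt
#'   generator on raw images (ablation mode); later stages always use the
#'   best available upstream outputs
#' @param verbose print per-stage progress
#' @return a model bundle: list(denoiser, apg, sfi, seg, config, audit,
#'   stages) where `audit` records the terminal losses of stages 1 and 2
#'   and the stage-3 step-0 joint loss on a fixed audit crop
#' @export
progressiveTrain <- function(pairs, config = defaultConfig(), seed = config$seed,
                             stages = 1:4, verbose = FALSE) {
  stopifnot(length(pairs) >= 1L)
  tcfg <- config$train
  vb <- function(n) if (verbose) n else 0L
  set.seed(as.integer(abs(seed) %% 2147483647))
  dpar <- denoiserParams(config$denoiser$n_levels, config$denoiser$base_channels,
                         config$denoiser$channel_growth)
  apar <- apgParams(config$apg$n_levels, config$apg$base_channels,
                    config$apg$channel_growth, config$apg$fpn_channels,
                    config$apg$head_hidden)
  audit <- list()
  # fixed audit crop (deterministic) for the warm-start bookkeeping
  aud <- pairs[[1L]]
  asc <- aud@scene
  side <- min(tcfg$apg_crop, nrow(aud@even@pixels))
  auditCrop <- list(even = aud@even@pixels[seq_len(side), seq_len(side)],
                    odd = aud@odd@pixels[seq_len(side), seq_len(side)],
                    mask = asc@gtMask[seq_len(side), seq_len(side)])
  keep <- asc@centers[, 1L] <= side - 3 & asc@centers[, 2L] <= side - 3
  auditCrop$centers <- asc@centers[keep, , drop = FALSE]

  if (1L %in% stages) {
    if (verbose) message("stage 1: denoiser (Noise2Noise)")
    st1 <- trainDenoiser(pairs, dpar, steps = tcfg$denoiser_steps,
                         lr = tcfg$denoiser_lr, patch = tcfg$denoiser_patch,
                         seed = seed + 11L, verboseEvery = vb(50L))
    dpar <- st1$params
  }
  auditDen <- function(dp) {
    fw <- denoiserForward(auditCrop$even, dp)
    adVal(n2nLoss(fw$out, array(auditCrop$odd, c(dim(auditCrop$odd), 1L))))
  }
  audit$stage1Loss <- auditDen(paramValues(dpar))

  # stage-1 denoised images (raw images in ablation mode)
  denoised <- lapply(pairs, function(pr) {
    if (1L %in% stages) denoiseMicrograph(pr@even, dpar)@pixels else pr@even@pixels
  })
  items2 <- lapply(seq_along(pairs), function(i) {
    scn <- pairs[[i]]@scene
    list(img = denoised[[i]], centers = scn@centers, mask = scn@gtMask)
  })

  if (2L %in% stages) {
    if (verbose) message("stage 2: prompt generator")
    st2 <- trainAPG(items2, apar, config, steps = tcfg$apg_steps,
                    lr = tcfg$apg_lr, crop = tcfg$apg_crop,
                    seed = seed + 23L, verboseEvery = vb(50L))
    apar <- st2$params
  }
  auditApg <- function(ap, sc = NULL, rawU = NULL, img) {
    afw <- apgForward(img, ap, gridStride = config$apg$grid_stride,
                      peerFeatures = rawU, sfiBlocks = sc,
                      maxTokens = config$sfi$attn_max_tokens,
                      coarseScale = config$apg$coarse_scale,
                      clampOffsets = config$apg$clamp_offsets)
    adVal(apgLossForward(afw, auditCrop$centers, auditCrop$mask, config$loss)$loss)
  }
  auditDenoisedCrop <- denoiseMicrograph(auditCrop$even, dpar)@pixels
  audit$stage2Loss <- auditApg(paramValues(apar), img = auditDenoisedCrop)

  sfi <- makeSfiBlocks(dpar, apar, enabled = config$sfi$enabled)
  if (3L %in% stages) {
    if (verbose) message("stage 3: joint training with feature exchange")
    jf0 <- jointForward(auditCrop$even, auditCrop$odd, auditCrop$centers,
                        auditCrop$mask, paramValues(dpar), paramValues(apar),
                        paramValues(sfi$sfiU), paramValues(sfi$sfiC), config)
    audit$stage3Step0Joint <- adVal(jf0$Ld) + adVal(jf0$La)
    st3 <- trainJoint(pairs, dpar, apar, sfi, config,
                      steps = tcfg$joint_steps, lr = tcfg$joint_lr,
                      crop = tcfg$apg_crop, seed = seed + 37L,
                      verboseEvery = vb(10L))
    dpar <- st3$denParams; apar <- st3$apgParams; sfi <- st3$sfi
  }

  spar <- NULL
  segAudit <- NULL
  if (4L %in% stages) {
    if (verbose) message("stage 4: segmenter fine-tuning")
    scfg <- config$promptseg
    H <- nrow(pairs[[1L]]@even@pixels)
    spar <- promptsegParams(
      inputSize = as.integer(ceiling(H / scfg$patch_size) * scfg$patch_size),
      patchSize = scfg$patch_size, embedDim = scfg$embed_dim,
      depth = scfg$depth, nHeads = scfg$n_heads, monaDim = scfg$mona_dim)
    items4 <- lapply(seq_along(pairs), function(i) {
      pr <- pairs[[i]]
      inf <- inferPrompts(pr@even@pixels, dpar, apar, sfi, config)
      scn <- pr@scene
      list(img = inf$denoised, points = inf$points, labels = inf$labels,
           coarseMask = inf$coarseMask, gtMask = scn@gtMask)
    })
    st4 <- trainSegmenter(items4, spar, config, steps = tcfg$seg_steps,
                          lr = tcfg$seg_lr, seed = seed + 53L,
                          verboseEvery = vb(50L))
    spar <- st4$params
    segAudit <- list(before = st4$backboneChecksumBefore,
                     after = st4$backboneChecksumAfter)
  }

  list(denoiser = paramValues(dpar), apg = paramValues(apar),
       sfi = rapplyList(sfi, adVal), seg = spar, config = config,
       audit = audit, segAudit = segAudit, stages = stages)
}
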