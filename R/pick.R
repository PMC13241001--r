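#' @title End-to-end particle picking
#' @description
#' Inference chain: denoise (with feature exchange when trained jointly),
#' generate point and mask prompts, decode the final mask with the
#' promptable segmenter, and post-process the mask into particle
#' coordinates ready for STAR export.
#' @name pick
NULL

# run denoiser + APG with whatever exchange blocks the bundle carries;
# returns denoised image, prompt points/labels, confidences, coarse mask
inferPrompts <- function(x, dpar, apar, sfi, config) {
  dp <- paramValues(dpar); ap <- paramValues(apar)
  su <- if (!is.null(sfi)) paramValues(sfi$sfiU)
  sc <- if (!is.null(sfi)) paramValues(sfi$sfiC)
  acfg <- config$apg
  fC <- if (!is.null(su)) apgEncoderFeatures(x, ap)
  dfw <- denoiserForward(x, dp, peerFeatures = fC, sfiBlocks = su,
                         maxTokens = config$sfi$attn_max_tokens)
  den <- matrix(adVal(dfw$out), nrow(x), ncol(x))
  afw <- apgForward(den, ap, gridStride = acfg$grid_stride,
                    peerFeatures = if (!is.null(sc)) lapply(dfw$raw, adVal),
                    sfiBlocks = sc, maxTokens = config$sfi$attn_max_tokens,
                    coarseScale = acfg$coarse_scale,
                    clampOffsets = acfg$clamp_offsets)
  conf <- as.numeric(adVal(afw$conf))
  pts <- adVal(afw$points)
  thr <- config$pick$conf_threshold
  sel <- which(conf >= thr)
  if (length(sel) > config$pick$max_prompts) {
    sel <- sel[order(conf[sel], decreasing = TRUE)[seq_len(config$pick$max_prompts)]]
  }
  list(denoised = den,
       points = pts[sel, , drop = FALSE],
       labels = rep(1L, length(sel)),
       conf = conf[sel],
       allPoints = pts, allConf = conf,
       coarseMask = adVal(afw$maskLogits))
}

# connected-component labelling of a binary mask (EBImage)
labelComponents <- function(binary) {
  EBImage::bwlabel(binary)
}

#' Post-process a mask into particle coordinates
#'
#' Binarizes the mask logits at probability 0.5, removes components
#' smaller than `minArea`, takes each surviving component's centroid,
#' attaches the maximum candidate-point confidence found inside the
#' component (1.0 when none falls inside), and applies greedy
#' minimum-distance suppression keeping higher confidences first (ties
#' broken by ascending y then x).
#'
#' @param maskLogits numeric matrix of mask logits at image resolution
#' @param candidatePoints m x 2 matrix of candidate centres (or NULL)
#' @param conf length-m candidate confidences
#' @param minDistance suppression radius in pixels
#' @param minArea minimum component area in pixels
#' @param diameter nominal particle diameter recorded in the output
#' @param micrographId id recorded in the output
#' @return a [ParticleSet-class]
#' @export
postprocessMask <- function(maskLogits, candidatePoints = NULL, conf = NULL,
                            minDistance = 12, minArea = 60, diameter = NA_real_,
                            micrographId = "") {
  binary <- (maskLogits > 0) * 1    # sigmoid(logit) > 0.5  <=>  logit > 0
  lab <- labelComponents(binary)
  n <- max(lab)
  if (n == 0L) return(ParticleSet(diameter = diameter, micrographId = micrographId))
  idx <- which(lab > 0)
  labs <- lab[idx]
  ys <- (idx - 1L) %% nrow(lab)      # 0-based row
  xs <- (idx - 1L) %/% nrow(lab)     # 0-based col
  area <- tabulate(labs, n)
  cx <- tapply(xs, labs, mean)
  cy <- tapply(ys, labs, mean)
  compConf <- rep(1, n)
  if (!is.null(candidatePoints) && nrow(candidatePoints) > 0L) {
    px <- pmin(pmax(round(candidatePoints[, 1L]), 0L), ncol(lab) - 1L)
    py <- pmin(pmax(round(candidatePoints[, 2L]), 0L), nrow(lab) - 1L)
    pl <- lab[cbind(py + 1L, px + 1L)]
    if (is.null(conf)) conf <- rep(1, nrow(candidatePoints))
    # max confidence per component (fallback 1.0 where no candidate inside)
    if (any(pl > 0L)) {
      agg <- tapply(conf[pl > 0L], pl[pl > 0L], max)
      compConf[as.integer(names(agg))] <- agg
    }
  }
  keep <- which(area >= minArea)
  if (!length(keep)) return(ParticleSet(diameter = diameter, micrographId = micrographId))
  cand <- data.frame(x = as.numeric(cx[keep]), y = as.numeric(cy[keep]),
                     conf = compConf[keep])
  cand <- cand[order(-cand$conf, cand$y, cand$x), ]
  sel <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (!length(sel) ||
        min(sqrt((cand$x[sel] - cand$x[i])^2 + (cand$y[sel] - cand$y[i])^2)) >= minDistance) {
      sel <- c(sel, i)
    }
  }
  out <- cand[sel, ]
  ParticleSet(cbind(out$x, out$y), confidences = pmin(pmax(out$conf, 0), 1),
              diameter = diameter, micrographId = micrographId)
}

#' Pick particles from a micrograph with a trained model bundle
#'
#' Denoises, generates prompts, decodes the final mask and post-processes
#' it into a [ParticleSet-class]. If no candidate clears the confidence
#' threshold a mask-only decode is attempted and a warning is issued.
#'
#' @param x [Micrograph-class] or matrix
#' @param bundle trained bundle from [progressiveTrain()]
#' @param confThreshold prompt confidence threshold (default from config)
#' @param minDistance suppression distance (default 0.8 x diameter)
#' @param diameter nominal particle diameter in pixels (default from the
#'   simulate config: 2 x radius)
#' @return list with `particles` ([ParticleSet-class]), `mask` (binary
#'   matrix), `maskLogits`, `denoised` ([Micrograph-class]), `prompts`,
#'   and per-stage `timings` (seconds)
#' @export
pickParticles <- function(x, bundle, confThreshold = NULL, minDistance = NULL,
                          diameter = NULL) {
  if (is(x, "Micrograph")) {
    mid <- x@id
    x <- x@pixels
  } else mid <- ""
  config <- bundle$config
  if (!is.null(confThreshold)) config$pick$conf_threshold <- confThreshold
  if (is.null(diameter)) diameter <- 2 * max(config$simulate$radius)
  if (is.null(minDistance)) minDistance <- config$pick$min_distance_frac * diameter
  minArea <- config$pick$min_area_frac * pi * (diameter / 2)^2
  t0 <- Sys.time()
  inf <- inferPrompts(x, bundle$denoiser, bundle$apg, bundle$sfi, config)
  t1 <- Sys.time()
  if (nrow(inf$points) == 0L) {
    warning("no prompt point cleared the confidence threshold; attempting mask-only decode")
  }
  lg <- segForward(inf$denoised,
                   points = if (nrow(inf$points)) inf$points,
                   labels = if (nrow(inf$points)) inf$labels,
                   coarseMask = inf$coarseMask,
                   params = paramValues(bundle$seg))
  lg <- adVal(lg)
  t2 <- Sys.time()
  particles <- postprocessMask(lg, inf$points, inf$conf,
                               minDistance = minDistance, minArea = minArea,
                               diameter = diameter, micrographId = mid)
  t3 <- Sys.time()
  list(particles = particles, mask = (lg > 0) * 1, maskLogits = lg,
       denoised = Micrograph(inf$denoised, id = paste0(mid, "_denoised")),
       prompts = inf,
       timings = c(prompts = as.numeric(t1 - t0, units = "secs"),
                   segment = as.numeric(t2 - t1, units = "secs"),
                   postprocess = as.numeric(t3 - t2, units = "secs")))
}
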