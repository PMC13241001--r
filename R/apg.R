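#' @title Automatic prompt generator (APG)
#'
#' @description
#' A convolutional encoder (ConvNeXt-style blocks: depthwise 7x7 +
#' layer-norm + pointwise MLP + residual) paired level-by-level with the
#' denoiser encoder through SFI blocks, a feature pyramid (1x1 lateral
#' projections, nearest-neighbour top-down addition), and three heads:
#' a regression MLP refining a fixed reference grid into particle-centre
#' proposals, a classification MLP scoring each proposal, and a
#' segmentation MLP producing a coarse mask from the element-wise sum of
#' the pyramid levels resampled to a common grid. Each reference point's
#' descriptor is the concatenation over pyramid levels of bilinearly
#' sampled feature vectors at its linearly mapped position.
#'
#' @name apg
NULL

#' Build a uniform reference grid
#'
#' Points at `(stride/2 + k * stride)` on each axis, row-major order
#' (y outer, x inner), `floor(H/stride) * floor(W/stride)` points total.
#' The stride should be smaller than the particle diameter so several
#' candidates fall inside each particle.
#'
#' @param imageSize integer (H, W)
#' @param stride grid stride in pixels (>= 1, < min(H, W))
#' @return list with `points` (M x 2 matrix of 0-based (x, y)) and `stride`
#' @export
buildReferenceGrid <- function(imageSize, stride) {
  H <- imageSize[1L]; W <- imageSize[2L]
  if (stride < 1) stop("stride must be >= 1")
  if (stride >= min(H, W)) stop("stride (", stride, ") must be smaller than min(H, W)")
  ny <- floor(H / stride); nx <- floor(W / stride)
  xs <- stride / 2 + (seq_len(nx) - 1L) * stride
  ys <- stride / 2 + (seq_len(ny) - 1L) * stride
  pts <- cbind(x = rep(xs, times = ny), y = rep(ys, each = nx))
  list(points = pts, stride = stride)
}

#' Map an image-space point to feature-level coordinates
#'
#' Linear scaling `(x * Wi / W, y * Hi / H)`.
#'
#' @param p numeric (x, y) or n x 2 matrix
#' @param imageSize (H, W) of the input image
#' @param levelSize (Hi, Wi) of the feature map
#' @return mapped coordinates, same shape as `p`
#' @export
mapPointToLevel <- function(p, imageSize, levelSize) {
  if (is.null(dim(p))) p <- matrix(p, 1L)
  cbind(p[, 1L] * levelSize[2L] / imageSize[2L],
        p[, 2L] * levelSize[1L] / imageSize[1L])
}

#' Bilinearly sample a feature map at one mapped point
#'
#' Standard 4-neighbour bilinear weights per channel; points outside the
#' map are clamped to the border.
#'
#' @param Fmap `Hi x Wi x C` array
#' @param point numeric (x, y) in 0-based level coordinates
#' @return numeric vector of length C
#' @export
sampleFeatureBilinear <- function(Fmap, point) {
  as.numeric(adGatherBilinear(Fmap, matrix(point, 1L)))
}

#' Multi-scale descriptor of a point
#'
#' Concatenates the bilinearly sampled per-level feature vectors in level
#' order 1..L; length is the sum of level channel counts.
#'
#' @param pyramid list of `Hi x Wi x C_i` arrays (decreasing spatial dims)
#' @param p numeric (x, y) in image coordinates
#' @param imageSize (H, W) of the input image
#' @return numeric vector of length `sum(C_i)`
#' @export
multiscaleDescriptor <- function(pyramid, p, imageSize) {
  unlist(lapply(pyramid, function(Fm) {
    dm <- dim(Fm)
    sampleFeatureBilinear(Fm, mapPointToLevel(p, imageSize, dm[1:2])[1L, ])
  }), use.names = FALSE)
}

#' Create APG parameters
#'
#' @param nLevels encoder depth (matches the denoiser for SFI pairing)
#' @param baseChannels level-1 width
#' @param channelGrowth per-level width multiplier
#' @param fpnChannels common pyramid width
#' @param headHidden hidden width of the MLP heads
#' @return nested parameter list
#' @export
apgParams <- function(nLevels = 3L, baseChannels = 16L, channelGrowth = 2,
                      fpnChannels = 32L, headHidden = 64L) {
  ch <- as.integer(round(baseChannels * channelGrowth^(seq_len(nLevels) - 1L)))
  enc <- vector("list", nLevels)
  for (i in seq_len(nLevels)) {
    enc[[i]] <- list(
      dw = list(w = initDw(7L, 7L, ch[i]), b = numeric(ch[i])),
      ln = lnParams(ch[i]),
      mlp1 = denseParams(ch[i], 2L * ch[i]),
      mlp2 = denseParams(2L * ch[i], ch[i]),
      down = if (i < nLevels) denseParams(ch[i], ch[i + 1L]) else NULL)
  }
  names(enc) <- paste0("l", seq_len(nLevels))
  stem <- convParams(3L, 3L, 1L, ch[1L])
  lat <- lapply(seq_len(nLevels), function(i) denseParams(ch[i], fpnChannels))
  names(lat) <- paste0("l", seq_len(nLevels))
  D <- nLevels * fpnChannels
  list(stem = stem, enc = enc, lat = lat,
       reg1 = denseParams(D, headHidden),
       reg2 = denseParams(headHidden, 2L, zero = TRUE),
       cls1 = denseParams(D, headHidden),
       cls2 = denseParams(headHidden, 1L),
       seg1 = denseParams(fpnChannels, headHidden),
       seg2 = denseParams(headHidden, 1L),
       meta = list(nLevels = nLevels, channels = ch, fpnChannels = fpnChannels))
}

convnextBlock <- function(x, bp) {
  y <- adDwConv2d(x, bp$dw$w, bp$dw$b)
  y <- adLayerNorm(y, bp$ln$gamma, bp$ln$beta)
  y <- dense2d(y, bp$mlp1)
  y <- adGelu(y)
  y <- dense2d(y, bp$mlp2)
  adAdd(x, y)
}

#' APG forward pass
#'
#' Runs the encoder (with optional SFI fusion against denoiser features),
#' builds the feature pyramid, and evaluates the three heads on the
#' reference grid.
#'
#' @param x input image: [Micrograph-class], matrix, or `H x W x 1` array
#'   (typically the denoised micrograph)
#' @param params from [apgParams()]
#' @param gridStride reference-grid stride (pixels)
#' @param peerFeatures optional per-level denoiser features `f_i^U`
#' @param sfiBlocks optional per-level [sfiParams()] blocks
#'   (direction: APG main, denoiser auxiliary)
#' @param maxTokens SFI attention bound
#' @param coarseScale coarse-mask down-scale factor (mask logits are at
#'   `H/coarseScale x W/coarseScale`)
#' @param clampOffsets clamp predicted offsets to +/- stride
#' @return list with `points` (M x 2 refined proposals), `conf` (length-M
#'   confidences in `[0,1]`), `confLogits`, `maskLogits`
#'   (`H/coarseScale x W/coarseScale`), `grid`, `trace` (encoder features
#'   `h_i^C`), and `pyramid`
#' @export
apgForward <- function(x, params, gridStride = 8, peerFeatures = NULL,
                       sfiBlocks = NULL, maxTokens = 32L, coarseScale = 2L,
                       clampOffsets = TRUE) {
  if (is(x, "Micrograph")) x <- x@pixels
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  L <- adVal(params$meta$nLevels)
  mu <- mean(x); sdv <- stats::sd(x); if (!is.finite(sdv) || sdv == 0) sdv <- 1
  xs <- (x - mu) / sdv
  padded <- reflectPadTo(xs, 2L^(L - 1L))
  Hp <- dim(padded$x)[1L]; Wp <- dim(padded$x)[2L]
  h <- adRelu(adConv2d(padded$x, params$stem$w, params$stem$b))
  trace <- vector("list", L)
  raw <- vector("list", L)
  for (i in seq_len(L)) {
    f <- convnextBlock(h, params$enc[[i]])
    raw[[i]] <- f
    if (!is.null(peerFeatures) && !is.null(peerFeatures[[i]])) {
      peer <- peerFeatures[[i]]
      if (!identical(dim(adVal(peer))[1:2], dim(adVal(f))[1:2]))
        stop("peer feature at level ", i, " has mismatched spatial dims")
      f <- sfiForward(f, peer, if (is.null(sfiBlocks)) NULL else sfiBlocks[[i]],
                      maxTokens = maxTokens)
    }
    trace[[i]] <- f
    if (i < L) h <- dense2d(adAvgPool2(f), params$enc[[i]]$down)
  }
  # feature pyramid: lateral 1x1 projections + top-down nearest up-sampling
  pyr <- vector("list", L)
  pyr[[L]] <- dense2d(trace[[L]], params$lat[[L]])
  for (i in seq(L - 1L, 1L)) {
    pyr[[i]] <- adAdd(dense2d(trace[[i]], params$lat[[i]]),
                      adUpNearest2(pyr[[i + 1L]]))
  }
  # reference grid on the ORIGINAL image size; mapping uses padded dims
  grid <- buildReferenceGrid(c(padded$h, padded$w), gridStride)
  M <- nrow(grid$points)
  desc <- adCbind(lapply(seq_len(L), function(i) {
    dm <- dim(adVal(pyr[[i]]))
    adGatherBilinear(pyr[[i]], mapPointToLevel(grid$points, c(Hp, Wp), dm[1:2]))
  }))
  offs <- denseForward(adRelu(denseForward(desc, params$reg1)), params$reg2)
  if (clampOffsets) offs <- adClamp(offs, -gridStride, gridStride)
  pts <- adAdd(offs, grid$points)
  confLogits <- denseForward(adRelu(denseForward(desc, params$cls1)), params$cls2)
  conf <- adSigmoid(confLogits)
  # segmentation head: all levels to the coarse grid, element-wise sum
  hc <- padded$h %/% coarseScale; wc <- padded$w %/% coarseScale
  agg <- adSumList(lapply(pyr, function(Fm) adResizeBilinear(Fm, hc, wc)))
  fc <- dim(adVal(agg))[3L]
  tok <- adReshape(agg, c(hc * wc, fc))
  segTok <- denseForward(adRelu(denseForward(tok, params$seg1)), params$seg2)
  maskLogits <- adReshape(segTok, c(hc, wc))
  list(points = pts, conf = conf, confLogits = confLogits,
       maskLogits = maskLogits, grid = grid, trace = trace, raw = raw,
       pyramid = pyr, imageSize = c(padded$h, padded$w))
}

#' Raw per-level APG encoder features
#'
#' Runs only the ConvNeXt encoder (no SFI fusion, no heads) and returns
#' the raw per-level features `f_i^C`, used as the auxiliary input to the
#' denoiser's fusion blocks when the multi-task exchange is active.
#'
#' @param x input image (matrix / Micrograph / `H x W x 1` array)
#' @param params from [apgParams()]
#' @return list of `Hi x Wi x C_i` features (nodes when params are nodes)
#' @export
apgEncoderFeatures <- function(x, params) {
  if (is(x, "Micrograph")) x <- x@pixels
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  L <- adVal(params$meta$nLevels)
  mu <- mean(x); sdv <- stats::sd(x); if (!is.finite(sdv) || sdv == 0) sdv <- 1
  padded <- reflectPadTo((x - mu) / sdv, 2L^(L - 1L))
  h <- adRelu(adConv2d(padded$x, params$stem$w, params$stem$b))
  raw <- vector("list", L)
  for (i in seq_len(L)) {
    f <- convnextBlock(h, params$enc[[i]])
    raw[[i]] <- f
    if (i < L) h <- dense2d(adAvgPool2(f), params$enc[[i]]$down)
  }
  raw
}
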