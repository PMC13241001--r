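#' @title Promptable segmentation model
#'
#' @description
#' A small promptable segmenter in the SAM mold, sized so it trains on one
#' CPU: a ViT-style image encoder (patch embedding, learned positional
#' embeddings, transformer blocks with multi-head self-attention), each
#' block followed by a Mona adapter — a parameter-efficient module whose
#' three parallel depthwise convolutions (kernels 3, 5, 7) add multi-scale
#' local detail, and whose zero-initialized up-projection makes it an exact
#' identity at construction; a prompt encoder turning labelled points into
#' Fourier positional embeddings plus label embeddings; mask-prompt fusion
#' by element-wise addition of a projected coarse mask onto the image
#' embedding; and a two-way cross-attention mask decoder with an
#' up-sampling head emitting one binary particle/background mask at input
#' resolution.
#'
#' Fine-tuning freezes the image-encoder backbone and updates only the
#' adapters, the prompt encoder and the mask decoder. The architecture
#' accepts externally obtained encoder weights via [loadEncoderWeights()];
#' nothing in the package requires them.
#'
#' @name promptseg
NULL

#' Create promptable-segmenter parameters
#'
#' @param inputSize fixed square input side (pixels, multiple of patchSize)
#' @param patchSize patch side in pixels
#' @param embedDim token width
#' @param depth number of transformer blocks
#' @param nHeads attention heads (embedDim divisible by nHeads)
#' @param monaDim adapter bottleneck width
#' @return nested parameter list with groups `backbone`, `mona`, `prompt`,
#'   `decoder` (the fine-tuning contract freezes `backbone` only)
#' @export
promptsegParams <- function(inputSize = 192L, patchSize = 8L, embedDim = 64L,
                            depth = 3L, nHeads = 4L, monaDim = 16L) {
  stopifnot(inputSize %% patchSize == 0L, embedDim %% nHeads == 0L)
  g <- inputSize %/% patchSize
  Tn <- g * g
  mkAttn <- function() list(wq = denseParams(embedDim, embedDim),
                            wk = denseParams(embedDim, embedDim),
                            wv = denseParams(embedDim, embedDim),
                            wo = denseParams(embedDim, embedDim))
  blocks <- lapply(seq_len(depth), function(k) list(
    ln1 = lnParams(embedDim), attn = mkAttn(), ln2 = lnParams(embedDim),
    mlp1 = denseParams(embedDim, 4L * embedDim),
    mlp2 = denseParams(4L * embedDim, embedDim)))
  names(blocks) <- paste0("b", seq_len(depth))
  mona <- lapply(seq_len(depth), function(k) list(
    ln = lnParams(embedDim),
    s1 = 1, s2 = 0,
    down = denseParams(embedDim, monaDim),
    dw3 = list(w = initDw(3L, 3L, monaDim)),
    dw5 = list(w = initDw(5L, 5L, monaDim)),
    dw7 = list(w = initDw(7L, 7L, monaDim)),
    up = denseParams(monaDim, embedDim, zero = TRUE)))
  names(mona) <- paste0("b", seq_len(depth))
  set_B <- matrix(stats::rnorm(2L * (embedDim %/% 2L)), 2L, embedDim %/% 2L)
  list(
    backbone = list(
      patch = denseParams(patchSize * patchSize, embedDim),
      pos = matrix(stats::rnorm(Tn * embedDim, sd = 0.02), Tn, embedDim),
      blocks = blocks),
    mona = mona,
    prompt = list(fourier = set_B,
                  proj = denseParams(embedDim, embedDim),
                  label = matrix(stats::rnorm(2L * embedDim, sd = 0.02), 2L, embedDim)),
    decoder = list(
      maskTok = matrix(stats::rnorm(embedDim, sd = 0.02), 1L, embedDim),
      maskProj = denseParams(1L, embedDim, zero = TRUE),
      selfAttn = mkAttn(), lnSelf = lnParams(embedDim),
      t2i = mkAttn(), lnT2i = lnParams(embedDim),
      i2t = mkAttn(), lnI2t = lnParams(embedDim),
      up1 = convParams(3L, 3L, embedDim, 32L),
      up2 = convParams(3L, 3L, 32L, 16L),
      up3 = convParams(3L, 3L, 16L, 8L),
      hyper = denseParams(embedDim, 8L),
      bias = 0),
    meta = list(inputSize = inputSize, patchSize = patchSize,
                embedDim = embedDim, depth = depth, nHeads = nHeads,
                monaDim = monaDim))
}

# multi-head attention: queries from A, keys/values from B (token matrices)
mhAttention <- function(A, B, p, nHeads) {
  e <- ncol(adVal(p$wq$w))
  dh <- e %/% nHeads
  Q <- denseForward(A, p$wq); K <- denseForward(B, p$wk); V <- denseForward(B, p$wv)
  heads <- lapply(seq_len(nHeads), function(h) {
    idx <- (h - 1L) * dh + seq_len(dh)
    Ah <- adSoftmaxRows(adScale(adMatmul(adCols(Q, idx), adCols(K, idx), tb = TRUE),
                                1 / sqrt(dh)))
    adMatmul(Ah, adCols(V, idx))
  })
  denseForward(adCbind(heads), p$wo)
}

# cut a plain H x W image into non-overlapping p x p patch rows
patchify <- function(x, patchSize) {
  H <- nrow(x); W <- ncol(x)
  g <- H %/% patchSize
  gw <- W %/% patchSize
  out <- matrix(0, g * gw, patchSize * patchSize)
  t <- 0L
  for (gy in seq_len(g)) {
    for (gx in seq_len(gw)) {
      t <- t + 1L
      out[t, ] <- x[(gy - 1L) * patchSize + seq_len(patchSize),
                    (gx - 1L) * patchSize + seq_len(patchSize)]
    }
  }
  out
}

#' Mona adapter forward pass
#'
#' `norm -> s1 * norm(F) + s2 * F -> down-projection -> three parallel
#' depthwise convolutions (3, 5, 7) summed -> GELU -> up-projection ->
#' + F`. With the up-projection zero-initialized the block is an exact
#' identity.
#'
#' @param Fi node or `T x C` token matrix
#' @param p one adapter's parameters (see [promptsegParams()])
#' @param gridDims integer (rows, cols) of the token grid; required to
#'   reshape tokens spatially (tokens are row-major over the grid)
#' @return token matrix of the same shape
#' @export
monaForward <- function(Fi, p, gridDims) {
  dmn <- dim(adVal(Fi))
  Tn <- dmn[1L]; C <- dmn[2L]
  if (length(gridDims) != 2L || prod(gridDims) != Tn)
    stop("gridDims must multiply to the token count (non-square grids need explicit dims)")
  z <- adAdd(adScale(adLayerNorm(Fi, p$ln$gamma, p$ln$beta), adVal(p$s1)),
             adScale(Fi, adVal(p$s2)))
  z <- denseForward(z, p$down)
  # tokens are row-major over the grid (x fastest), so the column-major
  # reshape yields a transposed spatial map; depthwise kernels are
  # orientation-free, so this needs no correction
  gr <- gridDims[1L]; gc <- gridDims[2L]
  z2 <- adReshape(z, c(gc, gr, ncol(adVal(z))))
  conv_sum <- adAdd(adAdd(adDwConv2d(z2, p$dw3$w), adDwConv2d(z2, p$dw5$w)),
                    adDwConv2d(z2, p$dw7$w))
  z3 <- adGelu(adReshape(conv_sum, c(Tn, ncol(adVal(z)))))
  adAdd(Fi, denseForward(z3, p$up))
}

#' Encode an image into patch-token embeddings
#'
#' Patch embedding + learned positional embeddings, then transformer
#' blocks each followed by its Mona adapter. Pass `useAdapters = FALSE`
#' for the adapter-free backbone output.
#'
#' @param x plain matrix or [Micrograph-class], resized to the model input
#'   size by the caller ([segForward()] handles this)
#' @param params from [promptsegParams()]
#' @param useAdapters apply Mona adapters between blocks
#' @return `T x embedDim` token matrix (node when params are nodes)
#' @export
encodeImage <- function(x, params, useAdapters = TRUE) {
  if (is(x, "Micrograph")) x <- x@pixels
  meta <- params$meta
  ps <- adVal(meta$patchSize); e <- adVal(meta$embedDim)
  nH <- adVal(meta$nHeads); depth <- adVal(meta$depth)
  g <- nrow(x) %/% ps
  tok <- adBiasAdd(adMatmul(patchify(x, ps), params$backbone$patch$w),
                   params$backbone$patch$b)
  tok <- adAdd(tok, params$backbone$pos)
  for (k in seq_len(depth)) {
    bp <- params$backbone$blocks[[k]]
    a <- adLayerNorm(tok, bp$ln1$gamma, bp$ln1$beta)
    tok <- adAdd(tok, mhAttention(a, a, bp$attn, nH))
    m <- adLayerNorm(tok, bp$ln2$gamma, bp$ln2$beta)
    m <- denseForward(adGelu(denseForward(m, bp$mlp1)), bp$mlp2)
    tok <- adAdd(tok, m)
    if (useAdapters) tok <- monaForward(tok, params$mona[[k]], c(g, g))
  }
  tok
}

#' Encode labelled point prompts
#'
#' Fourier positional features of the normalized coordinates, projected to
#' the embedding width, plus a learned embedding per label (positive = 1,
#' negative = 0). Zero points yield a 0-row matrix (mask-only prompting).
#'
#' @param points n x 2 matrix of (x, y) in model-input pixel space
#' @param labels integer vector, 1 = positive, 0 = negative
#' @param params from [promptsegParams()]
#' @return `n x embedDim` matrix of prompt embeddings
#' @export
encodePrompts <- function(points, labels, params) {
  e <- adVal(params$meta$embedDim)
  n <- if (is.null(points)) 0L else nrow(points)
  if (n == 0L) return(matrix(0, 0L, e))
  if (!all(labels %in% c(0L, 1L))) stop("prompt labels must be 0 (negative) or 1 (positive)")
  S <- adVal(params$meta$inputSize)
  xy <- as.matrix(points) / S
  ang <- 2 * pi * (xy %*% adVal(params$prompt$fourier))
  feats <- cbind(sin(ang), cos(ang))
  emb <- denseForward(feats, params$prompt$proj)
  lab <- adRows(params$prompt$label, labels + 1L)
  adAdd(emb, lab)
}

#' Fuse a coarse mask prompt into the image embedding
#'
#' The mask logits are bilinearly resized to the token grid, projected to
#' the embedding width with a zero-initialized linear map, and added
#' element-wise.
#'
#' @param tokens `T x embedDim` image tokens
#' @param coarseMask numeric matrix of mask logits (any size), or NULL
#' @param params from [promptsegParams()]
#' @return token matrix
#' @export
fuseMaskPrompt <- function(tokens, coarseMask, params) {
  if (is.null(coarseMask)) return(tokens)
  ps <- adVal(params$meta$patchSize)
  g <- as.integer(sqrt(nrow(adVal(tokens))))
  mg <- adResizeBilinear(array(coarseMask, c(dim(coarseMask), 1L)), g, g)
  # token order is row-major (x fastest); map grid is column-major (y fastest)
  mt <- matrix(aperm(adVal(mg), c(2L, 1L, 3L)), g * g, 1L)
  adAdd(tokens, denseForward(mt, params$decoder$maskProj))
}

#' Decode a particle mask from image and prompt embeddings
#'
#' Prompt tokens (points plus a learned mask token) self-attend, then
#' cross-attend with the image tokens in both directions; the up-sampling
#' head restores input resolution and the final logit at each pixel is the
#' inner product of its feature with an MLP of the mask token.
#'
#' @param tokens image tokens (after mask fusion)
#' @param promptEmb `n x embedDim` point-prompt embeddings (may be 0-row
#'   only if a mask was fused)
#' @param params from [promptsegParams()]
#' @param hasMask whether a mask prompt was fused (for the empty check)
#' @return mask logits as an `inputSize x inputSize` matrix (node when
#'   params are nodes)
#' @export
decodeMask <- function(tokens, promptEmb, params, hasMask = TRUE) {
  if (nrow(adVal(promptEmb)) == 0L && !hasMask)
    stop("at least one prompt modality (points or mask) is required")
  d <- params$decoder
  nH <- adVal(params$meta$nHeads)
  ps <- adVal(params$meta$patchSize)
  e <- adVal(params$meta$embedDim)
  g <- as.integer(sqrt(nrow(adVal(tokens))))
  P <- adRbind(list(d$maskTok, promptEmb))
  a <- adLayerNorm(P, d$lnSelf$gamma, d$lnSelf$beta)
  P <- adAdd(P, mhAttention(a, a, d$selfAttn, nH))
  P <- adAdd(P, mhAttention(adLayerNorm(P, d$lnT2i$gamma, d$lnT2i$beta),
                            tokens, d$t2i, nH))
  I <- adAdd(tokens, mhAttention(adLayerNorm(tokens, d$lnI2t$gamma, d$lnI2t$beta),
                                 P, d$i2t, nH))
  # tokens are row-major (x fastest); spatial arrays are column-major
  Im <- adReshape(I, c(g, g, e))      # gives x-fastest layout: dims (x, y, C)
  # GELU rather than ReLU: the head must stay trainable even when early
  # focal pressure drives it strongly negative
  featUp <- adGelu(adConv2d(adUpNearest2(Im), d$up1$w, d$up1$b))
  featUp <- adGelu(adConv2d(adUpNearest2(featUp), d$up2$w, d$up2$b))
  featUp <- adGelu(adConv2d(adUpNearest2(featUp), d$up3$w, d$up3$b))
  S <- g * ps
  featUp <- adResizeBilinear(featUp, S, S)
  hyp <- denseForward(adRows(P, 1L), d$hyper)          # 1 x 8
  logits <- adAdd(adMatmul(adReshape(featUp, c(S * S, 8L)), hyp, tb = TRUE),
                  d$bias)
  # featUp is in (x, y) layout; transpose back to rows = y
  adTransposeM(adReshape(logits, c(S, S)))
}

#' Full segmenter forward pass
#'
#' Resizes the input to the model's square input size, encodes, fuses the
#' mask prompt, decodes, and resizes the logits back to the original
#' image size. Point coordinates are given in original-image pixel space.
#'
#' @param x [Micrograph-class] or matrix (the denoised micrograph)
#' @param points n x 2 point prompts in image pixels (or NULL)
#' @param labels point labels (1 positive / 0 negative)
#' @param coarseMask coarse mask logits (any size, or NULL)
#' @param params from [promptsegParams()]
#' @param useAdapters apply Mona adapters
#' @return mask logits matrix of the original image size (node when
#'   params are nodes)
#' @export
segForward <- function(x, points = NULL, labels = NULL, coarseMask = NULL,
                       params, useAdapters = TRUE) {
  if (is(x, "Micrograph")) x <- x@pixels
  S <- adVal(params$meta$inputSize)
  H <- nrow(x); W <- ncol(x)
  mu <- mean(x); sdv <- stats::sd(x); if (!is.finite(sdv) || sdv == 0) sdv <- 1
  xr <- adVal(adResizeBilinear(array((x - mu) / sdv, c(H, W, 1L)), S, S))[, , 1L]
  pts <- if (!is.null(points) && nrow(points) > 0L) {
    cbind(points[, 1L] * S / W, points[, 2L] * S / H)
  } else NULL
  tok <- encodeImage(xr, params, useAdapters = useAdapters)
  tok <- fuseMaskPrompt(tok, coarseMask, params)
  pe <- encodePrompts(pts, labels, params)
  lg <- decodeMask(tok, pe, params, hasMask = !is.null(coarseMask))
  if (H != S || W != S) {
    lg <- adReshape(adResizeBilinear(adReshape(lg, c(S, S, 1L)), H, W), c(H, W))
  }
  lg
}

#' Install externally obtained encoder weights
#'
#' Replaces the image-encoder backbone with a compatible parameter list
#' (same patch size, width and depth). Intended as the hook for weights
#' converted from a pretrained promptable-segmentation checkpoint; the
#' package never requires such weights.
#'
#' @param params segmenter parameters
#' @param backbone replacement backbone parameter list
#' @return updated parameters
#' @export
loadEncoderWeights <- function(params, backbone) {
  old <- flattenList(paramValues(params$backbone))
  new <- flattenList(rapplyList(backbone, adVal))
  if (!setequal(names(old), names(new)))
    stop("backbone structure mismatch: expected fields ",
         paste(setdiff(names(old), names(new)), collapse = ", "))
  for (nm in names(old)) {
    if (!identical(dim(old[[nm]]), dim(new[[nm]])) &&
        !identical(length(old[[nm]]), length(new[[nm]])))
      stop("backbone field ", nm, " has incompatible shape")
  }
  params$backbone <- backbone
  params
}
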