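#' @title Selective feature integrator (SFI)
#'
#' @description
#' Gated cross-attention fusion between the feature of a main task and the
#' corresponding-level feature of an auxiliary task. The main feature
#' `f_x` queries the (projected, resampled) auxiliary feature `f_y` through
#' single-head cross-attention, giving the fused feature `f_Axy`. A
#' sigmoid "leaky" gate `r` controls how much of the (tanh-squashed) fused
#' content is injected, `f~ = f_x + r * tanh(W f_Axy)`; a sigmoid "memory"
#' gate `z` then mixes convexly, `h = z * f_x + (1 - z) * f~`. The final
#' content projection is zero-initialized, so a freshly constructed block
#' is an exact pass-through (`h == f_x`) — this is what makes the staged
#' warm start of joint training loss-neutral at step 0.
#'
#' Attention runs on a down-sampled token grid (at most `maxTokens` per
#' side) and the attended map is bilinearly up-sampled back, keeping the
#' quadratic attention cost bounded.
#'
#' @name sfi
NULL

#' Create SFI block parameters
#'
#' @param cx main-task channel width
#' @param cy auxiliary-task channel width
#' @param enabled logical; a disabled block returns `f_x` unchanged
#' @return parameter list (`proj`, `wq`, `wk`, `wv`, `gate1`, `gate2`,
#'   `gate3`) plus attributes used by [sfiForward()]
#' @export
sfiParams <- function(cx, cy, enabled = TRUE) {
  list(proj = denseParams(cy, cx),
       wq = denseParams(cx, cx),
       wk = denseParams(cx, cx),
       wv = denseParams(cx, cx),
       gate1 = denseParams(2L * cx, cx),
       gate2 = denseParams(cx, cx, zero = TRUE),
       gate3 = denseParams(2L * cx, cx),
       meta = list(cx = cx, cy = cy, enabled = as.numeric(enabled)))
}

# apply a dense map tokenwise to an H x W x C array
dense2d <- function(x, p) {
  dm <- dim(adVal(x))
  tok <- adReshape(x, c(dm[1L] * dm[2L], dm[3L]))
  out <- denseForward(tok, p)
  adReshape(out, c(dm[1L], dm[2L], ncol(adVal(p$w))))
}

#' Cross-attention fusion of two feature maps
#'
#' Queries come from `f_x`; keys and values from `f_y` after a 1x1 channel
#' projection and bilinear resampling to `f_x`'s grid. Attention weights
#' are a row-softmax over auxiliary positions (each query's weights sum
#' to 1). Output has `f_x`'s shape.
#'
#' @param fx node or `H x W x Cx` array (main feature)
#' @param fy node or `Hy x Wy x Cy` array (auxiliary feature)
#' @param p parameters from [sfiParams()]
#' @param maxTokens attention grid bound per side
#' @param returnAttention also return the attention matrix (plain value)
#' @return fused feature (same shape as `fx`); with
#'   `returnAttention = TRUE`, a list `(fused, attention)`
#' @export
crossAttentionFuse <- function(fx, fy, p, maxTokens = 32L, returnAttention = FALSE) {
  dmx <- dim(adVal(fx))
  H <- dmx[1L]; W <- dmx[2L]; Cx <- dmx[3L]
  dmy <- dim(adVal(fy))
  if (ncol(adVal(p$proj$w)) != Cx || nrow(adVal(p$proj$w)) != dmy[3L])
    stop("SFI projection dims incompatible with peer feature")
  fyp <- dense2d(fy, p$proj)
  fyp <- adResizeBilinear(fyp, H, W)
  ha <- min(H, maxTokens); wa <- min(W, maxTokens)
  fxs <- adResizeBilinear(fx, ha, wa)
  fys <- adResizeBilinear(fyp, ha, wa)
  Tn <- ha * wa
  Q <- denseForward(adReshape(fxs, c(Tn, Cx)), p$wq)
  K <- denseForward(adReshape(fys, c(Tn, Cx)), p$wk)
  V <- denseForward(adReshape(fys, c(Tn, Cx)), p$wv)
  A <- adSoftmaxRows(adScale(adMatmul(Q, K, tb = TRUE), 1 / sqrt(Cx)))
  Y <- adMatmul(A, V)
  fA <- adResizeBilinear(adReshape(Y, c(ha, wa, Cx)), H, W)
  if (returnAttention) list(fused = fA, attention = adVal(A)) else fA
}

#' SFI forward pass
#'
#' Computes `f_Axy` by cross-attention, then
#' `r = sigmoid(G1([f_x, f_Axy]))`,
#' `f~ = f_x + r * tanh(G2(f_Axy))`,
#' `z = sigmoid(G3([f_x, f~]))`,
#' `h = z * f_x + (1 - z) * f~`.
#' A disabled block (or `p = NULL`) returns `f_x` unchanged.
#'
#' @param fx main-task feature (node or array)
#' @param fy auxiliary-task feature (node or array; ignored when disabled)
#' @param p parameters from [sfiParams()] or NULL
#' @param maxTokens attention grid bound
#' @return fused feature `h`, same shape as `fx`
#' @export
sfiForward <- function(fx, fy, p, maxTokens = 32L) {
  if (is.null(p) || adVal(p$meta$enabled) == 0) return(fx)
  dmx <- dim(adVal(fx))
  fA <- crossAttentionFuse(fx, fy, p, maxTokens)
  both <- adConcatChannels(list(fx, fA))
  r <- adSigmoid(dense2d(both, p$gate1))
  content <- adTanh(dense2d(fA, p$gate2))
  ftilde <- adAdd(fx, adMul(r, content))
  z <- adSigmoid(dense2d(adConcatChannels(list(fx, ftilde)), p$gate3))
  # z * f_x + (1 - z) * f~, written so the pass-through case is bitwise exact
  adAdd(fx, adMul(adSub(1, z), adSub(ftilde, fx)))
}
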