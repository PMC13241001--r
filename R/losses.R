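#' @title Training losses
#' @description
#' The detection losses for the prompt generator (Smooth-L1 regression on
#' matched points, weighted binary cross-entropy on confidences, focal loss
#' on the coarse mask, and their weighted combination), the Noise2Noise MSE
#' for the denoiser, and the focal+dice objective for the promptable
#' segmenter. Each function has a plain-numeric form (used by the tests'
#' scalar oracles and for reporting) and participates in the autodiff graph
#' when handed nodes.
#' @name losses
NULL

#' Noise2Noise loss: mean squared error between prediction and the paired
#' independent observation
#'
#' @param pred node or numeric array
#' @param target numeric array of the same shape
#' @return scalar (node if `pred` is a node)
#' @export
n2nLoss <- function(pred, target) {
  if (is(pred, "Micrograph")) pred <- pred@pixels
  if (is(target, "Micrograph")) target <- target@pixels
  stopifnot(identical(dim(adVal(pred)), dim(adVal(target))))
  adMean(adSquare(adSub(pred, target)))
}

#' Smooth-L1 (Huber) value, elementwise
#'
#' `0.5 e^2` for `|e| < 1`, `|e| - 0.5` otherwise.
#'
#' @param e numeric error(s)
#' @return numeric of the same length
#' @export
smoothL1 <- function(e) {
  a <- abs(e)
  ifelse(a < 1, 0.5 * e * e, a - 0.5)
}

# autodiff-aware elementwise smooth-L1 on a node of errors
adSmoothL1 <- function(e) {
  un_op(e,
    function(x) { a <- abs(x); ifelse(a < 1, 0.5 * x * x, a - 0.5) },
    function(g, x, v) g * ifelse(abs(x) < 1, x, sign(x)))
}

#' Regression loss over matched point pairs
#'
#' Smooth-L1 applied per coordinate (x and y) and summed, then averaged
#' over the N matched points.
#'
#' @param predMatched node or N x 2 matrix of matched predicted points
#' @param gt N x 2 matrix of ground-truth points
#' @return scalar (node if input is a node)
#' @export
regLoss <- function(predMatched, gt) {
  N <- nrow(adVal(predMatched))
  if (N == 0L) return(0)
  adScale(adSum(adSmoothL1(adSub(predMatched, gt))), 1 / N)
}

#' Weighted binary cross-entropy over confidences
#'
#' `-(1/M) { sum_matched log(chat) + alpha * sum_unmatched log(1 - chat) }`
#' with matched predictions as positives and all unmatched predictions as
#' negatives. Confidences are clipped to `[eps, 1 - eps]`.
#'
#' @param conf node or length-M vector / M x 1 matrix of confidences
#' @param matchedIdx integer indices of the matched (positive) predictions
#' @param alpha negative-class weight
#' @param eps clipping constant (default 1e-7)
#' @return scalar (node if `conf` is a node)
#' @export
clsLoss <- function(conf, matchedIdx, alpha, eps = 1e-7) {
  v <- adVal(conf)
  M <- length(v)
  if (M == 0L) return(0)
  cm <- if (is.matrix(v)) conf else adReshape(conf, c(M, 1L))
  cm <- adClamp(cm, eps, 1 - eps)
  neg_idx <- setdiff(seq_len(M), matchedIdx)
  terms <- list()
  if (length(matchedIdx)) {
    terms <- c(terms, list(adSum(adLog(adRows(cm, matchedIdx)))))
  }
  if (length(neg_idx)) {
    one_minus <- adSub(1, adRows(cm, neg_idx))
    # adSub(1, node): scalar-first broadcast
    terms <- c(terms, list(adScale(adSum(adLog(one_minus)), alpha)))
  }
  adScale(adSumList(terms), -1 / M)
}

#' Binary focal loss on mask logits
#'
#' `FL(p_t) = -alpha_f * (1 - p_t)^gamma_f * log(p_t)`, averaged over
#' pixels, with `p_t = p` on positives and `1 - p` on negatives.
#'
#' @param logits node or numeric array of mask logits
#' @param gtMask binary array of the same shape
#' @param focalAlpha positive-class weight `alpha_f`
#' @param focalGamma focusing exponent `gamma_f`
#' @return scalar (node if `logits` is a node)
#' @export
segFocalLoss <- function(logits, gtMask, focalAlpha = 0.25, focalGamma = 2) {
  m <- as.numeric(adVal(gtMask))
  dm <- dim(adVal(logits))
  if (is.null(dm)) dm <- length(adVal(logits))
  mArr <- array(m, dm)
  p <- adSigmoid(logits)
  # -log p_t written through softplus so gradients survive saturation:
  # -log sigmoid(z) = softplus(-z), -log(1 - sigmoid(z)) = softplus(z)
  nlpPos <- adSoftplus(adScale(logits, -1))
  nlpNeg <- adSoftplus(logits)
  fl <- adAdd(adMul(adMul(adPow(adSub(1, p), focalGamma), nlpPos), mArr),
              adMul(adMul(adPow(p, focalGamma), nlpNeg), 1 - mArr))
  adScale(adMean(fl), focalAlpha)
}

#' Combined prompt-generator loss
#'
#' `lambda1 * L_reg + lambda2 * L_cls + lambda3 * L_seg`.
#'
#' @param lossReg,lossCls,lossSeg component losses (scalars or nodes)
#' @param lambda numeric length-3 weights
#' @return scalar (node when any component is a node)
#' @export
apgLoss <- function(lossReg, lossCls, lossSeg, lambda = c(2, 1, 1)) {
  adSumList(list(adScale(lossReg, lambda[1L]),
                 adScale(lossCls, lambda[2L]),
                 adScale(lossSeg, lambda[3L])))
}

#' Soft Dice loss
#'
#' `1 - (2 * sum(p * m) + s) / (sum(p) + sum(m) + s)` with probabilities
#' `p = sigmoid(logits)` and smoothing `s = 1`.
#'
#' @param logits node or array of logits
#' @param gtMask binary array
#' @param smooth smoothing constant
#' @return scalar (node if `logits` is a node)
#' @export
diceLoss <- function(logits, gtMask, smooth = 1) {
  p <- adSigmoid(logits)
  dm <- dim(adVal(logits))
  if (is.null(dm)) dm <- length(adVal(logits))
  m <- array(as.numeric(adVal(gtMask)), dm)
  inter <- adSum(adMul(p, m))
  denom <- adAdd(adSum(p), sum(m))
  adSub(1, adMul(adAdd(adScale(inter, 2), smooth),
                 adPow(adAdd(denom, smooth), -1)))
}

#' Segmenter fine-tuning loss: `lambda_f * focal + dice`
#'
#' @param logits node or array of predicted mask logits
#' @param gtMask binary ground-truth mask (same shape)
#' @param lambdaF focal weight
#' @param focalAlpha,focalGamma focal parameters
#' @return scalar (node if `logits` is a node)
#' @export
samLoss <- function(logits, gtMask, lambdaF = 20, focalAlpha = 0.25, focalGamma = 2) {
  adAdd(adScale(segFocalLoss(logits, gtMask, focalAlpha, focalGamma), lambdaF),
        diceLoss(logits, gtMask))
}
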