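#' @title Evaluation metrics
#' @description
#' Picking metrics (precision/recall/F1 with unique matching at IoU > 0.5
#' between boxes centred on coordinates), the Dice overlap for masks, and
#' a region-pair SNR estimate that needs no clean reference.
#' @name metrics
NULL

boxIoU <- function(a, b, d) {
  # a, b: (x, y) centres; d: box side
  ix <- pmax(0, pmin(a[1L], b[1L]) + d - pmax(a[1L], b[1L]))
  iy <- pmax(0, pmin(a[2L], b[2L]) + d - pmax(a[2L], b[2L]))
  inter <- ix * iy
  inter / (2 * d * d - inter)
}

circleIoU <- function(a, b, d) {
  r <- d / 2
  dist <- sqrt(sum((a - b)^2))
  if (dist >= 2 * r) return(0)
  if (dist == 0) return(1)
  lens <- 2 * r^2 * acos(dist / (2 * r)) - dist / 2 * sqrt(4 * r^2 - dist^2)
  lens / (2 * pi * r^2 - lens)
}

#' Precision, recall and F1 for particle picking
#'
#' Boxes of side `diameter` are centred on each coordinate; predictions
#' and ground truth are uniquely matched greedily in descending IoU order
#' and a pair counts as a true positive only when its IoU strictly exceeds
#' `iouThreshold`. Empty-set conventions: if both sets are empty all three
#' metrics are 1; if only predictions are empty, precision is 0.
#'
#' @param pred [ParticleSet-class] (or n x 2 matrix) of predictions
#' @param gt [ParticleSet-class] (or n x 2 matrix) of ground truth
#' @param diameter box side in pixels (> 0)
#' @param iouThreshold match threshold (default 0.5, strict inequality)
#' @param shape `"square"` (axis-aligned boxes) or `"circle"`
#' @return list with `precision`, `recall`, `f1`, `tp`, `fp`, `fn`
#' @export
evalPicking <- function(pred, gt, diameter, iouThreshold = 0.5,
                        shape = c("square", "circle")) {
  shape <- match.arg(shape)
  if (diameter <= 0) stop("diameter must be positive")
  P <- if (is(pred, "ParticleSet")) pred@coords else as.matrix(pred)
  G <- if (is(gt, "ParticleSet")) gt@coords else as.matrix(gt)
  np <- nrow(P); ng <- nrow(G)
  if (np == 0L && ng == 0L) {
    return(list(precision = 1, recall = 1, f1 = 1, tp = 0L, fp = 0L, fn = 0L))
  }
  tp <- 0L
  if (np > 0L && ng > 0L) {
    iouFun <- if (shape == "square") boxIoU else circleIoU
    ious <- matrix(0, np, ng)
    for (i in seq_len(np)) for (j in seq_len(ng)) {
      ious[i, j] <- iouFun(P[i, ], G[j, ], diameter)
    }
    usedP <- logical(np); usedG <- logical(ng)
    ord <- order(ious, decreasing = TRUE)
    for (k in ord) {
      if (ious[k] <= iouThreshold) break
      i <- (k - 1L) %% np + 1L; j <- (k - 1L) %/% np + 1L
      if (usedP[i] || usedG[j]) next
      usedP[i] <- TRUE; usedG[j] <- TRUE
      tp <- tp + 1L
    }
  }
  fp <- np - tp; fn <- ng - tp
  precision <- if (np > 0L) tp / np else 0
  recall <- if (ng > 0L) tp / ng else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall, f1 = f1,
       tp = tp, fp = fp, fn = fn)
}

#' Dice overlap of two binary masks
#'
#' `2 |A and B| / (|A| + |B|)`; 1 when both masks are empty.
#'
#' @param a,b binary matrices of equal shape
#' @return Dice score in `[0, 1]`
#' @export
diceScore <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  a <- a > 0.5; b <- b > 0.5
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

#' Region-pair SNR estimate (dB)
#'
#' For each (signal ROI, background ROI) pair: the background ROI supplies
#' mean `mu_b` and variance `v_b`; the signal amplitude is
#' `s = mean(signal ROI) - mu_b`; the pair contributes
#' `10 log10(s^2 / v_b)`. The average over pairs is returned. ROIs are
#' 0-based inclusive pixel rectangles `c(x0, y0, x1, y1)`.
#'
#' @param image [Micrograph-class] or matrix
#' @param regionPairs list of `list(signal = c(x0,y0,x1,y1),
#'   background = c(x0,y0,x1,y1))`
#' @return mean SNR over pairs, in dB
#' @export
snrPairedRegions <- function(image, regionPairs) {
  if (is(image, "Micrograph")) image <- image@pixels
  if (length(regionPairs) < 1L) stop("at least one region pair is required")
  H <- nrow(image); W <- ncol(image)
  roiPix <- function(r) {
    if (r[1L] < 0 || r[2L] < 0 || r[3L] >= W || r[4L] >= H || r[3L] < r[1L] || r[4L] < r[2L])
      stop("ROI out of bounds or degenerate")
    image[(r[2L]:r[4L]) + 1L, (r[1L]:r[3L]) + 1L]
  }
  vals <- vapply(regionPairs, function(pr) {
    sg <- roiPix(pr$signal); bg <- roiPix(pr$background)
    vb <- stats::var(as.vector(bg))
    if (!is.finite(vb) || vb == 0) stop("background ROI has zero variance")
    s <- mean(sg) - mean(bg)
    if (s == 0) stop("signal amplitude is zero in a region pair")
    10 * log10(s * s / vb)
  }, numeric(1L))
  mean(vals)
}

#' Region pairs for a synthetic scene
#'
#' Signal ROIs are squares centred on the known particle centres;
#' background ROIs are squares centred on the grid point farthest from all
#' particles (one per signal ROI).
#'
#' @param scene a [SyntheticScene-class]
#' @param half half-side of each ROI in pixels
#' @param nPairs number of pairs (capped at the particle count)
#' @return list of region pairs for [snrPairedRegions()]
#' @export
sceneRegionPairs <- function(scene, half = 3L, nPairs = 8L) {
  ctr <- scene@centers
  H <- nrow(scene@clean); W <- ncol(scene@clean)
  n <- min(nPairs, nrow(ctr))
  if (n == 0L) stop("scene has no particles")
  gx <- seq(half, W - 1L - half, by = 2L * half + 1L)
  gy <- seq(half, H - 1L - half, by = 2L * half + 1L)
  cand <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
  dmin <- apply(cand, 1L, function(p) min(sqrt((ctr[, 1L] - p[1L])^2 + (ctr[, 2L] - p[2L])^2)))
  bg <- cand[which.max(dmin), ]
  bgRoi <- c(bg[1L] - half, bg[2L] - half, bg[1L] + half, bg[2L] + half)
  lapply(seq_len(n), function(k) {
    cx <- round(ctr[k, 1L]); cy <- round(ctr[k, 2L])
    cx <- min(max(cx, half), W - 1L - half)
    cy <- min(max(cy, half), H - 1L - half)
    list(signal = c(cx - half, cy - half, cx + half, cy + half),
         background = bgRoi)
  })
}
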