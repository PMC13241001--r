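#' @title U-Net image denoiser
#'
#' @description
#' A small U-Net encoder-decoder trained unsupervised with the Noise2Noise
#' objective: the network maps one noisy observation of a micrograph to the
#' paired independent observation of the same signal, and the MSE minimizer
#' approaches the clean image. Each encoder level exposes its (optionally
#' SFI-fused) feature for exchange with the prompt-generator encoder; the
#' decoder mirrors the encoder with nearest-neighbour up-sampling and skip
#' connections and carries no fusion blocks. Inputs are standardized to
#' zero mean / unit variance per micrograph and destandardized on output;
#' the network learns the residual on the standardized scale.
#'
#' @name denoiser
NULL

#' Create denoiser parameters
#'
#' @param nLevels encoder depth (>= 2)
#' @param baseChannels channels at level 1
#' @param channelGrowth per-level width multiplier
#' @return nested parameter list
#' @export
denoiserParams <- function(nLevels = 3L, baseChannels = 16L, channelGrowth = 2) {
  stopifnot(nLevels >= 2L)
  ch <- as.integer(round(baseChannels * channelGrowth^(seq_len(nLevels) - 1L)))
  enc <- vector("list", nLevels)
  cin <- 1L
  for (i in seq_len(nLevels)) {
    enc[[i]] <- list(conv1 = convParams(3L, 3L, cin, ch[i]),
                     conv2 = convParams(3L, 3L, ch[i], ch[i]))
    cin <- ch[i]
  }
  names(enc) <- paste0("l", seq_len(nLevels))
  dec <- vector("list", nLevels - 1L)
  for (i in seq_len(nLevels - 1L)) {
    lev <- nLevels - i                      # decoder step i outputs level `lev` size
    cat_in <- ch[lev + 1L] + ch[lev]
    dec[[i]] <- list(conv1 = convParams(3L, 3L, cat_in, ch[lev]),
                     conv2 = convParams(3L, 3L, ch[lev], ch[lev]))
  }
  names(dec) <- paste0("d", seq_len(nLevels - 1L))
  list(enc = enc, dec = dec, out = convParams(1L, 1L, ch[1L], 1L, zero = TRUE),
       meta = list(nLevels = nLevels, channels = ch))
}

#' Channel widths of a denoiser
#' @param params from [denoiserParams()]
#' @keywords internal
denoiserChannels <- function(params) as.integer(round(adVal(params$meta$channels)))

#' Denoiser forward pass
#'
#' @param x input: [Micrograph-class], plain `H x W` matrix or `H x W x 1`
#'   array (already standardized if `standardize = FALSE`)
#' @param params from [denoiserParams()]
#' @param peerFeatures optional list of per-level auxiliary features
#'   (`f_i^C` from the prompt-generator encoder) for SFI fusion
#' @param sfiBlocks optional list of per-level [sfiParams()] blocks
#'   (direction: denoiser main, APG auxiliary)
#' @param maxTokens SFI attention bound
#' @param standardize standardize input / destandardize output
#' @return list with `out` (denoised, same H x W as input) and `trace`
#'   (list of per-level encoder features `h_i^U`, fused when SFI active)
#' @export
denoiserForward <- function(x, params, peerFeatures = NULL, sfiBlocks = NULL,
                            maxTokens = 32L, standardize = TRUE) {
  if (is(x, "Micrograph")) x <- x@pixels
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  L <- adVal(params$meta$nLevels)
  mu <- 0; sdv <- 1
  if (standardize) {
    mu <- mean(x); sdv <- stats::sd(x)
    if (!is.finite(sdv) || sdv == 0) sdv <- 1
    x <- (x - mu) / sdv
  }
  padded <- reflectPadTo(x, 2L^(L - 1L))
  h <- padded$x
  trace <- vector("list", L)
  raw <- vector("list", L)
  for (i in seq_len(L)) {
    f <- adRelu(adConv2d(h, params$enc[[i]]$conv1$w, params$enc[[i]]$conv1$b))
    f <- adRelu(adConv2d(f, params$enc[[i]]$conv2$w, params$enc[[i]]$conv2$b))
    raw[[i]] <- f
    if (!is.null(peerFeatures) && !is.null(peerFeatures[[i]])) {
      peer <- peerFeatures[[i]]
      if (!identical(dim(adVal(peer))[1:2], dim(adVal(f))[1:2]))
        stop("peer feature at level ", i, " has mismatched spatial dims")
      f <- sfiForward(f, peer, if (is.null(sfiBlocks)) NULL else sfiBlocks[[i]],
                      maxTokens = maxTokens)
    }
    trace[[i]] <- f
    if (i < L) h <- adAvgPool2(f)
  }
  d <- trace[[L]]
  for (s in seq_len(L - 1L)) {
    lev <- L - s
    up <- adUpNearest2(d)
    d <- adConcatChannels(list(up, trace[[lev]]))
    d <- adRelu(adConv2d(d, params$dec[[s]]$conv1$w, params$dec[[s]]$conv1$b))
    d <- adRelu(adConv2d(d, params$dec[[s]]$conv2$w, params$dec[[s]]$conv2$b))
  }
  res <- adConv2d(d, params$out$w, params$out$b)
  out <- adAdd(adReshape(adCrop(res, padded$h, padded$w),
                         c(padded$h, padded$w, 1L)),
               array(x[seq_len(padded$h), seq_len(padded$w), 1L],
                     c(padded$h, padded$w, 1L)))
  if (standardize) out <- adAdd(adScale(out, sdv), mu)
  list(out = out, trace = trace, raw = raw)
}

#' Denoise a micrograph with trained parameters
#'
#' @param x [Micrograph-class] or matrix
#' @param params trained denoiser parameters
#' @return a [Micrograph-class] with the denoised pixels
#' @export
denoiseMicrograph <- function(x, params) {
  mg <- if (is(x, "Micrograph")) x else Micrograph(as.matrix(x))
  out <- denoiserForward(mg@pixels, paramValues(params))$out
  Micrograph(matrix(adVal(out), nrow(mg@pixels), ncol(mg@pixels)),
             pixelSize = mg@pixelSize,
             id = if (nzchar(mg@id)) paste0(mg@id, "_denoised") else "denoised")
}

#' Train the denoiser with the Noise2Noise objective
#'
#' Each step samples a pair and an aligned random patch from both members;
#' both orientations (even to odd, odd to even) are used as training
#' samples. Training aborts on non-finite loss.
#'
#' @param pairs list of [NoisyPair-class]
#' @param params initial parameters from [denoiserParams()]
#' @param steps number of optimization steps
#' @param lr Adam learning rate
#' @param patch training patch side (pixels)
#' @param seed RNG seed controlling patch sampling
#' @param verboseEvery print smoothed loss every this many steps (0 = quiet)
#' @return list with trained `params`, the per-step `lossTrace`, and the
#'   terminal smoothed loss `finalLoss`
#' @export
trainDenoiser <- function(pairs, params, steps = 300L, lr = 2e-3, patch = 64L,
                          seed = 1L, verboseEvery = 0L) {
  stopifnot(length(pairs) >= 1L)
  opt <- adamInit(paramValues(params), lr = lr)
  pv <- paramValues(params)
  set.seed(as.integer(abs(seed) %% 2147483647))
  losses <- numeric(steps)
  for (s in seq_len(steps)) {
    pr <- pairs[[sample.int(length(pairs), 1L)]]
    a <- pr@even@pixels; b <- pr@odd@pixels
    if (stats::runif(1) < 0.5) { tmp <- a; a <- b; b <- tmp }  # symmetrize
    H <- nrow(a); W <- ncol(a)
    ph <- min(patch, H); pw <- min(patch, W)
    r0 <- sample.int(H - ph + 1L, 1L); c0 <- sample.int(W - pw + 1L, 1L)
    ain <- a[r0:(r0 + ph - 1L), c0:(c0 + pw - 1L)]
    bt <- b[r0:(r0 + ph - 1L), c0:(c0 + pw - 1L)]
    mu <- mean(ain); sdv <- stats::sd(ain); if (sdv == 0) sdv <- 1
    adTapeStart()
    w <- wrapParams(pv)
    fwd <- denoiserForward(array((ain - mu) / sdv, c(ph, pw, 1L)), w,
                           standardize = FALSE)
    loss <- n2nLoss(fwd$out, array((bt - mu) / sdv, c(ph, pw, 1L)))
    lv <- adVal(loss)
    if (!is.finite(lv)) stop("denoiser training diverged (non-finite loss) at step ", s)
    adBackward(loss)
    upd <- adamStep(pv, w, opt)
    pv <- upd$params; opt <- upd$opt
    adTapeStop()
    losses[s] <- lv
    if (verboseEvery > 0L && s %% verboseEvery == 0L) {
      message(sprintf("denoiser step %d/%d  loss %.5f", s, steps,
                      mean(losses[max(1L, s - 24L):s])))
    }
  }
  list(params = pv, lossTrace = losses,
       finalLoss = mean(losses[max(1L, steps - 24L):steps]))
}
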