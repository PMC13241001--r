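#' @title Spatial network operations
#' @description
#' Convolution, pooling and resampling primitives on `H x W x C` arrays.
#' The dense and depthwise convolutions call the package's compiled
#' kernels (src/conv.cpp: im2col + BLAS, shift-accumulate); pooling and
#' the separable bilinear resize are vectorized R. Each op is
#' autodiff-aware via the node protocol in `R/autodiff.R`.
#' @name nn-ops
#' @keywords internal
NULL

#' 2-D convolution, stride 1, zero 'same' padding
#'
#' @param x node or `H x W x Cin` array
#' @param w node or `kh x kw x Cin x Cout` kernel
#' @param b node or length-`Cout` bias (or NULL)
#' @keywords internal
adConv2d <- function(x, w, b = NULL) {
  vx <- adVal(x); vw <- adVal(w)
  dm <- dim(vx); kd <- dim(vw)
  H <- dm[1L]; W <- dm[2L]; Cin <- dm[3L]
  kh <- kd[1L]; kw <- kd[2L]; Cout <- kd[4L]
  stopifnot(kd[3L] == Cin)
  wm <- aperm(vw, c(3L, 1L, 2L, 4L))
  v <- cpp_conv2d(vx, wm, H, W, Cin, kh, kw, Cout)
  if (!is.null(b)) v <- v + rep(adVal(b), each = H * W)
  if (!isNode(x) && !isNode(w) && !isNode(b)) return(v)
  newNode(v, list(x, w, b), function(n) {
    g <- n$g
    if (isNode(b)) accGrad(b, colSums(matrix(g, H * W, Cout)))
    bw <- cpp_conv2d_bwd(adVal(x), wm, g, H, W, Cin, kh, kw, Cout,
                         isNode(x), isNode(w))
    if (isNode(w)) {
      accGrad(w, aperm(array(bw$gw, c(Cin, kh, kw, Cout)), c(2L, 3L, 1L, 4L)))
    }
    if (isNode(x)) accGrad(x, bw$gx)
  })
}

#' Depthwise 2-D convolution, stride 1, zero 'same' padding
#'
#' One `kh x kw` filter per channel (the spatial half of a depthwise
#' separable convolution).
#' @param x node or `H x W x C` array
#' @param w node or `kh x kw x C` kernel
#' @param b node or length-C bias (or NULL)
#' @keywords internal
adDwConv2d <- function(x, w, b = NULL) {
  vx <- adVal(x); vw <- adVal(w)
  dm <- dim(vx); kd <- dim(vw)
  H <- dm[1L]; W <- dm[2L]; C <- dm[3L]
  kh <- kd[1L]; kw <- kd[2L]
  stopifnot(kd[3L] == C)
  v <- cpp_dwconv(vx, vw, H, W, C, kh, kw)
  if (!is.null(b)) v <- v + rep(adVal(b), each = H * W)
  if (!isNode(x) && !isNode(w) && !isNode(b)) return(v)
  newNode(v, list(x, w, b), function(n) {
    g <- n$g
    if (isNode(b)) accGrad(b, colSums(matrix(g, H * W, C)))
    bw <- cpp_dwconv_bwd(adVal(x), vw, g, H, W, C, kh, kw,
                         isNode(x), isNode(w))
    if (isNode(w)) accGrad(w, bw$gw)
    if (isNode(x)) accGrad(x, bw$gx)
  })
}

#' 2x2 average pooling, stride 2
#' @param x node or `H x W x C` array, H and W even
#' @keywords internal
adAvgPool2 <- function(x) {
  vx <- adVal(x)
  dm <- dim(vx)
  H <- dm[1L]; W <- dm[2L]; C <- dm[3L]
  stopifnot(H %% 2L == 0L, W %% 2L == 0L)
  i1 <- seq(1L, H, by = 2L); i2 <- i1 + 1L
  j1 <- seq(1L, W, by = 2L); j2 <- j1 + 1L
  fwd <- function(z) 0.25 * (z[i1, j1, , drop = FALSE] + z[i2, j1, , drop = FALSE] +
                             z[i1, j2, , drop = FALSE] + z[i2, j2, , drop = FALSE])
  un_op(x, fwd, function(g, z, v) {
    gx <- array(0, dm)
    gq <- 0.25 * g
    gx[i1, j1, ] <- gq; gx[i2, j1, ] <- gq
    gx[i1, j2, ] <- gq; gx[i2, j2, ] <- gq
    gx
  })
}

#' Nearest-neighbour 2x upsampling
#' @param x node or `H x W x C` array
#' @keywords internal
adUpNearest2 <- function(x) {
  vx <- adVal(x)
  dm <- dim(vx)
  H <- dm[1L]; W <- dm[2L]
  ri <- rep(seq_len(H), each = 2L)
  rj <- rep(seq_len(W), each = 2L)
  un_op(x,
    function(z) z[ri, rj, , drop = FALSE],
    function(g, z, v) {
      i1 <- seq(1L, 2L * H, by = 2L); j1 <- seq(1L, 2L * W, by = 2L)
      g[i1, j1, , drop = FALSE] + g[i1 + 1L, j1, , drop = FALSE] +
        g[i1, j1 + 1L, , drop = FALSE] + g[i1 + 1L, j1 + 1L, , drop = FALSE]
    })
}

# separable bilinear interpolation matrix mapping `n_in` samples to `n_out`,
# aligned so that cell centres map linearly (align_corners = FALSE convention)
bilinearMatrix <- function(n_out, n_in) {
  if (n_out == n_in) return(diag(n_in))
  pos <- ((seq_len(n_out) - 0.5) * n_in / n_out) - 0.5
  pos <- pmin(pmax(pos, 0), n_in - 1L)
  lo <- pmin(floor(pos), n_in - 1L)
  hi <- pmin(lo + 1L, n_in - 1L)
  whi <- pos - lo
  M <- matrix(0, n_out, n_in)
  idx <- seq_len(n_out)
  M[cbind(idx, lo + 1L)] <- M[cbind(idx, lo + 1L)] + (1 - whi)
  M[cbind(idx, hi + 1L)] <- M[cbind(idx, hi + 1L)] + whi
  M
}

#' Bilinear resize of an `H x W x C` array to `oh x ow`
#' @param x node or array
#' @param oh,ow output spatial dims
#' @keywords internal
adResizeBilinear <- function(x, oh, ow) {
  vx <- adVal(x)
  dm <- dim(vx)
  H <- dm[1L]; W <- dm[2L]; C <- dm[3L]
  if (H == oh && W == ow) return(if (isNode(x)) x else vx)
  Rh <- bilinearMatrix(oh, H)
  Rw <- t(bilinearMatrix(ow, W))
  fwd <- function(z) {
    out <- array(0, c(oh, ow, C))
    for (c in seq_len(C)) out[, , c] <- Rh %*% z[, , c] %*% Rw
    out
  }
  un_op(x, fwd, function(g, z, v) {
    gx <- array(0, dm)
    for (c in seq_len(C)) gx[, , c] <- crossprod(Rh, g[, , c]) %*% t(Rw)
    gx
  })
}

# sparse M x (Hi*Wi) bilinear sampling operator for points (x, y) given in
# 0-based level coordinates; points are clamped to the valid border
bilinearGatherOp <- function(pts, Hi, Wi) {
  px <- pmin(pmax(pts[, 1L], 0), Wi - 1L)
  py <- pmin(pmax(pts[, 2L], 0), Hi - 1L)
  x0 <- pmin(floor(px), Wi - 1L); x1 <- pmin(x0 + 1L, Wi - 1L)
  y0 <- pmin(floor(py), Hi - 1L); y1 <- pmin(y0 + 1L, Hi - 1L)
  fx <- px - x0; fy <- py - y0
  M <- nrow(pts)
  # column-major cell index for (y, x): y + 1 + Hi * x
  cell <- function(y, x) y + 1L + Hi * x
  i <- rep(seq_len(M), 4L)
  j <- c(cell(y0, x0), cell(y1, x0), cell(y0, x1), cell(y1, x1))
  w <- c((1 - fy) * (1 - fx), fy * (1 - fx), (1 - fy) * fx, fy * fx)
  Matrix::sparseMatrix(i = i, j = j, x = w, dims = c(M, Hi * Wi))
}

#' Sample a feature map at fractional points by bilinear interpolation
#'
#' @param Fmap node or `Hi x Wi x C` array
#' @param pts `M x 2` matrix of 0-based (x, y) level coordinates
#' @return `M x C` matrix (or node)
#' @keywords internal
adGatherBilinear <- function(Fmap, pts) {
  vF <- adVal(Fmap)
  dm <- dim(vF)
  G <- bilinearGatherOp(pts, dm[1L], dm[2L])
  fwd <- function(z) as.matrix(G %*% matrix(z, dm[1L] * dm[2L], dm[3L]))
  un_op(Fmap, fwd, function(g, z, v)
    array(as.matrix(Matrix::crossprod(G, g)), dm))
}

#' Reflect-pad a plain `H x W x C` array so both spatial dims are multiples
#' of `m` (used on network inputs; outputs are cropped back)
#' @param x plain array
#' @param m divisor
#' @return list(x = padded array, h, w = original dims)
#' @keywords internal
reflectPadTo <- function(x, m) {
  dm <- dim(x)
  H <- dm[1L]; W <- dm[2L]
  ph <- (m - H %% m) %% m
  pw <- (m - W %% m) %% m
  if (ph == 0L && pw == 0L) return(list(x = x, h = H, w = W))
  out <- array(0, c(H + ph, W + pw, dm[3L]))
  out[seq_len(H), seq_len(W), ] <- x
  if (ph > 0L) out[H + seq_len(ph), seq_len(W), ] <- x[H - seq_len(ph), seq_len(W), ]
  if (pw > 0L) out[, W + seq_len(pw), ] <- out[, W - seq_len(pw), ]
  list(x = out, h = H, w = W)
}
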