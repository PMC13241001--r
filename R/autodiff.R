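#' @title Reverse-mode automatic differentiation engine
#'
#' @description
#' A compact tape-based reverse-mode autodiff engine used to train every
#' network in the package on CPU. Values are plain R arrays (images as
#' `H x W x C` arrays, token sets as `T x C` matrices); a node wraps a value
#' together with a backward closure. Operations are generic over plain arrays
#' and nodes: called on plain arrays they just compute (inference mode, no
#' tape, no caching); called on at least one node they record themselves on
#' the active tape so that [adBackward()] can accumulate gradients.
#'
#' This is deliberately minimal — single-threaded, double precision, no
#' broadcasting beyond the few cases the networks need — but the gradients
#' are exact and are verified against central finite differences in the test
#' suite.
#'
#' @name autodiff
#' @keywords internal
NULL

.ad <- new.env(parent = emptyenv())
.ad$tape <- NULL
.ad$n <- 0L

#' Start recording a fresh tape
#' @keywords internal
adTapeStart <- function() {
  .ad$tape <- vector("list", 256L)
  .ad$n <- 0L
  invisible(NULL)
}

#' Stop recording and drop the tape
#' @keywords internal
adTapeStop <- function() {
  .ad$tape <- NULL
  .ad$n <- 0L
  invisible(NULL)
}

adRecording <- function() !is.null(.ad$tape)

adPush <- function(node) {
  n <- .ad$n + 1L
  if (n > length(.ad$tape)) .ad$tape <- c(.ad$tape, vector("list", length(.ad$tape)))
  .ad$tape[[n]] <- node
  .ad$n <- n
  node
}

#' Is `x` an autodiff node?
#' @param x object
#' @keywords internal
isNode <- function(x) inherits(x, "adnode")

#' Value of a node or plain array
#' @param x node or numeric
#' @keywords internal
adVal <- function(x) if (isNode(x)) x$v else x

newNode <- function(v, parents = list(), backward = NULL) {
  node <- new.env(parent = emptyenv())
  node$v <- v
  node$g <- NULL
  node$pa <- parents
  node$bk <- backward
  class(node) <- "adnode"
  adPush(node)
}

#' Create a leaf (parameter) node holding `v`
#'
#' Leaf nodes keep their gradient after [adBackward()]; the optimizer reads
#' it via `$g`.
#' @param v numeric array
#' @keywords internal
adLeaf <- function(v) {
  if (!adRecording()) adTapeStart()
  newNode(v)
}

accGrad <- function(p, g) {
  if (!isNode(p)) return(invisible(NULL))
  if (is.null(p$g)) p$g <- g else p$g <- p$g + g
  invisible(NULL)
}

#' Run backpropagation from a scalar loss node
#'
#' Seeds the loss gradient with 1 and sweeps the tape in reverse. Leaf
#' gradients remain available on the leaf nodes afterwards.
#' @param loss scalar adnode
#' @keywords internal
adBackward <- function(loss) {
  stopifnot(isNode(loss), length(loss$v) == 1L)
  loss$g <- 1
  for (k in seq(.ad$n, 1L)) {
    node <- .ad$tape[[k]]
    if (!is.null(node$g) && !is.null(node$bk)) node$bk(node)
  }
  invisible(NULL)
}

## ---- helpers ------------------------------------------------------------

bin_op <- function(a, b, fwd, bwd_a, bwd_b) {
  va <- adVal(a); vb <- adVal(b)
  v <- fwd(va, vb)
  if (!isNode(a) && !isNode(b)) return(v)
  newNode(v, list(a, b), function(n) {
    if (isNode(a)) accGrad(a, bwd_a(n$g, va, vb, n$v))
    if (isNode(b)) accGrad(b, bwd_b(n$g, va, vb, n$v))
  })
}

un_op <- function(a, fwd, bwd) {
  va <- adVal(a)
  v <- fwd(va)
  if (!isNode(a)) return(v)
  newNode(v, list(a), function(n) accGrad(a, bwd(n$g, va, n$v)))
}

## ---- elementwise arithmetic --------------------------------------------

#' Elementwise addition (same shape, or scalar second argument)
#' @param a,b nodes or arrays
#' @keywords internal
adAdd <- function(a, b) bin_op(a, b, `+`,
  function(g, va, vb, v) if (length(vb) == 1L && length(va) > 1L) g else g,
  function(g, va, vb, v) if (length(vb) == 1L && length(va) > 1L) sum(g) else g)

#' Elementwise subtraction
#' @param a,b nodes or arrays
#' @keywords internal
adSub <- function(a, b) bin_op(a, b, `-`,
  function(g, va, vb, v) g,
  function(g, va, vb, v) if (length(vb) == 1L && length(va) > 1L) -sum(g) else -g)

#' Elementwise product (same shape, or scalar second argument)
#' @param a,b nodes or arrays
#' @keywords internal
adMul <- function(a, b) bin_op(a, b, `*`,
  function(g, va, vb, v) if (length(vb) == 1L && length(va) > 1L) g * vb else g * vb,
  function(g, va, vb, v) if (length(vb) == 1L && length(va) > 1L) sum(g * va) else g * va)

#' Multiply by a plain scalar constant
#' @param a node or array
#' @param s numeric scalar (constant)
#' @keywords internal
adScale <- function(a, s) un_op(a, function(x) x * s, function(g, x, v) g * s)

#' Elementwise square
#' @param a node or array
#' @keywords internal
adSquare <- function(a) un_op(a, function(x) x * x, function(g, x, v) 2 * g * x)

#' Elementwise power with constant exponent (positive base assumed)
#' @param a node or array
#' @param p numeric exponent
#' @keywords internal
adPow <- function(a, p) un_op(a, function(x) x^p, function(g, x, v) g * p * x^(p - 1))

#' Natural logarithm
#' @param a node or array
#' @keywords internal
adLog <- function(a) un_op(a, log, function(g, x, v) g / x)

#' Clamp values into `[lo, hi]`; gradient is zero outside the interval
#' @param a node or array
#' @param lo,hi bounds
#' @keywords internal
adClamp <- function(a, lo, hi) un_op(a,
  function(x) pmin(pmax(x, lo), hi),
  function(g, x, v) g * as.numeric(x >= lo & x <= hi))

## ---- activations --------------------------------------------------------

#' ReLU activation
#' @param a node or array
#' @keywords internal
adRelu <- function(a) un_op(a, function(x) pmax(x, 0), function(g, x, v) g * (x > 0))

#' GELU activation (fast sigmoid approximation, `x * sigmoid(1.702 x)`)
#' @param a node or array
#' @keywords internal
adGelu <- function(a) un_op(a,
  function(x) x / (1 + exp(-1.702 * x)),
  function(g, x, v) {
    s <- 1 / (1 + exp(-1.702 * x))
    g * (s + 1.702 * x * s * (1 - s))
  })

#' Logistic sigmoid
#' @param a node or array
#' @keywords internal
adSigmoid <- function(a) un_op(a,
  function(x) 1 / (1 + exp(-x)),
  function(g, x, v) g * v * (1 - v))

#' Numerically stable softplus, `log(1 + exp(x))`
#' @param a node or array
#' @keywords internal
adSoftplus <- function(a) un_op(a,
  function(x) pmax(x, 0) + log1p(exp(-abs(x))),
  function(g, x, v) g / (1 + exp(-x)))

#' Hyperbolic tangent
#' @param a node or array
#' @keywords internal
adTanh <- function(a) un_op(a, tanh, function(g, x, v) g * (1 - v * v))

## ---- linear algebra -----------------------------------------------------

#' Matrix product with optional transposes
#' @param a,b nodes or matrices
#' @param ta,tb transpose flags
#' @keywords internal
adMatmul <- function(a, b, ta = FALSE, tb = FALSE) {
  va <- adVal(a); vb <- adVal(b)
  v <- if (!ta && !tb) va %*% vb
  else if (ta && !tb) crossprod(va, vb)
  else if (!ta && tb) tcrossprod(va, vb)
  else t(vb %*% va)
  if (!isNode(a) && !isNode(b)) return(v)
  newNode(v, list(a, b), function(n) {
    g <- n$g
    if (isNode(a)) {
      ga <- if (!ta && !tb) tcrossprod(g, vb)
      else if (ta && !tb) tcrossprod(vb, g)
      else if (!ta && tb) g %*% vb
      else crossprod(vb, t(g))
      accGrad(a, ga)
    }
    if (isNode(b)) {
      gb <- if (!ta && !tb) crossprod(va, g)
      else if (ta && !tb) va %*% g
      else if (!ta && tb) crossprod(g, va)
      else tcrossprod(t(g), va)
      accGrad(b, gb)
    }
  })
}

#' Add a per-column bias vector to a matrix, or per-channel bias to an
#' `H x W x C` array
#' @param x node or array
#' @param b node or vector of length `ncol(x)` / channels
#' @keywords internal
adBiasAdd <- function(x, b) {
  vx <- adVal(x); vb <- adVal(b)
  dm <- dim(vx)
  C <- dm[length(dm)]
  stopifnot(length(vb) == C)
  v <- vx + rep(vb, each = length(vx) / C)
  if (!isNode(x) && !isNode(b)) return(v)
  newNode(v, list(x, b), function(n) {
    if (isNode(x)) accGrad(x, n$g)
    if (isNode(b)) accGrad(b, colSums(matrix(n$g, ncol = C)))
  })
}

#' Row-wise softmax of a matrix
#' @param a node or matrix
#' @keywords internal
adSoftmaxRows <- function(a) un_op(a,
  function(x) {
    m <- x - apply(x, 1L, max)
    e <- exp(m)
    e / rowSums(e)
  },
  function(g, x, v) (g - rowSums(g * v)) * v)

#' Layer normalization over the last dimension
#'
#' Normalizes each row (token/pixel) of a `T x C` matrix (an `H x W x C`
#' array is treated as `H*W` rows) to zero mean and unit variance, then
#' applies a learned per-channel scale and shift.
#' @param x node or array
#' @param gamma,beta nodes or vectors of length C
#' @param eps numeric stabilizer
#' @keywords internal
adLayerNorm <- function(x, gamma, beta, eps = 1e-5) {
  vx <- adVal(x)
  dm <- dim(vx); C <- dm[length(dm)]
  xm <- matrix(vx, ncol = C)
  mu <- rowMeans(xm)
  xc <- xm - mu
  va <- rowMeans(xc * xc)
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * inv
  vg <- adVal(gamma); vb <- adVal(beta)
  out <- sweep(xhat, 2L, vg, `*`)
  out <- sweep(out, 2L, vb, `+`)
  v <- array(out, dm)
  if (!isNode(x) && !isNode(gamma) && !isNode(beta)) return(v)
  newNode(v, list(x, gamma, beta), function(n) {
    gm <- matrix(n$g, ncol = C)
    if (isNode(gamma)) accGrad(gamma, colSums(gm * xhat))
    if (isNode(beta)) accGrad(beta, colSums(gm))
    if (isNode(x)) {
      gh <- sweep(gm, 2L, vg, `*`)
      # d xhat/d x backward for per-row normalization
      gx <- inv * (gh - rowMeans(gh) - xhat * rowMeans(gh * xhat))
      accGrad(x, array(gx, dm))
    }
  })
}

## ---- shape ops ----------------------------------------------------------

#' Reshape preserving element order
#' @param a node or array
#' @param dm new dim vector
#' @keywords internal
adReshape <- function(a, dm) {
  va <- adVal(a)
  old <- dim(va)
  if (is.null(old)) old <- length(va)
  un_op(a, function(x) array(x, dm), function(g, x, v) array(g, old))
}

#' Concatenate matrices column-wise
#' @param xs list of nodes/matrices with equal row counts
#' @keywords internal
adCbind <- function(xs) {
  vs <- lapply(xs, adVal)
  v <- do.call(cbind, vs)
  if (!any(vapply(xs, isNode, logical(1L)))) return(v)
  offs <- c(0L, cumsum(vapply(vs, ncol, integer(1L))))
  newNode(v, xs, function(n) {
    for (i in seq_along(xs)) {
      if (isNode(xs[[i]])) accGrad(xs[[i]], n$g[, (offs[i] + 1L):offs[i + 1L], drop = FALSE])
    }
  })
}

#' Concatenate `H x W x C` arrays along the channel axis
#' @param xs list of nodes/arrays with equal spatial dims
#' @keywords internal
adConcatChannels <- function(xs) {
  vs <- lapply(xs, adVal)
  dm1 <- dim(vs[[1L]])
  cs <- vapply(vs, function(x) dim(x)[3L], numeric(1L))
  v <- array(unlist(vs, use.names = FALSE), c(dm1[1L], dm1[2L], sum(cs)))
  if (!any(vapply(xs, isNode, logical(1L)))) return(v)
  offs <- c(0L, cumsum(cs))
  newNode(v, xs, function(n) {
    for (i in seq_along(xs)) {
      if (isNode(xs[[i]]))
        accGrad(xs[[i]], n$g[, , (offs[i] + 1L):offs[i + 1L], drop = FALSE])
    }
  })
}

#' Take a subset of matrix rows (gather)
#' @param a node or matrix
#' @param idx integer row indices
#' @keywords internal
adRows <- function(a, idx) {
  va <- adVal(a)
  un_op(a,
    function(x) x[idx, , drop = FALSE],
    function(g, x, v) {
      gx <- matrix(0, nrow(x), ncol(x))
      # scatter-add (idx may repeat in principle)
      for (k in seq_along(idx)) gx[idx[k], ] <- gx[idx[k], ] + g[k, ]
      gx
    })
}

#' Matrix transpose
#' @param a node or matrix
#' @keywords internal
adTransposeM <- function(a) un_op(a, t, function(g, x, v) t(g))

#' Take a subset of matrix columns
#' @param a node or matrix
#' @param idx integer column indices (no repeats)
#' @keywords internal
adCols <- function(a, idx) {
  va <- adVal(a)
  un_op(a,
    function(x) x[, idx, drop = FALSE],
    function(g, x, v) {
      gx <- matrix(0, nrow(x), ncol(x))
      gx[, idx] <- g
      gx
    })
}

#' Stack matrices row-wise
#' @param xs list of nodes/matrices with equal column counts
#' @keywords internal
adRbind <- function(xs) {
  xs <- xs[!vapply(xs, is.null, logical(1L))]
  vs <- lapply(xs, adVal)
  v <- do.call(rbind, vs)
  if (!any(vapply(xs, isNode, logical(1L)))) return(v)
  offs <- c(0L, cumsum(vapply(vs, nrow, integer(1L))))
  newNode(v, xs, function(n) {
    for (i in seq_along(xs)) {
      if (isNode(xs[[i]])) accGrad(xs[[i]], n$g[(offs[i] + 1L):offs[i + 1L], , drop = FALSE])
    }
  })
}

#' Crop the top-left `h x w` window of an `H x W x C` array
#' @param a node or array
#' @param h,w output spatial dims
#' @keywords internal
adCrop <- function(a, h, w) {
  va <- adVal(a)
  dm <- dim(va)
  un_op(a,
    function(x) x[seq_len(h), seq_len(w), , drop = FALSE],
    function(g, x, v) {
      gx <- array(0, dm)
      gx[seq_len(h), seq_len(w), ] <- g
      gx
    })
}

## ---- reductions ---------------------------------------------------------

#' Mean of all elements
#' @param a node or array
#' @keywords internal
adMean <- function(a) un_op(a, mean,
  function(g, x, v) array(g / length(x), if (is.null(dim(x))) length(x) else dim(x)))

#' Sum of all elements
#' @param a node or array
#' @keywords internal
adSum <- function(a) un_op(a, sum,
  function(g, x, v) array(g, if (is.null(dim(x))) length(x) else dim(x)))

#' Sum a list of scalar nodes/numbers
#' @param xs list
#' @keywords internal
adSumList <- function(xs) {
  out <- xs[[1L]]
  if (length(xs) > 1L) for (i in 2L:length(xs)) out <- adAdd(out, xs[[i]])
  out
}
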