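#' @title Parameter containers and optimizer
#' @description
#' Model parameters live in nested named lists of plain numeric arrays.
#' [wrapParams()] converts such a list into a parallel list of autodiff leaf
#' nodes for one training step; [adamStep()] updates the plain arrays in
#' place from the leaf gradients. Initializers follow common practice
#' (He for ReLU convs, Glorot for linear maps); any layer whose final
#' projection must start as an exact identity is zero-initialized.
#' @name nn-layers
#' @keywords internal
NULL

#' He-initialized convolution kernel
#' @param kh,kw,cin,cout kernel dims
#' @keywords internal
initConv <- function(kh, kw, cin, cout) {
  array(stats::rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
        c(kh, kw, cin, cout))
}

#' Glorot-initialized dense weight matrix
#' @param cin,cout dims
#' @keywords internal
initDense <- function(cin, cout) {
  matrix(stats::rnorm(cin * cout, sd = sqrt(2 / (cin + cout))), cin, cout)
}

#' Depthwise kernel initializer
#' @param kh,kw,c dims
#' @keywords internal
initDw <- function(kh, kw, c) {
  array(stats::rnorm(kh * kw * c, sd = sqrt(2 / (kh * kw))), c(kh, kw, c))
}

#' Wrap a nested parameter list into autodiff leaf nodes
#' @param params nested named list of arrays
#' @keywords internal
wrapParams <- function(params) {
  rapplyList(params, adLeaf)
}

#' Extract plain values from a (possibly wrapped) parameter list
#' @param params nested list of nodes or arrays
#' @keywords internal
paramValues <- function(params) {
  rapplyList(params, adVal)
}

# recursive map over a nested list, applying f to non-list leaves
rapplyList <- function(x, f) {
  if (is.list(x) && !isNode(x)) lapply(x, rapplyList, f = f) else f(x)
}

# flatten a nested list to a single-level named list ("a.b.c")
flattenList <- function(x, prefix = NULL) {
  if (!is.list(x) || isNode(x)) {
    out <- list(x); names(out) <- prefix
    return(out)
  }
  out <- list()
  for (nm in names(x)) {
    key <- if (is.null(prefix)) nm else paste(prefix, nm, sep = ".")
    out <- c(out, flattenList(x[[nm]], key))
  }
  out
}

#' Create Adam optimizer state for a parameter list
#' @param params nested list of plain arrays
#' @param lr learning rate
#' @param beta1,beta2,eps Adam moment parameters
#' @keywords internal
adamInit <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  flat <- flattenList(params)
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
       m = lapply(flat, function(p) p * 0),
       v = lapply(flat, function(p) p * 0))
}

#' One Adam update
#'
#' @param params nested list of plain arrays (current values)
#' @param wrapped parallel nested list of leaf nodes carrying gradients
#' @param opt state from [adamInit()]
#' @param trainable optional character vector of flat-name prefixes to
#'   update; parameters not matching any prefix are left untouched (used to
#'   enforce the frozen-backbone contract during fine-tuning)
#' @return list(params = updated values, opt = updated state)
#' @keywords internal
adamStep <- function(params, wrapped, opt, trainable = NULL) {
  flat <- flattenList(params)
  grads <- lapply(flattenList(wrapped), function(n) if (is.null(n$g)) NULL else n$g)
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (nm in names(flat)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (!is.null(trainable) && !any(startsWith(nm, trainable))) next
    opt$m[[nm]] <- opt$beta1 * opt$m[[nm]] + (1 - opt$beta1) * g
    opt$v[[nm]] <- opt$beta2 * opt$v[[nm]] + (1 - opt$beta2) * g * g
    flat[[nm]] <- flat[[nm]] -
      opt$lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + opt$eps)
  }
  list(params = unflattenList(flat), opt = opt)
}

# inverse of flattenList
unflattenList <- function(flat) {
  out <- list()
  for (nm in names(flat)) {
    path <- strsplit(nm, ".", fixed = TRUE)[[1L]]
    out <- assignPath(out, path, flat[[nm]])
  }
  out
}

assignPath <- function(x, path, value) {
  if (length(path) == 1L) {
    x[[path]] <- value
    return(x)
  }
  if (is.null(x[[path[1L]]])) x[[path[1L]]] <- list()
  x[[path[1L]]] <- assignPath(x[[path[1L]]], path[-1L], value)
  x
}

#' Deterministic checksum of a parameter subset (freezing audit)
#' @param params nested list of arrays
#' @param prefixes flat-name prefixes to include (NULL = all)
#' @keywords internal
paramChecksum <- function(params, prefixes = NULL) {
  flat <- flattenList(paramValues(params))
  if (!is.null(prefixes)) {
    keep <- vapply(names(flat), function(nm) any(startsWith(nm, prefixes)), logical(1L))
    flat <- flat[keep]
  }
  vals <- unlist(flat[order(names(flat))], use.names = FALSE)
  # order-sensitive digest without external deps
  sum(vals * sin(seq_along(vals))) + sum(abs(vals))
}

#' Dense layer parameters
#' @param cin,cout dims
#' @param zero zero-initialize the weight (identity/neutral start)
#' @keywords internal
denseParams <- function(cin, cout, zero = FALSE) {
  list(w = if (zero) matrix(0, cin, cout) else initDense(cin, cout),
       b = numeric(cout))
}

#' Apply a dense layer to a token matrix
#' @param x node or `T x Cin` matrix
#' @param p dense parameter list
#' @keywords internal
denseForward <- function(x, p) adBiasAdd(adMatmul(x, p$w), p$b)

#' Conv layer parameters
#' @param kh,kw,cin,cout dims
#' @param zero zero-init
#' @keywords internal
convParams <- function(kh, kw, cin, cout, zero = FALSE) {
  list(w = if (zero) array(0, c(kh, kw, cin, cout)) else initConv(kh, kw, cin, cout),
       b = numeric(cout))
}

#' LayerNorm parameters
#' @param c channels
#' @keywords internal
lnParams <- function(c) list(gamma = rep(1, c), beta = numeric(c))
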