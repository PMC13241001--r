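# Shared helpers: independent scalar-loop oracles and finite-difference
# gradient checking. These deliberately avoid the package's vectorized
# implementations so they can serve as independent references.

`%||%` <- function(a, b) if (is.null(a)) b else a

# central finite-difference gradient of a scalar-valued forward function
fdGradCheck <- function(fwd, x, eps = 1e-5) {
  PromptPick:::adTapeStart()
  xl <- PromptPick:::adLeaf(x)
  L <- fwd(xl)
  PromptPick:::adBackward(L)
  g <- xl$g
  PromptPick:::adTapeStop()
  gn <- array(0, dim(x) %||% length(x))
  for (k in seq_along(x)) {
    xp <- x; xp[k] <- xp[k] + eps
    xm <- x; xm[k] <- xm[k] - eps
    gn[k] <- (fwd(xp) - fwd(xm)) / (2 * eps)
  }
  max(abs(g - gn))
}

# exhaustive minimum-cost injective assignment (rows into columns)
bruteAssign <- function(D) {
  N <- nrow(D); M <- ncol(D)
  best <- Inf; besta <- NULL
  rec <- function(i, used, acc, a) {
    if (i > N) {
      if (acc < best - 1e-12) { best <<- acc; besta <<- a }
      return(invisible(NULL))
    }
    for (j in seq_len(M)) {
      if (!used[j]) {
        used[j] <- TRUE
        rec(i + 1L, used, acc + D[i, j], c(a, j))
        used[j] <- FALSE
      }
    }
  }
  rec(1L, logical(M), 0, integer(0))
  list(cost = best, assignment = besta)
}

# scalar-loop weighted BCE (matched/unmatched partition), clipped
oracleClsLoss <- function(conf, matchedIdx, alpha, eps = 1e-7) {
  M <- length(conf)
  conf <- pmin(pmax(conf, eps), 1 - eps)
  acc <- 0
  for (i in seq_len(M)) {
    if (i %in% matchedIdx) acc <- acc + log(conf[i])
    else acc <- acc + alpha * log(1 - conf[i])
  }
  -acc / M
}

# scalar-loop binary focal loss on logits
oracleFocal <- function(logits, mask, af, gf) {
  acc <- 0
  for (k in seq_along(logits)) {
    p <- 1 / (1 + exp(-logits[k]))
    p <- min(max(p, 1e-7), 1 - 1e-7)
    pt <- if (mask[k] > 0.5) p else 1 - p
    acc <- acc - af * (1 - pt)^gf * log(pt)
  }
  acc / length(logits)
}

# scalar-loop soft dice loss
oracleDiceLoss <- function(logits, mask, smooth = 1) {
  p <- 1 / (1 + exp(-as.numeric(logits)))
  m <- as.numeric(mask)
  inter <- 0; sp <- 0; sm <- 0
  for (k in seq_along(p)) {
    inter <- inter + p[k] * m[k]; sp <- sp + p[k]; sm <- sm + m[k]
  }
  1 - (2 * inter + smooth) / (sp + sm + smooth)
}

# scalar-loop MSE
oracleMse <- function(a, b) {
  acc <- 0
  for (k in seq_along(a)) acc <- acc + (a[k] - b[k])^2
  acc / length(a)
}

# scalar-loop bilinear interpolation of one channel
oracleBilinear <- function(Fm, x, y) {
  Hi <- nrow(Fm); Wi <- ncol(Fm)
  x <- min(max(x, 0), Wi - 1); y <- min(max(y, 0), Hi - 1)
  x0 <- min(floor(x), Wi - 1); x1 <- min(x0 + 1, Wi - 1)
  y0 <- min(floor(y), Hi - 1); y1 <- min(y0 + 1, Hi - 1)
  fx <- x - x0; fy <- y - y0
  (1 - fy) * (1 - fx) * Fm[y0 + 1, x0 + 1] + fy * (1 - fx) * Fm[y1 + 1, x0 + 1] +
    (1 - fy) * fx * Fm[y0 + 1, x1 + 1] + fy * fx * Fm[y1 + 1, x1 + 1]
}

# small standard scene used across tests
tinyScene <- function(seed = 1, n = 4, size = 64, radius = 6) {
  generateScene(SceneParams(height = size, width = size, nParticles = n,
                            radius = radius, minDistance = 2.2 * radius,
                            seed = seed))
}
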