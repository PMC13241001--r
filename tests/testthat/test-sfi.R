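test_that("cross-attention weights are a row-stochastic softmax", {
  set.seed(61)
  p <- PromptPick:::sfiParams(4, 6)
  fx <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  fy <- array(rnorm(8 * 8 * 6), c(8, 8, 6))
  out <- crossAttentionFuse(fx, fy, p, returnAttention = TRUE)
  expect_equal(dim(out$fused), dim(fx))
  expect_equal(rowSums(out$attention), rep(1, nrow(out$attention)),
               tolerance = 1e-6)
})

test_that("attention over a constant auxiliary map returns its value projection", {
  set.seed(62)
  p <- PromptPick:::sfiParams(3, 3)
  fx <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  fy <- array(rep(c(1, 2, 3), each = 16), c(4, 4, 3))   # spatially constant
  fused <- crossAttentionFuse(fx, fy, p)
  # every attended value is identical, so softmax weights are irrelevant
  ref <- as.numeric(
    PromptPick:::denseForward(
      PromptPick:::denseForward(matrix(c(1, 2, 3), 1), p$proj), p$wv))
  for (c in seq_len(3)) {
    expect_equal(as.vector(fused[, , c]), rep(ref[c], 16), tolerance = 1e-9)
  }
})

test_that("single-position attention equals the value projection of f_y", {
  set.seed(63)
  p <- PromptPick:::sfiParams(5, 2)
  fx <- array(rnorm(5), c(1, 1, 5))
  fy <- array(rnorm(2), c(1, 1, 2))
  fused <- crossAttentionFuse(fx, fy, p)
  ref <- PromptPick:::denseForward(
    PromptPick:::denseForward(matrix(as.numeric(fy), 1), p$proj), p$wv)
  expect_equal(as.numeric(fused), as.numeric(ref), tolerance = 1e-12)
})

test_that("disabled and zero-initialized blocks are exact pass-throughs", {
  set.seed(64)
  fx <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  fy <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  off <- PromptPick:::sfiParams(4, 4, enabled = FALSE)
  expect_identical(PromptPick:::sfiForward(fx, fy, off), fx)
  expect_identical(PromptPick:::sfiForward(fx, fy, NULL), fx)
  # enabled, but gate2 zero-initialized (the default): exact identity
  on <- PromptPick:::sfiParams(4, 4, enabled = TRUE)
  expect_equal(PromptPick:::sfiForward(fx, fy, on), fx, tolerance = 0)
})

test_that("forward matches a step-by-step reimplementation of the gating", {
  set.seed(65)
  p <- PromptPick:::sfiParams(4, 4)
  p$gate2$w <- matrix(rnorm(16, sd = 0.3), 4, 4)   # non-trivial content path
  fx <- array(rnorm(6 * 6 * 4), c(6, 6, 4))
  fy <- array(rnorm(6 * 6 * 4), c(6, 6, 4))
  got <- PromptPick:::sfiForward(fx, fy, p)
  fA <- crossAttentionFuse(fx, fy, p)
  d2 <- function(x, pp) PromptPick:::dense2d(x, pp)
  sig <- function(z) 1 / (1 + exp(-z))
  r <- sig(d2(PromptPick:::adConcatChannels(list(fx, fA)), p$gate1))
  ftil <- fx + r * tanh(d2(fA, p$gate2))
  z <- sig(d2(PromptPick:::adConcatChannels(list(fx, ftil)), p$gate3))
  expect_equal(got, z * fx + (1 - z) * ftil, tolerance = 1e-12)
  expect_true(all(r > 0 & r < 1))
  expect_true(all(z > 0 & z < 1))
})

test_that("paired per-level blocks have independent parameters per direction", {
  dp <- PromptPick:::denoiserParams(3, 8, 2)
  ap <- apgParams(3, 8, 2, 16, 32)
  blocks <- makeSfiBlocks(dp, ap)
  expect_length(blocks$sfiU, 3)
  expect_length(blocks$sfiC, 3)
  expect_false(identical(blocks$sfiU[[1]]$wq$w, blocks$sfiC[[1]]$wq$w))
})
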