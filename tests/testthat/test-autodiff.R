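# The autodiff engine's gradients are exact; verify the spatial and
# algebraic ops against central finite differences on small inputs.

test_that("conv, depthwise conv and pooling gradients match finite differences", {
  set.seed(11)
  x <- array(rnorm(6 * 5 * 2), c(6, 5, 2))
  w <- PromptPick:::initConv(3, 3, 2, 3)
  dw <- PromptPick:::initDw(5, 5, 2)
  sq <- function(z) PromptPick:::adMean(PromptPick:::adSquare(z))
  b3 <- rnorm(3)
  expect_lt(fdGradCheck(function(z) sq(PromptPick:::adConv2d(z, w, b3)), x), 1e-8)
  expect_lt(fdGradCheck(function(z) sq(PromptPick:::adConv2d(x, z, NULL)), w), 1e-8)
  expect_lt(fdGradCheck(function(z) sq(PromptPick:::adDwConv2d(z, dw)), x), 1e-8)
  expect_lt(fdGradCheck(function(z) sq(PromptPick:::adDwConv2d(x, z)), dw), 1e-8)
  x2 <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  expect_lt(fdGradCheck(function(z) sq(PromptPick:::adAvgPool2(z)), x2), 1e-8)
  expect_lt(fdGradCheck(function(z) sq(PromptPick:::adUpNearest2(z)), x2), 1e-8)
  expect_lt(fdGradCheck(function(z) sq(PromptPick:::adResizeBilinear(z, 7, 5)), x2), 1e-8)
})

test_that("attention-path gradients (matmul, softmax, layernorm) are exact", {
  set.seed(12)
  m <- matrix(rnorm(12), 3, 4)
  B <- matrix(rnorm(8), 4, 2)
  sq <- function(z) PromptPick:::adMean(PromptPick:::adSquare(z))
  expect_lt(fdGradCheck(function(z) sq(PromptPick:::adMatmul(z, B)), m), 1e-8)
  expect_lt(fdGradCheck(function(z) sq(PromptPick:::adMatmul(z, t(B), tb = TRUE)), m), 1e-8)
  expect_lt(fdGradCheck(function(z) sq(PromptPick:::adSoftmaxRows(z)), m), 1e-8)
  g1 <- rep(1, 4); b1 <- rnorm(4)
  expect_lt(fdGradCheck(function(z) sq(PromptPick:::adLayerNorm(z, g1, b1)), m), 1e-7)
  expect_lt(fdGradCheck(function(z) sq(PromptPick:::adGelu(z)), m), 1e-8)
  expect_lt(fdGradCheck(function(z) sq(PromptPick:::adSigmoid(PromptPick:::adTanh(z))), m), 1e-8)
})

test_that("gather, slicing and concat ops route gradients correctly", {
  set.seed(13)
  x2 <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  m <- matrix(rnorm(12), 3, 4)
  sq <- function(z) PromptPick:::adMean(PromptPick:::adSquare(z))
  pts <- cbind(runif(5, 0, 3), runif(5, 0, 3))
  expect_lt(fdGradCheck(function(z) sq(PromptPick:::adGatherBilinear(z, pts)), x2), 1e-8)
  expect_lt(fdGradCheck(function(z) sq(PromptPick:::adRows(z, c(1, 3, 1))), m), 1e-8)
  expect_lt(fdGradCheck(function(z) sq(PromptPick:::adCols(z, c(2, 4))), m), 1e-8)
  expect_lt(fdGradCheck(function(z) sq(PromptPick:::adCbind(list(z, m))), m * 2), 1e-7)
  expect_lt(fdGradCheck(function(z) sq(PromptPick:::adConcatChannels(list(z, x2))), x2), 1e-8)
  expect_lt(fdGradCheck(function(z) sq(PromptPick:::adCrop(z, 2, 3)), x2), 1e-8)
  expect_lt(fdGradCheck(function(z) sq(PromptPick:::adTransposeM(z)), m), 1e-8)
})

test_that("inference mode (plain arrays in) returns plain arrays and equal values", {
  set.seed(14)
  x <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  w <- PromptPick:::initConv(3, 3, 2, 4)
  plain <- PromptPick:::adConv2d(x, w, NULL)
  expect_false(PromptPick:::isNode(plain))
  PromptPick:::adTapeStart()
  node <- PromptPick:::adConv2d(PromptPick:::adLeaf(x), w, NULL)
  expect_true(PromptPick:::isNode(node))
  expect_equal(PromptPick:::adVal(node), plain)
  PromptPick:::adTapeStop()
})
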