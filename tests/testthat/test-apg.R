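test_that("reference grid placement, count and error contract", {
  g <- buildReferenceGrid(c(64, 64), 16)
  expect_equal(nrow(g$points), 16L)
  expect_equal(unname(g$points[1, ]), c(8, 8))
  expect_error(buildReferenceGrid(c(64, 64), 64), "smaller")
  for (k in 1:10) {
    H <- sample(40:120, 1); W <- sample(40:120, 1); s <- sample(5:20, 1)
    g <- buildReferenceGrid(c(H, W), s)
    expect_equal(nrow(g$points), floor(H / s) * floor(W / s))
    expect_true(all(g$points[, 1] < W & g$points[, 2] < H))
  }
  # row-major order: x varies fastest
  g2 <- buildReferenceGrid(c(32, 32), 8)
  expect_equal(g2$points[1:4, 1], c(4, 12, 20, 28))
  expect_equal(g2$points[1:4, 2], rep(4, 4))
})

test_that("point-to-level mapping is the stated linear scaling", {
  expect_equal(unname(mapPointToLevel(c(512, 512), c(1024, 1024), c(256, 256))[1, ]),
               c(128, 128))
  expect_equal(unname(mapPointToLevel(c(0, 0), c(64, 64), c(16, 16))[1, ]), c(0, 0))
  p <- c(37.5, 12.25)
  a <- mapPointToLevel(p, c(96, 96), c(48, 48))
  b <- mapPointToLevel(p, c(96, 96), c(24, 24))
  expect_equal(unname(a[1, ]), 2 * unname(b[1, ]))   # linearity in level size
})

test_that("bilinear feature sampling matches a scalar-loop oracle", {
  set.seed(81)
  Fm <- array(rnorm(7 * 9 * 3), c(7, 9, 3))
  # exact at integer nodes
  v <- sampleFeatureBilinear(Fm, c(4, 2))
  expect_equal(v, as.numeric(Fm[3, 5, ]))
  # centre of a 2x2 single-channel map {1,2,3,4}
  F2 <- array(c(1, 2, 3, 4), c(2, 2, 1))
  expect_equal(sampleFeatureBilinear(F2, c(0.5, 0.5)), 2.5)
  # random points vs oracle, including out-of-range clamping
  for (k in 1:25) {
    pt <- c(runif(1, -1, 9.5), runif(1, -1, 7.5))
    got <- sampleFeatureBilinear(Fm, pt)
    want <- vapply(1:3, function(c) oracleBilinear(Fm[, , c], pt[1], pt[2]),
                   numeric(1))
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("multi-scale descriptor is the ordered concatenation over levels", {
  set.seed(82)
  pyr <- list(array(rnorm(16 * 16 * 4), c(16, 16, 4)),
              array(rnorm(8 * 8 * 8), c(8, 8, 8)))
  p <- c(5.3, 9.1)
  d <- multiscaleDescriptor(pyr, p, c(16, 16))
  expect_length(d, 12L)
  manual <- c(
    sampleFeatureBilinear(pyr[[1]], unname(mapPointToLevel(p, c(16, 16), c(16, 16))[1, ])),
    sampleFeatureBilinear(pyr[[2]], unname(mapPointToLevel(p, c(16, 16), c(8, 8))[1, ])))
  expect_equal(d, manual)
  # constant pyramids give tiled constants
  pyrC <- list(array(1, c(8, 8, 2)), array(2, c(4, 4, 3)))
  expect_equal(multiscaleDescriptor(pyrC, c(3, 3), c(8, 8)),
               c(1, 1, 2, 2, 2))
})

test_that("apg forward has the contracted output shapes and bounded confidences", {
  set.seed(83)
  p <- apgParams(3, 8, 2, 16, 32)
  fw <- apgForward(matrix(rnorm(64 * 64), 64), p, gridStride = 8)
  M <- nrow(fw$grid$points)
  expect_equal(M, 64L)
  expect_equal(dim(PromptPick:::adVal(fw$points)), c(M, 2L))
  expect_length(as.numeric(PromptPick:::adVal(fw$conf)), M)
  expect_true(all(PromptPick:::adVal(fw$conf) >= 0 & PromptPick:::adVal(fw$conf) <= 1))
  expect_equal(dim(PromptPick:::adVal(fw$maskLogits)), c(32L, 32L))
  # zero-initialized regression head refines nothing
  expect_equal(PromptPick:::adVal(fw$points), fw$grid$points, ignore_attr = TRUE)
})

test_that("apg forward with pass-through SFI equals the fusion-free forward", {
  set.seed(84)
  dp <- PromptPick:::denoiserParams(3, 8, 2)
  ap <- apgParams(3, 8, 2, 16, 32)
  blocks <- makeSfiBlocks(dp, ap)
  x <- matrix(rnorm(48 * 48), 48)
  dfw <- denoiserForward(x, dp)
  peers <- lapply(dfw$raw, PromptPick:::adVal)
  f0 <- apgForward(x, ap, gridStride = 8)
  f1 <- apgForward(x, ap, gridStride = 8, peerFeatures = peers,
                   sfiBlocks = blocks$sfiC)
  expect_equal(PromptPick:::adVal(f1$conf), PromptPick:::adVal(f0$conf), tolerance = 0)
  expect_equal(PromptPick:::adVal(f1$maskLogits), PromptPick:::adVal(f0$maskLogits),
               tolerance = 0)
})

test_that("confidence maps shift with the input (translation covariance)", {
  set.seed(85)
  ap <- apgParams(3, 8, 2, 16, 32)
  sc <- generateScene(SceneParams(height = 96, width = 96, nParticles = 3,
                                  radius = 8, minDistance = 18, seed = 5))
  x <- cleanImage(sc)
  stride <- 8L
  xs <- cbind(x[, (stride + 1):96], x[, 1:stride])   # shift left by one stride
  c0 <- matrix(as.numeric(PromptPick:::adVal(apgForward(x, ap, gridStride = stride)$conf)),
               12, 12, byrow = TRUE)
  c1 <- matrix(as.numeric(PromptPick:::adVal(apgForward(xs, ap, gridStride = stride)$conf)),
               12, 12, byrow = TRUE)
  # deep-interior cells shift by exactly one grid cell (columns far from
  # both vertical edges, beyond the encoder's receptive field)
  expect_equal(c1[4:9, 4:8], c0[4:9, 5:9], tolerance = 1e-6)
})
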