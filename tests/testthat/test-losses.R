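test_that("smooth-L1 has the stated piecewise values", {
  expect_equal(smoothL1(0), 0)
  expect_equal(smoothL1(0.5), 0.125)
  expect_equal(smoothL1(-0.5), 0.125)
  expect_equal(smoothL1(2), 1.5)
  expect_equal(smoothL1(-3), 2.5)
  # continuity at the branch point
  expect_equal(smoothL1(1 - 1e-9), smoothL1(1 + 1e-9), tolerance = 1e-8)
})

test_that("regression loss averages per-point coordinate sums over N", {
  pred <- matrix(c(0.5, 0, 2, 0), 2, 2, byrow = TRUE)
  gt <- matrix(0, 2, 2)
  # point 1: 0.125 + 0; point 2: 1.5 + 0; mean = 0.8125
  expect_equal(PromptPick:::adVal(regLoss(pred, gt)), 0.8125)
  # monotonicity: moving a matched prediction away never decreases the loss
  set.seed(51)
  base <- matrix(rnorm(10), 5, 2)
  l0 <- PromptPick:::adVal(regLoss(base, matrix(0, 5, 2)))
  worse <- base; worse[3, 1] <- worse[3, 1] + sign(worse[3, 1] + 1e-12) * 2
  expect_gte(PromptPick:::adVal(regLoss(worse, matrix(0, 5, 2))), l0)
})

test_that("classification loss matches Eq-style weighted BCE", {
  expect_equal(PromptPick:::adVal(clsLoss(c(1, 0), 1L, alpha = 1)), 0,
               tolerance = 1e-5)
  expect_equal(PromptPick:::adVal(clsLoss(0.5, integer(0), alpha = 1)),
               -log(0.5), tolerance = 1e-12)
  set.seed(52)
  for (k in 1:20) {
    M <- sample(2:8, 1); N <- sample(0:(M - 1), 1)
    conf <- runif(M)
    matched <- if (N > 0) sample(M, N) else integer(0)
    a <- runif(1, 0.2, 2)
    expect_equal(PromptPick:::adVal(clsLoss(conf, matched, a)),
                 oracleClsLoss(conf, matched, a), tolerance = 1e-9)
  }
})

test_that("focal loss reduces to BCE at gamma 0 and saturates on perfect logits", {
  set.seed(53)
  lg <- matrix(rnorm(30), 5)
  m <- matrix(rbinom(30, 1, 0.4), 5)
  bce <- mean(-(m * log(plogis(lg)) + (1 - m) * log(1 - plogis(lg))))
  expect_equal(PromptPick:::adVal(segFocalLoss(lg, m, focalAlpha = 1, focalGamma = 0)),
               bce, tolerance = 1e-9)
  perfect <- (m * 2 - 1) * 20
  expect_lt(PromptPick:::adVal(segFocalLoss(perfect, m, 0.25, 2)), 1e-6)
  # scalar-loop oracle on random instances
  for (k in 1:20) {
    lg <- matrix(rnorm(16), 4); m <- matrix(rbinom(16, 1, 0.5), 4)
    expect_equal(PromptPick:::adVal(segFocalLoss(lg, m, 0.25, 2)),
                 oracleFocal(lg, m, 0.25, 2), tolerance = 1e-9)
  }
})

test_that("combined APG loss is the stated weighted sum", {
  expect_equal(PromptPick:::adVal(apgLoss(0.2, 0.3, 0.5, c(1, 1, 1))), 1.0)
  expect_equal(PromptPick:::adVal(apgLoss(9, 0.3, 0.5, c(0, 1, 2))), 1.3)
})

test_that("segmenter loss equals lambda_f * focal + dice and obeys its limits", {
  set.seed(54)
  lg <- matrix(rnorm(25), 5); m <- matrix(rbinom(25, 1, 0.5), 5)
  expect_equal(PromptPick:::adVal(samLoss(lg, m, lambdaF = 20)),
               20 * oracleFocal(lg, m, 0.25, 2) + oracleDiceLoss(lg, m),
               tolerance = 1e-8)
  # lambda_f = 0: pure dice loss
  expect_equal(PromptPick:::adVal(samLoss(lg, m, lambdaF = 0)),
               oracleDiceLoss(lg, m), tolerance = 1e-10)
  perfect <- (m * 2 - 1) * 20
  expect_lt(PromptPick:::adVal(samLoss(perfect, m, lambdaF = 20)), 1e-3)
})

test_that("Noise2Noise loss is the mean squared difference", {
  a <- matrix(rnorm(36), 6)
  expect_equal(PromptPick:::adVal(n2nLoss(a, a)), 0)
  expect_equal(PromptPick:::adVal(n2nLoss(a + 2, a)), 4)
  b <- matrix(rnorm(36), 6)
  expect_equal(PromptPick:::adVal(n2nLoss(a, b)), oracleMse(a, b), tolerance = 1e-12)
})

test_that("losses are non-negative", {
  set.seed(55)
  for (k in 1:10) {
    lg <- matrix(rnorm(16, sd = 3), 4); m <- matrix(rbinom(16, 1, 0.5), 4)
    expect_gte(PromptPick:::adVal(segFocalLoss(lg, m)), 0)
    expect_gte(PromptPick:::adVal(diceLoss(lg, m)), 0)
    expect_gte(PromptPick:::adVal(clsLoss(runif(5), sample(5, 2), 0.5)), 0)
  }
})
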