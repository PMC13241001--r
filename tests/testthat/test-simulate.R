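test_that("empty scene is background only", {
  sc <- generateScene(SceneParams(nParticles = 0, seed = 3))
  expect_equal(nrow(coords(sc)), 0L)
  expect_true(all(groundTruthMask(sc) == 0))
  expect_true(all(cleanImage(sc) == 0))   # flat background
})

test_that("a single soft disk has footprint area close to pi r^2", {
  sc <- generateScene(SceneParams(height = 64, width = 64, nParticles = 1,
                                  radius = 10, minDistance = 22, contrast = -1,
                                  seed = 5))
  area <- sum(groundTruthMask(sc))
  expect_lt(abs(area - pi * 100) / (pi * 100), 0.05)
  # footprint thresholds the noiseless image at half contrast
  expect_equal(groundTruthMask(sc), (cleanImage(sc) <= -0.5) * 1,
               ignore_attr = TRUE)
})

test_that("scene generation is deterministic given the seed", {
  p <- SceneParams(nParticles = 10, seed = 42)
  s1 <- generateScene(p); s2 <- generateScene(p)
  expect_identical(cleanImage(s1), cleanImage(s2))
  expect_identical(coords(s1), coords(s2))
  n1 <- makeNoisyPair(s1, 0.5, seed = 7); n2 <- makeNoisyPair(s2, 0.5, seed = 7)
  expect_identical(pixels(evenImage(n1)), pixels(evenImage(n2)))
  expect_identical(pixels(oddImage(n1)), pixels(oddImage(n2)))
})

test_that("rejection sampling fails informatively when particles cannot fit", {
  p <- SceneParams(height = 48, width = 48, nParticles = 60, radius = 6,
                   minDistance = 14, seed = 1)
  expect_error(generateScene(p, maxAttempts = 500L), "achieved")
})

test_that("centers lie inside connected mask components", {
  sc <- tinyScene(seed = 9, n = 5)
  m <- groundTruthMask(sc)
  for (k in seq_len(nrow(coords(sc)))) {
    cx <- round(coords(sc)[k, 1]); cy <- round(coords(sc)[k, 2])
    expect_equal(m[cy + 1, cx + 1], 1)
  }
})

test_that("noisy pair members share the signal but carry independent noise", {
  sc <- generateScene(SceneParams(height = 256, width = 256, nParticles = 0,
                                  seed = 2))
  np <- makeNoisyPair(sc, noiseSigma = 1, seed = 11)
  d <- pixels(evenImage(np)) - pixels(oddImage(np))
  expect_lt(abs(var(as.vector(d)) - 2) / 2, 0.05)
  e1 <- pixels(evenImage(np)) - cleanImage(sc)
  e2 <- pixels(oddImage(np)) - cleanImage(sc)
  expect_lt(abs(cor(as.vector(e1), as.vector(e2))), 0.02)
  # zero-noise pair collapses onto the clean image
  np0 <- makeNoisyPair(sc, noiseSigma = 0, seed = 11)
  expect_equal(pixels(evenImage(np0)), cleanImage(sc), ignore_attr = TRUE)
  expect_equal(pixels(oddImage(np0)), cleanImage(sc), ignore_attr = TRUE)
})

test_that("oracle SNR matches its defining ratio", {
  set.seed(21)
  clean <- matrix(rnorm(100, sd = 2), 10)
  resid <- matrix(rnorm(100, sd = 2 / sqrt(10)), 10)
  # scale residual so Var(clean) = 10 * Var(resid) exactly
  resid <- resid * sqrt(var(as.vector(clean)) / (10 * var(as.vector(resid))))
  expect_equal(oracleSNR(clean, clean + resid), 10, tolerance = 1e-10)
  resid1 <- resid * sqrt(10)
  expect_equal(oracleSNR(clean, clean + resid1), 0, tolerance = 1e-10)
  expect_error(oracleSNR(clean, clean), "exactly")
  expect_error(oracleSNR(matrix(1, 5, 5), matrix(rnorm(25), 5)), "zero variance")
})

test_that("oracle SNR on a unit-contrast scene matches the plug-in estimate", {
  sc <- generateScene(SceneParams(height = 256, width = 256, nParticles = 30,
                                  radius = 8, minDistance = 18, contrast = 1,
                                  seed = 8))
  np <- makeNoisyPair(sc, noiseSigma = 1, seed = 4)
  s <- oracleSNR(cleanImage(sc), pixels(evenImage(np)))
  expect_lt(abs(s - 10 * log10(var(as.vector(cleanImage(sc))))), 0.3)
})

test_that("sigmaForSNR hits the requested raw SNR", {
  sc <- tinyScene(seed = 3, n = 5, size = 128)
  sg <- sigmaForSNR(sc, -5)
  np <- makeNoisyPair(sc, noiseSigma = sg, seed = 99)
  expect_lt(abs(oracleSNR(cleanImage(sc), pixels(evenImage(np))) + 5), 0.5)
})
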