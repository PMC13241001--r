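# Compact end-to-end exercise of the four-stage schedule and the picking
# chain on small scenes; the full-scale synthetic benchmark lives in the
# acceptance suite.

test_that("progressive training, picking and STAR export work end to end", {
  cfg <- defaultConfig()
  cfg$simulate$height <- cfg$simulate$width <- 96
  cfg$simulate$n_particles <- 6
  cfg$train$denoiser_steps <- 25
  cfg$train$apg_steps <- 40
  cfg$train$joint_steps <- 5
  cfg$train$seg_steps <- 200
  cfg$train$denoiser_patch <- 64
  cfg$train$apg_crop <- 96
  sp <- configSceneParams(cfg, seed = 5)
  pairs <- simulateDataset(8, sp, targetSnrDb = -3)
  bundle <- progressiveTrain(pairs, cfg, seed = 5)

  # staged warm start: step-0 joint loss decomposes into the stage terminals
  expect_equal(bundle$audit$stage3Step0Joint,
               bundle$audit$stage1Loss + bundle$audit$stage2Loss,
               tolerance = 1e-10)
  # frozen segmenter backbone
  expect_identical(bundle$segAudit$before, bundle$segAudit$after)

  spTest <- sp; spTest@seed <- 901
  testPair <- simulateDataset(1, spTest, targetSnrDb = -3)[[1]]
  res <- pickParticles(evenImage(testPair), bundle)
  sc <- testPair@scene
  expect_true(length(res$particles) >= 1)
  m <- evalPicking(res$particles, ParticleSet(coords(sc)), diameter = 16)
  expect_gte(m$recall, 0.5)
  # picked coordinates land inside (or immediately next to) mask components
  for (k in seq_len(length(res$particles))) {
    cx <- round(coords(res$particles)[k, 1]); cy <- round(coords(res$particles)[k, 2])
    win <- res$mask[max(1, cy - 1):min(96, cy + 3), max(1, cx - 1):min(96, cx + 3)]
    expect_gt(sum(win), 0)
  }
  # STAR round trip of the picks
  f <- tempfile(fileext = ".star")
  writeSTAR(res$particles, f)
  expect_equal(coords(readSTAR(f)), coords(res$particles), tolerance = 1e-9)
  unlink(f)

  # candidate count grows monotonically as the threshold drops
  inf <- res$prompts
  n_hi <- sum(inf$allConf >= 0.9)
  n_md <- sum(inf$allConf >= 0.5)
  n_lo <- sum(inf$allConf >= 0.1)
  expect_true(n_hi <= n_md && n_md <= n_lo)

  # blank micrograph: no particles (negative control)
  blank <- generateScene(SceneParams(height = 96, width = 96, nParticles = 0,
                                     seed = 77))
  blankNoisy <- makeNoisyPair(blank, noiseSigma = sigmaForSNR(tinyScene(1, 6, 96), -3),
                              seed = 3)
  resB <- suppressWarnings(pickParticles(evenImage(blankNoisy), bundle))
  expect_lte(length(resB$particles), 1L)   # at most a stray component
})

test_that("skipping stage 1 trains the prompt generator on raw images", {
  cfg <- defaultConfig()
  cfg$simulate$height <- cfg$simulate$width <- 96
  cfg$simulate$n_particles <- 5
  cfg$train$apg_steps <- 6
  cfg$train$joint_steps <- 2
  sp <- configSceneParams(cfg, seed = 9)
  pairs <- simulateDataset(3, sp, targetSnrDb = -3)
  bundle <- progressiveTrain(pairs, cfg, seed = 9, stages = c(2, 3))
  expect_null(bundle$seg)
  expect_true(is.finite(bundle$audit$stage2Loss))
  expect_equal(bundle$stages, c(2, 3))
})
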