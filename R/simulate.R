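#' @title Synthetic micrograph simulator
#'
#' @description
#' Generates micrograph scenes with known ground truth so that every stage
#' of the pipeline — Noise2Noise denoiser, prompt generator, promptable
#' segmenter — can be trained and validated without external data. Particles
#' are soft-edged disks (radial logistic profile) scattered with a
#' minimum-distance constraint on a flat or low-order polynomial background;
#' observation noise is additive Gaussian, with the two members of a
#' training pair drawn independently so their expectation is the clean
#' image, exactly the statistical structure even/odd frame-sum micrographs
#' provide.
#'
#' @name simulate
NULL

# radial profile: 1 inside the disk, 0 outside, logistic rim of scale s
diskProfile <- function(d, r, s) 1 / (1 + exp((d - r) / max(s, 1e-6)))

#' Generate a synthetic scene
#'
#' Particle centres are placed by rejection sampling honouring the
#' minimum-distance constraint; each particle adds `contrast` times a soft
#' disk profile to the background. The ground-truth mask marks pixels where
#' some particle's noiseless footprint exceeds half its contrast, i.e. the
#' disk interior `d <= r`.
#'
#' @param params a [SceneParams-class] object
#' @param maxAttempts rejection-sampling budget per scene
#' @return a [SyntheticScene-class]; deterministic given `params@seed`
#' @examples
#' sc <- generateScene(SceneParams(nParticles = 5, seed = 7))
#' nrow(coords(sc))
#' @export
generateScene <- function(params, maxAttempts = 500L * max(1L, as.integer(params@nParticles))) {
  validObject(params)
  H <- as.integer(params@height); W <- as.integer(params@width)
  n <- as.integer(params@nParticles)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(abs(params@seed) %% 2147483647))

  rmax <- max(params@radius)
  margin <- rmax + 1
  centers <- matrix(numeric(0), 0, 2)
  attempts <- 0L
  while (nrow(centers) < n && attempts < maxAttempts) {
    attempts <- attempts + 1L
    cx <- stats::runif(1, margin, W - 1 - margin)
    cy <- stats::runif(1, margin, H - 1 - margin)
    if (nrow(centers) == 0L ||
        min(sqrt((centers[, 1L] - cx)^2 + (centers[, 2L] - cy)^2)) >= params@minDistance) {
      centers <- rbind(centers, c(cx, cy))
    }
  }
  if (nrow(centers) < n) {
    stop(sprintf(paste0(
      "could not place %d particles with minDistance %.1f in a %d x %d image ",
      "within %d attempts (achieved %d); reduce nParticles or minDistance"),
      n, params@minDistance, H, W, maxAttempts, nrow(centers)))
  }
  radii <- if (length(params@radius) == 2L) {
    stats::runif(n, params@radius[1L], params@radius[2L])
  } else rep(params@radius, n)

  xs <- matrix(rep(0:(W - 1L), each = H), H, W)   # x = column index
  ys <- matrix(rep(0:(H - 1L), times = W), H, W)  # y = row index
  clean <- switch(params@background,
    flat = matrix(0, H, W),
    low_order_polynomial = {
      cf <- stats::rnorm(5, sd = 0.1)
      u <- xs / max(W - 1, 1) - 0.5; v <- ys / max(H - 1, 1) - 0.5
      cf[1L] + cf[2L] * u + cf[3L] * v + cf[4L] * u * v + cf[5L] * (u^2 - v^2)
    })
  gtMask <- matrix(0, H, W)
  if (n > 0L) {
    for (k in seq_len(n)) {
      d <- sqrt((xs - centers[k, 1L])^2 + (ys - centers[k, 2L])^2)
      clean <- clean + params@contrast * diskProfile(d, radii[k], params@edgeSoftness)
      gtMask[d <= radii[k]] <- 1
    }
  }
  colnames(centers) <- c("x", "y")
  new("SyntheticScene", clean = clean, centers = centers, radii = radii,
      gtMask = gtMask, params = params)
}

#' Observe a scene through two independent noise realizations
#'
#' Returns the even/odd-style pair `(clean + eps1, clean + eps2)` with
#' `eps1, eps2` i.i.d. Gaussian of standard deviation `noiseSigma`, drawn
#' from distinct sub-seeds so the two fields are independent.
#'
#' @param scene a [SyntheticScene-class]
#' @param noiseSigma noise standard deviation (>= 0); defaults to the
#'   scene's `params@noiseSigma`
#' @param seed integer seed for the noise (distinct from the scene seed)
#' @param mode `"gaussian"` (default) or `"poisson_gaussian"`, which adds
#'   signal-dependent shot noise on top of the Gaussian read noise
#' @param poissonScale photon scale for `"poisson_gaussian"`
#' @return a [NoisyPair-class] carrying the scene as ground truth
#' @export
makeNoisyPair <- function(scene, noiseSigma = scene@params@noiseSigma,
                          seed = scene@params@seed + 1000L,
                          mode = c("gaussian", "poisson_gaussian"),
                          poissonScale = 50) {
  mode <- match.arg(mode)
  stopifnot(noiseSigma >= 0)
  clean <- scene@clean
  n <- length(clean)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  drawNoise <- function(sub) {
    set.seed(as.integer((abs(seed) %% 1e9) * 2 + sub))
    eps <- matrix(stats::rnorm(n, sd = noiseSigma), nrow(clean), ncol(clean))
    if (mode == "poisson_gaussian") {
      lam <- pmax(clean - min(clean) + 0.5, 0) * poissonScale
      shot <- (matrix(stats::rpois(n, lam), nrow(clean)) - lam) / poissonScale
      eps <- eps + shot
    }
    eps
  }
  mid <- sprintf("scene%d", as.integer(scene@params@seed))
  new("NoisyPair",
      even = Micrograph(clean + drawNoise(0L), id = paste0(mid, "_even")),
      odd = Micrograph(clean + drawNoise(1L), id = paste0(mid, "_odd")),
      scene = scene)
}

#' Oracle signal-to-noise ratio in dB
#'
#' With the clean signal known (synthetic data only), the SNR of an
#' observation is `10 * log10(Var(clean) / Var(observed - clean))`.
#'
#' @param clean numeric matrix, the noiseless image
#' @param observed numeric matrix of identical shape
#' @return SNR in dB
#' @export
oracleSNR <- function(clean, observed) {
  if (is(clean, "Micrograph")) clean <- clean@pixels
  if (is(observed, "Micrograph")) observed <- observed@pixels
  stopifnot(identical(dim(clean), dim(observed)))
  vc <- stats::var(as.vector(clean))
  if (vc == 0) stop("oracle SNR undefined: clean image has zero variance")
  resid <- as.vector(observed - clean)
  vr <- stats::var(resid)
  if (vr == 0) stop("oracle SNR undefined: observed equals clean exactly")
  10 * log10(vc / vr)
}

#' Noise level achieving a target raw oracle SNR
#'
#' Given a clean image and a target SNR in dB, returns the Gaussian sigma
#' such that `oracleSNR(clean, clean + noise)` is approximately the target.
#'
#' @param clean numeric matrix or [SyntheticScene-class]
#' @param targetDb target raw SNR in dB (e.g. -5)
#' @return noise standard deviation
#' @export
sigmaForSNR <- function(clean, targetDb) {
  if (is(clean, "SyntheticScene")) clean <- clean@clean
  sqrt(stats::var(as.vector(clean)) / 10^(targetDb / 10))
}

#' Generate a dataset of scenes and noisy pairs
#'
#' Convenience wrapper producing `n` scenes that differ only in seed, each
#' observed as an independent noisy pair.
#'
#' @param n number of scenes
#' @param params template [SceneParams-class]; per-scene seeds are
#'   `params@seed + 0 .. n-1`
#' @param noiseSigma noise sd; if `NULL`, computed once via [sigmaForSNR()]
#'   from the first scene to hit `targetSnrDb`
#' @param targetSnrDb raw-SNR target used when `noiseSigma` is NULL
#' @return list of [NoisyPair-class] objects
#' @export
simulateDataset <- function(n, params = SceneParams(), noiseSigma = NULL,
                            targetSnrDb = -3) {
  pairs <- vector("list", n)
  for (i in seq_len(n)) {
    p <- params
    p@seed <- params@seed + i - 1
    sc <- generateScene(p)
    if (is.null(noiseSigma)) noiseSigma <- sigmaForSNR(sc, targetSnrDb)
    pairs[[i]] <- makeNoisyPair(sc, noiseSigma = noiseSigma,
                                seed = p@seed * 13L + 7L)
  }
  pairs
}
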