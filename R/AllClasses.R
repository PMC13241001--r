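#' @import methods
NULL

#' Micrograph: a 2-D real-valued image
#'
#' Container for a single 2-D micrograph. Pixels are stored as a numeric
#' matrix with rows indexing y and columns indexing x; all coordinates in
#' the package are 0-based `(x, y) = (column, row)` with pixel centres at
#' integer coordinates.
#'
#' @slot pixels numeric matrix (H x W), all values finite
#' @slot pixelSize numeric(1), Angstrom per pixel (`NA_real_` if unknown)
#' @slot id character(1) identifier
#'
#' @examples
#' mg <- Micrograph(matrix(rnorm(64 * 64), 64), id = "demo")
#' dim(pixels(mg))
#' @export
setClass("Micrograph",
  representation(pixels = "matrix", pixelSize = "numeric", id = "character"),
  prototype(pixelSize = NA_real_, id = ""))

setValidity("Micrograph", function(object) {
  px <- object@pixels
  if (!is.numeric(px)) return("pixels must be numeric")
  if (nrow(px) < 1L || ncol(px) < 1L) return("micrograph must be at least 1 x 1")
  if (!all(is.finite(px))) return("pixels must all be finite")
  if (length(object@pixelSize) != 1L) return("pixelSize must be length 1")
  if (length(object@id) != 1L) return("id must be length 1")
  TRUE
})

#' Construct a Micrograph
#' @param pixels numeric matrix (rows = y, columns = x)
#' @param pixelSize Angstrom per pixel, or `NA`
#' @param id identifier string
#' @return a [Micrograph-class] object
#' @export
Micrograph <- function(pixels, pixelSize = NA_real_, id = "") {
  new("Micrograph", pixels = pixels, pixelSize = as.numeric(pixelSize),
      id = as.character(id))
}

#' ParticleSet: picked or ground-truth particle coordinates
#'
#' Particle centres with per-particle confidences and a nominal diameter.
#' Coordinates are 0-based pixel positions `(x, y)`.
#'
#' @slot coords numeric matrix (n x 2), columns x and y
#' @slot confidences numeric vector in `[0, 1]`, one per particle
#' @slot diameter numeric(1), nominal particle diameter in pixels
#' @slot micrographId character(1), id of the source micrograph
#' @export
setClass("ParticleSet",
  representation(coords = "matrix", confidences = "numeric",
                 diameter = "numeric", micrographId = "character"),
  prototype(diameter = NA_real_, micrographId = ""))

setValidity("ParticleSet", function(object) {
  if (ncol(object@coords) != 2L && nrow(object@coords) > 0L)
    return("coords must have two columns (x, y)")
  if (length(object@confidences) != nrow(object@coords))
    return("confidences must align with coords")
  if (length(object@confidences) &&
      (any(object@confidences < 0) || any(object@confidences > 1)))
    return("confidences must lie in [0, 1]")
  TRUE
})

#' Construct a ParticleSet
#' @param coords n x 2 matrix (or 2-column data.frame) of (x, y) pixel coords
#' @param confidences per-particle confidences in `[0, 1]`; defaults to 1
#' @param diameter nominal particle diameter (pixels)
#' @param micrographId id of the source micrograph
#' @return a [ParticleSet-class] object
#' @export
ParticleSet <- function(coords = matrix(numeric(0), 0, 2), confidences = NULL,
                        diameter = NA_real_, micrographId = "") {
  coords <- as.matrix(coords)
  if (nrow(coords) > 0L) storage.mode(coords) <- "double"
  if (ncol(coords) == 0L) coords <- matrix(numeric(0), 0, 2)
  colnames(coords) <- c("x", "y")
  if (is.null(confidences)) confidences <- rep(1, nrow(coords))
  new("ParticleSet", coords = coords, confidences = as.numeric(confidences),
      diameter = as.numeric(diameter), micrographId = as.character(micrographId))
}

#' SceneParams: parameters of a synthetic micrograph scene
#'
#' The simulator draws roughly circular dark (or bright) particles with a
#' soft logistic rim on a smooth background and observes them through
#' additive Gaussian noise. Defaults mirror the package's synthetic
#' benchmark conditions: small dense particles of radius 8 px with a
#' minimum centre distance that keeps ground-truth footprints disjoint.
#'
#' @slot height,width image dims (pixels)
#' @slot nParticles number of particles
#' @slot radius particle radius in pixels; length 1 (fixed) or 2 (range)
#' @slot minDistance minimum centre-to-centre distance (pixels)
#' @slot edgeSoftness rim falloff scale (pixels)
#' @slot contrast signed particle amplitude relative to background
#'   (negative mimics dark cryo-EM particles)
#' @slot background `"flat"` or `"low_order_polynomial"`
#' @slot noiseSigma additive Gaussian noise s.d.
#' @slot seed integer RNG seed
#' @export
setClass("SceneParams",
  representation(height = "numeric", width = "numeric", nParticles = "numeric",
                 radius = "numeric", minDistance = "numeric",
                 edgeSoftness = "numeric", contrast = "numeric",
                 background = "character", noiseSigma = "numeric",
                 seed = "numeric"))

setValidity("SceneParams", function(object) {
  if (object@height < 8 || object@width < 8) return("image too small")
  if (object@nParticles < 0) return("nParticles must be >= 0")
  if (any(object@radius <= 0)) return("radius must be positive")
  if (!length(object@radius) %in% 1:2) return("radius must be length 1 or 2")
  if (object@minDistance < 2 * max(object@radius))
    return("minDistance must be >= 2 * radius (overlap disallowed)")
  if (object@noiseSigma < 0) return("noiseSigma must be >= 0")
  if (!object@background %in% c("flat", "low_order_polynomial"))
    return("background must be 'flat' or 'low_order_polynomial'")
  TRUE
})

#' Construct SceneParams
#'
#' @param height,width image size in pixels
#' @param nParticles particle count
#' @param radius particle radius (scalar, or length-2 range)
#' @param minDistance minimum centre distance; default `2.2 * max(radius)`
#'   keeps ground-truth mask components disjoint
#' @param edgeSoftness rim softness in pixels
#' @param contrast signed particle amplitude (default -1: dark particles)
#' @param background background model, `"flat"` or `"low_order_polynomial"`
#' @param noiseSigma additive Gaussian noise s.d.
#' @param seed RNG seed
#' @return a [SceneParams-class] object
#' @export
SceneParams <- function(height = 192, width = 192, nParticles = 20, radius = 8,
                        minDistance = 2.2 * max(radius), edgeSoftness = 1,
                        contrast = -1, background = "flat", noiseSigma = 0.5,
                        seed = 1) {
  new("SceneParams", height = height, width = width, nParticles = nParticles,
      radius = radius, minDistance = minDistance, edgeSoftness = edgeSoftness,
      contrast = contrast, background = background, noiseSigma = noiseSigma,
      seed = seed)
}

#' SyntheticScene: a simulated micrograph with ground truth
#'
#' @slot clean numeric matrix, the noiseless image
#' @slot centers n x 2 matrix of particle centres (x, y)
#' @slot radii per-particle radii
#' @slot gtMask binary matrix, union of particle footprints
#' @slot params the generating [SceneParams-class]
#' @export
setClass("SyntheticScene",
  representation(clean = "matrix", centers = "matrix", radii = "numeric",
                 gtMask = "matrix", params = "SceneParams"))

setValidity("SyntheticScene", function(object) {
  n <- nrow(object@centers)
  if (length(object@radii) != n) return("radii must align with centers")
  if (!identical(dim(object@clean), dim(object@gtMask)))
    return("clean and gtMask dims differ")
  if (n > 0L) {
    H <- nrow(object@clean); W <- ncol(object@clean)
    if (any(object@centers[, 1L] < 0) || any(object@centers[, 1L] > W - 1) ||
        any(object@centers[, 2L] < 0) || any(object@centers[, 2L] > H - 1))
      return("centers must lie inside image bounds")
  }
  TRUE
})

#' NoisyPair: two observations of one clean signal
#'
#' Emulates the even/odd frame-sum micrographs used for Noise2Noise
#' training: the two members share the underlying signal but carry
#' independent zero-mean noise.
#'
#' @slot even,odd [Micrograph-class] objects of identical shape
#' @slot scene optional [SyntheticScene-class] (or NULL)
#' @export
setClass("NoisyPair",
  representation(even = "Micrograph", odd = "Micrograph", scene = "ANY"),
  prototype(scene = NULL))

setValidity("NoisyPair", function(object) {
  if (!identical(dim(object@even@pixels), dim(object@odd@pixels)))
    return("even and odd members must have identical shape")
  if (!is.null(object@scene) && !is(object@scene, "SyntheticScene"))
    return("scene must be NULL or a SyntheticScene")
  TRUE
})

## ---- generics & accessors ----------------------------------------------

#' Pixel matrix of a Micrograph
#' @param x a [Micrograph-class]
#' @return numeric matrix
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname pixels
#' @export
setMethod("pixels", "Micrograph", function(x) x@pixels)

#' Pixel size (Angstrom/pixel) of a Micrograph
#' @param x a [Micrograph-class]
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname pixelSize
#' @export
setMethod("pixelSize", "Micrograph", function(x) x@pixelSize)

#' Particle coordinates
#' @param x a [ParticleSet-class] or [SyntheticScene-class]
#' @return n x 2 numeric matrix of (x, y)
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname coords
#' @export
setMethod("coords", "ParticleSet", function(x) x@coords)

#' @rdname coords
#' @export
setMethod("coords", "SyntheticScene", function(x) x@centers)

#' Particle confidences
#' @param x a [ParticleSet-class]
#' @export
setGeneric("confidences", function(x) standardGeneric("confidences"))

#' @rdname confidences
#' @export
setMethod("confidences", "ParticleSet", function(x) x@confidences)

#' Ground-truth mask of a synthetic scene
#' @param x a [SyntheticScene-class]
#' @return binary matrix
#' @export
setGeneric("groundTruthMask", function(x) standardGeneric("groundTruthMask"))

#' @rdname groundTruthMask
#' @export
setMethod("groundTruthMask", "SyntheticScene", function(x) x@gtMask)

#' Clean (noiseless) image of a synthetic scene
#' @param x a [SyntheticScene-class]
#' @export
setGeneric("cleanImage", function(x) standardGeneric("cleanImage"))

#' @rdname cleanImage
#' @export
setMethod("cleanImage", "SyntheticScene", function(x) x@clean)

#' Members of a noisy pair
#' @param x a [NoisyPair-class]
#' @export
setGeneric("evenImage", function(x) standardGeneric("evenImage"))

#' @rdname evenImage
#' @export
setMethod("evenImage", "NoisyPair", function(x) x@even)

#' @rdname evenImage
#' @export
setGeneric("oddImage", function(x) standardGeneric("oddImage"))

#' @rdname evenImage
#' @export
setMethod("oddImage", "NoisyPair", function(x) x@odd)

setMethod("show", "Micrograph", function(object) {
  cat(sprintf("Micrograph '%s': %d x %d px, pixel size %s A/px\n",
              object@id, nrow(object@pixels), ncol(object@pixels),
              ifelse(is.na(object@pixelSize), "unknown", format(object@pixelSize))))
})

setMethod("show", "ParticleSet", function(object) {
  cat(sprintf("ParticleSet: %d particles, diameter %s px (micrograph '%s')\n",
              nrow(object@coords),
              ifelse(is.na(object@diameter), "?", format(object@diameter)),
              object@micrographId))
})

setMethod("show", "SyntheticScene", function(object) {
  cat(sprintf("SyntheticScene: %d x %d px, %d particles, background '%s'\n",
              nrow(object@clean), ncol(object@clean), nrow(object@centers),
              object@params@background))
})

setMethod("show", "NoisyPair", function(object) {
  d <- dim(object@even@pixels)
  cat(sprintf("NoisyPair: %d x %d px%s\n", d[1L], d[2L],
              if (is.null(object@scene)) "" else " (with synthetic ground truth)"))
})

#' Number of particles in a set
#' @param x a [ParticleSet-class]
#' @export
setMethod("length", "ParticleSet", function(x) nrow(x@coords))
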