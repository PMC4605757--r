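#' @import methods
NULL

#' SpectralCube: a multispectral reflectance cube
#'
#' An m x n x W array of reflectance values (band axis last) together with
#' the W acquisition wavelengths in nanometres, strictly increasing. Cubes
#' must be free of infinite values; NaN entries are permitted only as the
#' result of mask application (excluded pixels).
#'
#' @slot data numeric array, m x n x W; m, n >= 3 (neighbourhood operations
#'   need a 3 x 3 window).
#' @slot wavelengths numeric vector of length W, strictly increasing, in nm.
#' @slot sourceId free-text provenance tag.
#'
#' @seealso [SpectralCube()], [readCube()], [normalizeBands()]
#' @export
setClass("SpectralCube",
  representation(data = "array", wavelengths = "numeric", sourceId = "character"),
  prototype(sourceId = ""))

setValidity("SpectralCube", function(object) {
  d <- object@data
  if (length(dim(d)) != 3L)
    return("data must have exactly 3 axes (m x n x W)")
  if (dim(d)[1] < 3L || dim(d)[2] < 3L)
    return("spatial dimensions must be at least 3 x 3")
  if (length(object@wavelengths) != dim(d)[3])
    return("length(wavelengths) must equal the number of bands")
  if (any(diff(object@wavelengths) <= 0))
    return("wavelengths must be strictly increasing")
  if (any(is.infinite(d)))
    return("cube contains infinite values")
  TRUE
})

#' Construct a SpectralCube
#'
#' @param data m x n x W numeric array of reflectances, band axis last.
#' @param wavelengths wavelengths in nm (one per band, strictly increasing);
#'   defaults to band indices `0:(W-1)` with a warning.
#' @param sourceId free-text provenance tag.
#' @return a validated [SpectralCube-class] object.
#' @examples
#' cube <- SpectralCube(array(runif(5 * 5 * 4), c(5, 5, 4)))
#' dim(cubeData(cube))
#' @export
SpectralCube <- function(data, wavelengths = NULL, sourceId = "") {
  data <- unname(data)
  storage.mode(data) <- "double"
  if (is.null(wavelengths)) {
    warning("no wavelengths supplied; defaulting to band indices 0..W-1")
    wavelengths <- seq_len(dim(data)[3]) - 1
  }
  new("SpectralCube", data = data, wavelengths = as.numeric(wavelengths),
      sourceId = as.character(sourceId))
}

#' PreprocessedCube: a cube after normalization
#'
#' A [SpectralCube-class] carrying its preprocessing stage: `"bandnorm"`
#' after per-band min-max scaling, `"bandnorm+snv"` after the additional
#' per-pixel Standard Normal Variate transform. Degenerate inputs (constant
#' bands, constant spectra) are flagged rather than raising.
#'
#' @slot stage `"bandnorm"` or `"bandnorm+snv"`.
#' @slot constantBands integer indices of bands that were constant (mapped
#'   to all-zero).
#' @slot constantPixels number of pixels whose spectrum was constant
#'   (mapped to all-zero by SNV).
#' @seealso [normalizeBands()], [snv()]
#' @export
setClass("PreprocessedCube", contains = "SpectralCube",
  representation(stage = "character", constantBands = "integer",
                 constantPixels = "integer"),
  prototype(stage = "bandnorm", constantBands = integer(0),
            constantPixels = 0L))

setValidity("PreprocessedCube", function(object) {
  if (!object@stage %in% c("bandnorm", "bandnorm+snv"))
    return("stage must be 'bandnorm' or 'bandnorm+snv'")
  TRUE
})

#' BinaryMask: a single-band inclusion mask
#'
#' Boolean m x n matrix marking included pixels. A mask with no TRUE pixel
#' must carry the explicit `empty` flag; downstream operations reject
#' silently-empty masks.
#'
#' @slot data logical matrix.
#' @slot label one of `"foreground_stage1"`, `"informative_final"`,
#'   `"custom"`.
#' @slot empty explicit empty-mask flag.
#' @seealso [BinaryMask()], [applyMask()], [areaFraction()]
#' @export
setClass("BinaryMask",
  representation(data = "matrix", label = "character", empty = "logical"),
  prototype(label = "custom", empty = FALSE))

setValidity("BinaryMask", function(object) {
  if (!is.logical(object@data)) return("mask data must be logical")
  if (anyNA(object@data)) return("mask data must not contain NA")
  if (!object@label %in% c("foreground_stage1", "informative_final", "custom"))
    return("unknown mask label")
  if (!object@empty && !any(object@data))
    return("mask has no TRUE pixel and the 'empty' flag is not set")
  TRUE
})

#' Construct a BinaryMask
#'
#' @param data logical (or coercible 0/1 numeric) matrix of included pixels.
#' @param label mask role tag.
#' @return a [BinaryMask-class]; the `empty` flag is set automatically when
#'   no pixel is TRUE.
#' @examples
#' m <- BinaryMask(matrix(c(TRUE, FALSE, TRUE, TRUE), 2, 2))
#' areaFraction(m)
#' @export
BinaryMask <- function(data, label = "custom") {
  if (!is.logical(data)) {
    stopifnot(is.numeric(data))
    data <- data != 0
  }
  data <- unname(data)
  new("BinaryMask", data = data, label = label, empty = !any(data))
}

#' Mixture1D: a fitted 1-D Gaussian mixture
#'
#' Parameters of a C-component univariate Gaussian mixture fitted by EM on
#' a weighted (binned) sample, with fit diagnostics and its
#' minimum-message-length score. Components are stored sorted by ascending
#' mean.
#'
#' @slot weights mixing proportions, nonnegative, summing to 1.
#' @slot means component means.
#' @slot variances component variances, each at or above the variance floor.
#' @slot ncomp component count.
#' @slot loglik final log-likelihood of the weighted sample.
#' @slot loglikTrace per-iteration log-likelihood sequence (nondecreasing).
#' @slot messageLength MML score of the fit (lower is better).
#' @slot n effective number of observations.
#' @slot converged whether EM reached its relative-change tolerance.
#' @slot flags character vector of degeneracy flags (e.g. `"degenerate"`).
#' @seealso [fitEM()], [selectModel()], [messageLength()]
#' @export
setClass("Mixture1D",
  representation(weights = "numeric", means = "numeric", variances = "numeric",
    ncomp = "integer", loglik = "numeric", loglikTrace = "numeric",
    messageLength = "numeric", n = "numeric", converged = "logical",
    flags = "character"),
  prototype(flags = character(0), converged = FALSE,
            messageLength = NA_real_))

setValidity("Mixture1D", function(object) {
  C <- object@ncomp
  if (C < 1L) return("C must be >= 1")
  if (length(object@weights) != C || length(object@means) != C ||
      length(object@variances) != C)
    return("weights, means, variances must each have length C")
  if (abs(sum(object@weights) - 1) > 1e-9)
    return("weights must sum to 1")
  if (any(object@weights < 0)) return("weights must be nonnegative")
  if (any(object@variances <= 0)) return("variances must be positive")
  if (is.unsorted(object@means)) return("components must be sorted by mean")
  TRUE
})

#' ThresholdDecision: an automatic intensity threshold
#'
#' The cutoff derived from a fitted mixture, how it was derived
#' (`"bayes"`: crossing of the two weighted component densities;
#' `"kurtosis"`: skew-directed tail rejection on a single component), and
#' which side of the cutoff is foreground.
#'
#' @slot threshold intensity cutoff (may be `Inf` when nothing is rejected).
#' @slot method `"bayes"` or `"kurtosis"`.
#' @slot CSelected number of components behind the decision.
#' @slot foregroundSide `"above"` or `"below"`.
#' @slot mixture the [Mixture1D-class] behind the decision.
#' @seealso [bayesThreshold()], [kurtosisThreshold()]
#' @export
setClass("ThresholdDecision",
  representation(threshold = "numeric", method = "character",
    CSelected = "integer", foregroundSide = "character", mixture = "Mixture1D"))

setValidity("ThresholdDecision", function(object) {
  if (!object@method %in% c("bayes", "kurtosis"))
    return("method must be 'bayes' or 'kurtosis'")
  if (!object@foregroundSide %in% c("above", "below"))
    return("foregroundSide must be 'above' or 'below'")
  if (object@method == "bayes") {
    if (object@CSelected != 2L) return("bayes threshold requires C = 2")
    mu <- object@mixture@means
    t <- object@threshold
    if (t < mu[1] - 1e-12 || t > mu[2] + 1e-12)
      return("bayes threshold must lie between the component means")
  }
  if (object@method == "kurtosis" && object@CSelected != 1L)
    return("kurtosis threshold requires C = 1")
  TRUE
})

#' FitConfig: mixture-fitting configuration
#'
#' @slot cMax maximum number of components tried by [selectModel()]
#'   (default 2: informative area plus at most one nuisance class).
#' @slot emTol relative log-likelihood change at which EM stops.
#' @slot maxIter EM iteration cap.
#' @slot varianceFloor variance floor as a fraction of the data variance
#'   (guards against component collapse on spike-shaped histograms).
#' @slot nBins number of histogram bins intensities are fitted on.
#' @slot seed integer seed recorded with results (all fitting is itself
#'   deterministic: quantile initialization, no random restarts).
#' @slot kurtosisK tail cutoff multiplier k in the mu +/- k*sigma rejection
#'   rule of [kurtosisThreshold()].
#' @seealso [fitConfig()]
#' @export
setClass("FitConfig",
  representation(cMax = "integer", emTol = "numeric", maxIter = "integer",
    varianceFloor = "numeric", nBins = "integer", seed = "integer",
    kurtosisK = "numeric"))

setValidity("FitConfig", function(object) {
  if (object@cMax < 1L) return("cMax must be >= 1")
  if (object@emTol <= 0 || object@maxIter < 1L || object@varianceFloor <= 0 ||
      object@nBins < 2L || object@kurtosisK <= 0)
    return("all FitConfig fields must be positive")
  TRUE
})

#' Create a FitConfig
#'
#' @param cMax,emTol,maxIter,varianceFloor,nBins,seed,kurtosisK see
#'   [FitConfig-class].
#' @return a [FitConfig-class] object.
#' @examples
#' fitConfig(nBins = 128L)
#' @export
fitConfig <- function(cMax = 2L, emTol = 1e-7, maxIter = 500L,
                      varianceFloor = 1e-4, nBins = 256L, seed = 1L,
                      kurtosisK = 2.0) {
  new("FitConfig", cMax = as.integer(cMax), emTol = emTol,
      maxIter = as.integer(maxIter), varianceFloor = varianceFloor,
      nBins = as.integer(nBins), seed = as.integer(seed),
      kurtosisK = kurtosisK)
}

#' PipelineConfig: full segmentation-cascade configuration
#'
#' @slot fit the [FitConfig-class] used by every mixture fit.
#' @slot skipStage2 run only the background-removal stage (for products
#'   without a fat/connective-tissue class).
#' @slot foregroundRule how the foreground side of a Bayes threshold is
#'   identified: `"central"` (side dominating the central 25-percent-area
#'   window; samples sit centred in the dish), `"larger_component"`,
#'   `"above"`, or `"below"`.
#' @slot combiner how a band pair is combined into a grey image:
#'   `"difference"` (signed difference, min-max rescaled; default),
#'   `"absdiff"`, or `"ratio"`.
#' @slot cleanupMinSize post-threshold cleanup: drop connected mask
#'   components smaller than this many pixels (0 disables, the default).
#' @slot cleanupMaxHole fill mask holes smaller than this many pixels
#'   (0 disables, the default).
#' @slot minSeparation minimum component separation (Ashman's D,
#'   `|mu_2 - mu_1| / sqrt((s_1^2 + s_2^2) / 2)`) for a two-component fit
#'   to be treated as genuinely bimodal by a stage; below it the stage
#'   falls back to the single-component tail-rejection path. A mixture of
#'   two Gaussians has a histogram valley only for D around 2 or more, so
#'   a Bayes crossing between less separated components would split a
#'   single population.
#' @seealso [pipelineConfig()], [runPipeline()]
#' @export
setClass("PipelineConfig",
  representation(fit = "FitConfig", skipStage2 = "logical",
    foregroundRule = "character", combiner = "character",
    cleanupMinSize = "integer", cleanupMaxHole = "integer",
    minSeparation = "numeric"))

setValidity("PipelineConfig", function(object) {
  if (!object@foregroundRule %in% c("central", "larger_component", "above", "below"))
    return("unknown foregroundRule")
  if (!object@combiner %in% c("difference", "absdiff", "ratio"))
    return("combiner must be 'difference', 'absdiff' or 'ratio'")
  if (object@cleanupMinSize < 0L || object@cleanupMaxHole < 0L)
    return("cleanup sizes must be >= 0")
  if (object@minSeparation < 0) return("minSeparation must be >= 0")
  TRUE
})

#' Create a PipelineConfig
#'
#' @param fit a [FitConfig-class].
#' @param skipStage2,foregroundRule,combiner,cleanupMinSize,cleanupMaxHole,minSeparation
#'   see [PipelineConfig-class].
#' @return a [PipelineConfig-class] object.
#' @examples
#' pipelineConfig(skipStage2 = TRUE)
#' @export
pipelineConfig <- function(fit = fitConfig(), skipStage2 = FALSE,
                           foregroundRule = "central",
                           combiner = "difference",
                           cleanupMinSize = 0L, cleanupMaxHole = 0L,
                           minSeparation = 2.0) {
  new("PipelineConfig", fit = fit, skipStage2 = skipStage2,
      foregroundRule = foregroundRule, combiner = combiner,
      cleanupMinSize = as.integer(cleanupMinSize),
      cleanupMaxHole = as.integer(cleanupMaxHole),
      minSeparation = minSeparation)
}

#' StageResult: outcome of one cascade stage
#'
#' @slot pair the winning band pair (i, j), 1-based band indices, i < j.
#' @slot ranking data.frame of all scored pairs (`i`, `j`, `ebcm`),
#'   ascending by score.
#' @slot diffImage the winning pair's difference image, rescaled to [0, 1].
#' @slot decision the [ThresholdDecision-class] applied to it.
#' @slot mask the resulting [BinaryMask-class].
#' @seealso [segmentStage()]
#' @export
setClass("StageResult",
  representation(pair = "integer", ranking = "data.frame",
    diffImage = "matrix", decision = "ThresholdDecision", mask = "BinaryMask"))

#' SegmentationResult: full cascade output
#'
#' @slot stage1 background-removal [StageResult-class].
#' @slot stage2 fat/connective-tissue [StageResult-class], or NULL when
#'   skipped or degraded.
#' @slot finalMask intersection of the stage masks.
#' @slot maskedCube the input cube with excluded pixels set to NaN in every
#'   band.
#' @slot snvCube the band-normalized + SNV cube, retained for spectral
#'   export.
#' @slot config the [PipelineConfig-class] snapshot.
#' @slot log character vector of run messages.
#' @seealso [runPipeline()]
#' @export
setClass("SegmentationResult",
  representation(stage1 = "StageResult", stage2 = "ANY",
    finalMask = "BinaryMask", maskedCube = "SpectralCube",
    snvCube = "PreprocessedCube", config = "PipelineConfig",
    log = "character"))

#' PhantomSpec: synthetic-cube specification
#'
#' Describes a synthetic multispectral scene: elliptical sample region(s)
#' on a surround, optional fat speckle blobs inside the sample, one spectral
#' signature per region, additive Gaussian noise, and a per-pixel
#' multiplicative gain (constant across bands -- exactly the illumination
#' structure SNV is meant to remove).
#'
#' @slot shape integer (m, n, W).
#' @slot ellipses numeric matrix with columns cx, cy, rx, ry (pixel units),
#'   one row per sample ellipse.
#' @slot fatCount number of fat speckle blobs.
#' @slot fatSizeRange blob radius range in pixels.
#' @slot signatures 3 x W matrix of region spectra in [0, 1]; rows
#'   surround, sample, fat.
#' @slot wavelengths W wavelengths in nm.
#' @slot noiseSd additive Gaussian noise standard deviation.
#' @slot gainRange per-pixel multiplicative gain interval.
#' @slot seed mandatory RNG seed.
#' @slot name preset tag.
#' @seealso [phantomPreset()], [makePhantom()]
#' @export
setClass("PhantomSpec",
  representation(shape = "integer", ellipses = "matrix", fatCount = "integer",
    fatSizeRange = "numeric", signatures = "matrix", wavelengths = "numeric",
    noiseSd = "numeric", gainRange = "numeric", seed = "integer",
    name = "character"),
  prototype(name = "custom"))

setValidity("PhantomSpec", function(object) {
  if (length(object@shape) != 3L) return("shape must be (m, n, W)")
  W <- object@shape[3]
  if (ncol(object@signatures) != W) return("signature length must equal W")
  if (nrow(object@signatures) != 3L)
    return("signatures must have rows surround, sample, fat")
  if (any(object@signatures < 0) || any(object@signatures > 1))
    return("signatures must lie in [0, 1]")
  if (length(object@wavelengths) != W) return("need W wavelengths")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  if (length(object@gainRange) != 2L || object@gainRange[1] > object@gainRange[2] ||
      object@gainRange[1] <= 0)
    return("gainRange must be a positive interval")
  if (length(object@seed) != 1L || is.na(object@seed))
    return("seed is mandatory")
  if (ncol(object@ellipses) != 4L || nrow(object@ellipses) < 1L)
    return("ellipses must be a matrix with columns cx, cy, rx, ry")
  m <- object@shape[1]; n <- object@shape[2]
  e <- object@ellipses
  if (any(e[, 1] - e[, 3] < 1) || any(e[, 1] + e[, 3] > m) ||
      any(e[, 2] - e[, 4] < 1) || any(e[, 2] + e[, 4] > n))
    return("sample ellipse does not fit inside the image")
  TRUE
})

#' PhantomTruth: a synthetic cube with ground truth
#'
#' @slot cube the generated [SpectralCube-class].
#' @slot truthSample sample-region mask (fat excluded).
#' @slot truthFat fat-speckle mask.
#' @slot truthSurround surround mask; the three masks partition the image.
#' @slot spec the generating [PhantomSpec-class].
#' @seealso [makePhantom()]
#' @export
setClass("PhantomTruth",
  representation(cube = "SpectralCube", truthSample = "BinaryMask",
    truthFat = "BinaryMask", truthSurround = "BinaryMask",
    spec = "PhantomSpec"))
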