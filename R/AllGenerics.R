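#' Accessors
#'
#' Extractors for the package's S4 containers. `cubeData` returns the raw
#' m x n x W array, `wavelengths` the band wavelengths in nm, `maskData`
#' the logical matrix of a mask, `isEmptyMask` its explicit empty flag.
#'
#' @param x a [SpectralCube-class], [BinaryMask-class] or
#'   [SegmentationResult-class] as appropriate.
#' @return the extracted component.
#' @name accessors
#' @examples
#' cube <- SpectralCube(array(runif(45), c(3, 3, 5)), wavelengths = 1:5)
#' wavelengths(cube)
NULL

#' @rdname accessors
#' @export
setGeneric("cubeData", function(x) standardGeneric("cubeData"))

#' @rdname accessors
#' @export
setMethod("cubeData", "SpectralCube", function(x) x@data)

#' @rdname accessors
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @rdname accessors
#' @export
setMethod("wavelengths", "SpectralCube", function(x) x@wavelengths)

#' @rdname accessors
#' @export
setGeneric("sourceId", function(x) standardGeneric("sourceId"))

#' @rdname accessors
#' @export
setMethod("sourceId", "SpectralCube", function(x) x@sourceId)

#' @rdname accessors
#' @export
setGeneric("maskData", function(x) standardGeneric("maskData"))

#' @rdname accessors
#' @export
setMethod("maskData", "BinaryMask", function(x) x@data)

#' @rdname accessors
#' @export
setGeneric("isEmptyMask", function(x) standardGeneric("isEmptyMask"))

#' @rdname accessors
#' @export
setMethod("isEmptyMask", "BinaryMask", function(x) x@empty || !any(x@data))

#' @rdname accessors
#' @export
setGeneric("finalMask", function(x) standardGeneric("finalMask"))

#' @rdname accessors
#' @export
setMethod("finalMask", "SegmentationResult", function(x) x@finalMask)

#' @rdname accessors
#' @export
setGeneric("maskedCube", function(x) standardGeneric("maskedCube"))

#' @rdname accessors
#' @export
setMethod("maskedCube", "SegmentationResult", function(x) x@maskedCube)

#' Mixture accessors
#'
#' @param x a [Mixture1D-class].
#' @return numeric vector of component parameters (sorted by ascending
#'   mean), or the component count.
#' @name mixture-accessors
#' @examples
#' fit <- fitEM(c(rnorm(200, 0.3, 0.02), rnorm(200, 0.7, 0.02)), C = 2)
#' mixtureMeans(fit)
NULL

#' @rdname mixture-accessors
#' @export
setGeneric("mixtureWeights", function(x) standardGeneric("mixtureWeights"))

#' @rdname mixture-accessors
#' @export
setMethod("mixtureWeights", "Mixture1D", function(x) x@weights)

#' @rdname mixture-accessors
#' @export
setGeneric("mixtureMeans", function(x) standardGeneric("mixtureMeans"))

#' @rdname mixture-accessors
#' @export
setMethod("mixtureMeans", "Mixture1D", function(x) x@means)

#' @rdname mixture-accessors
#' @export
setGeneric("mixtureVariances", function(x) standardGeneric("mixtureVariances"))

#' @rdname mixture-accessors
#' @export
setMethod("mixtureVariances", "Mixture1D", function(x) x@variances)

#' @rdname mixture-accessors
#' @export
setGeneric("nComponents", function(x) standardGeneric("nComponents"))

#' @rdname mixture-accessors
#' @export
setMethod("nComponents", "Mixture1D", function(x) x@ncomp)

setMethod("show", "SpectralCube", function(object) {
  d <- dim(object@data)
  cat(sprintf("%s: %d x %d pixels, %d bands (%g-%g nm)\n",
              class(object), d[1], d[2], d[3],
              min(object@wavelengths), max(object@wavelengths)))
  if (is(object, "PreprocessedCube"))
    cat("  stage:", object@stage, "\n")
  nNaN <- sum(is.nan(object@data))
  if (nNaN > 0) cat("  masked (NaN) entries:", nNaN, "\n")
  if (nzchar(object@sourceId)) cat("  source:", object@sourceId, "\n")
})

setMethod("show", "BinaryMask", function(object) {
  cat(sprintf("BinaryMask (%s): %d x %d, %d included pixels%s\n",
              object@label, nrow(object@data), ncol(object@data),
              sum(object@data), if (isEmptyMask(object)) " [empty]" else ""))
})

setMethod("show", "Mixture1D", function(object) {
  cat(sprintf("Mixture1D: C = %d, n = %g, loglik = %.4f, MML = %.4f%s\n",
              object@ncomp, object@n, object@loglik, object@messageLength,
              if (object@converged) "" else " [not converged]"))
  for (m in seq_len(object@ncomp))
    cat(sprintf("  pi = %.4f, mu = %.5f, sigma = %.5f\n",
                object@weights[m], object@means[m], sqrt(object@variances[m])))
})

setMethod("show", "ThresholdDecision", function(object) {
  cat(sprintf("ThresholdDecision: t = %.6g (%s, C = %d), foreground %s\n",
              object@threshold, object@method, object@CSelected,
              object@foregroundSide))
})

setMethod("show", "StageResult", function(object) {
  cat(sprintf("StageResult: bands (%d, %d), EBCM = %.5f\n",
              object@pair[1], object@pair[2], object@ranking$ebcm[1]))
  show(object@decision)
  show(object@mask)
})

setMethod("show", "SegmentationResult", function(object) {
  cat("SegmentationResult\n-- stage 1 --\n")
  show(object@stage1)
  if (!is.null(object@stage2)) {
    cat("-- stage 2 --\n")
    show(object@stage2)
  } else cat("-- stage 2: skipped --\n")
  cat("-- final --\n")
  show(object@finalMask)
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec '%s': %d x %d x %d, %d sample ellipse(s), %d fat blob(s), noise sd %g, gain [%g, %g], seed %d\n",
              object@name, object@shape[1], object@shape[2], object@shape[3],
              nrow(object@ellipses), object@fatCount, object@noiseSd,
              object@gainRange[1], object@gainRange[2], object@seed))
})
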