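#' Per-band min-max normalization
#'
#' First preprocessing phase: each spectral band is independently mapped to
#' [0, 1] by `(v - min) / (max - min)`, so every band exploits the full
#' dynamic range regardless of the raw reflectance span. A constant band
#' carries no contrast: it maps to all zeros and is flagged (its index is
#' recorded in `constantBands`) with a warning rather than aborting a batch
#' run.
#'
#' @param cube a [SpectralCube-class] with finite values.
#' @return a [PreprocessedCube-class] with `stage = "bandnorm"`.
#' @seealso [snv()] for the second phase.
#' @examples
#' cube <- SpectralCube(array(runif(48, 0.2, 0.8), c(4, 4, 3)),
#'                      wavelengths = c(450, 550, 650))
#' pc <- normalizeBands(cube)
#' range(cubeData(pc))
#' @export
normalizeBands <- function(cube) {
  stopifnot(is(cube, "SpectralCube"))
  validObject(cube)
  if (anyNA(cube@data)) stop("cannot normalize a cube containing NaN")
  d <- cube@data
  W <- dim(d)[3]
  constant <- integer(0)
  for (w in seq_len(W)) {
    band <- d[, , w]
    r <- .rescale01(band)
    if (is.null(r)) {
      d[, , w] <- 0
      constant <- c(constant, w)
    } else {
      d[, , w] <- r
    }
  }
  if (length(constant) > 0)
    warning("constant band(s) mapped to zero: ",
            paste(constant, collapse = ", "))
  new("PreprocessedCube", data = d, wavelengths = cube@wavelengths,
      sourceId = cube@sourceId, stage = "bandnorm",
      constantBands = constant, constantPixels = 0L)
}

#' Standard Normal Variate (SNV) spectral normalization
#'
#' Second preprocessing phase: every pixel's W-band spectrum is centred and
#' scaled to mean 0, sample standard deviation 1 (denominator W - 1). SNV
#' satisfies `snv(a*v + b) = snv(v)` for any gain a > 0 and offset b, which
#' is exactly what removes the multiplicative illumination variation
#' inherent to the acquisition. Constant-spectrum pixels are mapped to all
#' zeros and counted in `constantPixels` (division-by-zero guard).
#'
#' @param cube a [PreprocessedCube-class] with `stage = "bandnorm"` and
#'   W >= 2 bands.
#' @return a [PreprocessedCube-class] with `stage = "bandnorm+snv"`.
#' @examples
#' cube <- SpectralCube(array(runif(48), c(4, 4, 3)))
#' sc <- snv(normalizeBands(cube))
#' rowSums(matrix(cubeData(sc), 16, 3))  # per-pixel means are 0
#' @export
snv <- function(cube) {
  stopifnot(is(cube, "PreprocessedCube"))
  if (cube@stage != "bandnorm")
    stop("snv expects a band-normalized cube (stage 'bandnorm')")
  d <- cube@data
  dims <- dim(d)
  W <- dims[3]
  if (W < 2L) stop("SNV needs at least 2 bands")
  spectra <- matrix(d, nrow = dims[1] * dims[2], ncol = W)
  mu <- rowMeans(spectra)
  cs <- spectra - mu
  sdv <- sqrt(rowSums(cs^2) / (W - 1))
  flat <- sdv < 1e-300
  sdv[flat] <- 1
  out <- cs / sdv
  out[flat, ] <- 0
  nFlat <- sum(flat)
  if (nFlat > 0)
    warning(nFlat, " constant-spectrum pixel(s) mapped to zero")
  new("PreprocessedCube", data = array(out, dims),
      wavelengths = cube@wavelengths, sourceId = cube@sourceId,
      stage = "bandnorm+snv", constantBands = cube@constantBands,
      constantPixels = as.integer(nFlat))
}
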