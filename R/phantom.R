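#' @importFrom stats runif rnorm
NULL

#' Generate a synthetic multispectral phantom
#'
#' Builds a cube with the statistical structure the segmentation method
#' assumes: 2-3 spectrally distinct regions (surround, sample, optional
#' fat speckles), additive Gaussian noise, and a per-pixel multiplicative
#' gain drawn once per pixel and shared across all bands -- the
#' illumination structure that SNV preprocessing removes. Pixel values are
#' `gain(x, y) * signature_region(w) + noise`, clipped at 0. Fully
#' deterministic for a given seed; the three truth masks partition the
#' image.
#'
#' @param spec a [PhantomSpec-class].
#' @return a [PhantomTruth-class].
#' @examples
#' tt <- makePhantom(phantomPreset("meat", m = 64, seed = 7))
#' areaFraction(tt@truthSample)
#' @export
makePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  m <- spec@shape[1]; n <- spec@shape[2]; W <- spec@shape[3]
  rows <- matrix(seq_len(m), m, n)
  cols <- matrix(seq_len(n), m, n, byrow = TRUE)
  lab <- matrix(1L, m, n)                       # 1 = surround
  for (k in seq_len(nrow(spec@ellipses))) {
    e <- spec@ellipses[k, ]
    lab[((rows - e[1]) / e[3])^2 + ((cols - e[2]) / e[4])^2 <= 1] <- 2L
  }
  data <- array(0, c(m, n, W))
  .withSeed(spec@seed, {
    if (spec@fatCount > 0L) {
      inSample <- which(lab == 2L)
      centers <- sample(inSample, spec@fatCount, replace = FALSE)
      radii <- runif(spec@fatCount, spec@fatSizeRange[1], spec@fatSizeRange[2])
      for (k in seq_len(spec@fatCount)) {
        ci <- ((centers[k] - 1) %% m) + 1
        cj <- ((centers[k] - 1) %/% m) + 1
        blob <- (rows - ci)^2 + (cols - cj)^2 <= radii[k]^2
        lab[blob & lab == 2L] <- 3L            # fat only inside the sample
      }
    }
    # bell-shaped illumination variation: normal centred in the gain
    # interval, truncated at 3 sigma to its bounds
    gc <- mean(spec@gainRange)
    gs <- diff(spec@gainRange) / 6
    if (gs > 0) {
      u <- runif(m * n)
      p3 <- stats::pnorm(3)
      gain <- matrix(gc + gs * stats::qnorm((1 - p3) + u * (2 * p3 - 1)),
                     m, n)
    } else {
      gain <- matrix(gc, m, n)
    }
    for (w in seq_len(W)) {
      sig <- spec@signatures[, w]
      data[, , w] <- gain * matrix(sig[lab], m, n) +
        rnorm(m * n, 0, spec@noiseSd)
    }
  })
  data <- pmax(data, 0)
  cube <- SpectralCube(data, wavelengths = spec@wavelengths,
                       sourceId = sprintf("phantom:%s:seed%d", spec@name,
                                          spec@seed))
  new("PhantomTruth", cube = cube,
      truthSample = BinaryMask(lab == 2L, label = "informative_final"),
      truthFat = BinaryMask(lab == 3L),
      truthSurround = BinaryMask(lab == 1L),
      spec = spec)
}

#' Build a custom phantom specification
#'
#' @param shape integer (m, n, W).
#' @param ellipses matrix with columns cx, cy, rx, ry (pixels), one sample
#'   ellipse per row.
#' @param signatures 3 x W matrix of region spectra in [0, 1] (rows
#'   surround, sample, fat).
#' @param wavelengths W wavelengths in nm.
#' @param fatCount,fatSizeRange fat speckle count and radius range.
#' @param noiseSd additive noise standard deviation.
#' @param gainRange per-pixel multiplicative gain interval.
#' @param seed RNG seed (mandatory).
#' @param name free-text tag.
#' @return a validated [PhantomSpec-class].
#' @seealso [phantomPreset()] for ready-made archetypes.
#' @export
phantomSpec <- function(shape, ellipses, signatures, wavelengths,
                        fatCount = 0L, fatSizeRange = c(3, 7),
                        noiseSd = 0.02, gainRange = c(0.8, 1.2),
                        seed = 1L, name = "custom") {
  new("PhantomSpec", shape = as.integer(shape),
      ellipses = matrix(as.numeric(ellipses), ncol = 4L),
      fatCount = as.integer(fatCount), fatSizeRange = as.numeric(fatSizeRange),
      signatures = unname(signatures), wavelengths = as.numeric(wavelengths),
      noiseSd = noiseSd, gainRange = as.numeric(gainRange),
      seed = as.integer(seed), name = name)
}

#' Phantom presets mirroring the food archetypes
#'
#' Ready-made [PhantomSpec-class]s for desk-scale testing, 18 bands over
#' 405-970 nm:
#' \describe{
#'   \item{meat}{central disk of lean tissue with fat speckle blobs on a
#'     dark surround. The lean spectrum rises linearly across the bands;
#'     the fat spectrum rises in parallel up to mid-spectrum and folds
#'     back, so one family of band pairs contrasts the whole sample (lean
#'     + fat together) against the surround, while another contrasts fat
#'     against lean -- the structure the two-stage cascade expects.}
#'   \item{creme}{one homogeneous sample disk with a mild spectral slope
#'     and no fat class; the gain interval is narrow ([0.95, 1.05])
#'     because the archetype is a glossy, homogeneous surface. Stage 2
#'     then sees a unimodal histogram and must take the tail-rejection
#'     path.}
#'   \item{olives}{five small dark ellipses clustered near the image
#'     centre on a bright dish.}
#' }
#'
#' @param name `"meat"`, `"creme"`, or `"olives"`.
#' @param m image side in pixels (square images; default 256 for
#'   desk-scale work, full instrument size 1200 is supported).
#' @param seed RNG seed passed into the spec.
#' @return a [PhantomSpec-class].
#' @examples
#' phantomPreset("meat", m = 128, seed = 3)
#' @export
phantomPreset <- function(name = c("meat", "creme", "olives"), m = 256L,
                          seed = 1L) {
  name <- match.arg(name)
  W <- 18L
  wl <- round(seq(405, 970, length.out = W))
  r <- (seq_len(W) - 1) / (W - 1)
  m <- as.integer(m)
  ctr <- (m + 1) / 2
  if (name == "meat") {
    surround <- rep(0.10, W)
    lean <- 0.35 + 0.45 * r
    # parallel to lean up to band 12, then folds back down: fat(7) ==
    # fat(17) and fat(6) == fat(18), giving stage 2 a pair in which lean
    # keeps its full contrast while fat has none
    fat <- 0.57 + 0.45 * r
    fat[13:18] <- seq(fat[12], 0.57 + 0.45 * r[6], length.out = 7)[-1]
    phantomSpec(shape = c(m, m, W),
                ellipses = matrix(c(ctr, ctr, 0.36 * m, 0.36 * m), 1),
                signatures = rbind(surround, lean, fat),
                wavelengths = wl,
                fatCount = max(1L, as.integer(round(25 * (m / 256)^2))),
                fatSizeRange = c(3, 7) * m / 256,
                noiseSd = 0.02, gainRange = c(0.8, 1.2),
                seed = seed, name = "meat")
  } else if (name == "creme") {
    # opposing spectral slopes (a dish has its own colour): sample and
    # surround then move in opposite directions in every signed band
    # difference, so any candidate pair separates the two regions
    surround <- 0.60 - 0.35 * r
    sample <- 0.28 + 0.62 * r
    fat <- rep(0, W)   # unused: no fat class
    phantomSpec(shape = c(m, m, W),
                ellipses = matrix(c(ctr, ctr, 0.38 * m, 0.38 * m), 1),
                signatures = rbind(surround, sample, fat),
                wavelengths = wl,
                fatCount = 0L, noiseSd = 0.02, gainRange = c(0.95, 1.05),
                seed = seed, name = "creme")
  } else {
    surround <- 0.62 - 0.25 * r
    olive <- 0.12 + 0.45 * r
    fat <- rep(0, W)
    off <- 0.17 * m
    cs <- rbind(c(ctr - off, ctr - off), c(ctr - off, ctr + off),
                c(ctr + off, ctr - off), c(ctr + off, ctr + off),
                c(ctr, ctr))
    ell <- cbind(cs, rep(0.10 * m, 5), rep(0.12 * m, 5))
    phantomSpec(shape = c(m, m, W), ellipses = ell,
                signatures = rbind(surround, olive, fat),
                wavelengths = wl,
                fatCount = 0L, noiseSd = 0.02, gainRange = c(0.8, 1.2),
                seed = seed, name = "olives")
  }
}
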