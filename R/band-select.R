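#' Sobel gradient magnitude
#'
#' Per-pixel gradient magnitude `sqrt(Gx^2 + Gy^2)` with the standard 3 x 3
#' Sobel kernels; border pixels are computed with edge (reflect) padding so
#' every pixel of the input receives an edge value.
#'
#' @param image numeric matrix, at least 3 x 3, finite.
#' @return matrix of nonnegative edge magnitudes (all zero for a constant
#'   input).
#' @examples
#' step <- cbind(matrix(0, 8, 4), matrix(1, 8, 4))
#' range(sobelMagnitude(step))
#' @export
sobelMagnitude <- function(image) {
  stopifnot(is.matrix(image))
  if (nrow(image) < 3L || ncol(image) < 3L)
    stop("image must be at least 3 x 3")
  if (!all(is.finite(image))) stop("image contains non-finite values")
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  gx <- .conv3(image, kx)
  gy <- .conv3(image, t(kx))
  sqrt(gx^2 + gy^2)
}

#' Edge-based contrast measure (EBCM)
#'
#' The mean over all pixels of the per-pixel contrast
#' `c(x, y) = |I - e| / (I + e)`, where `e(x, y)` is the edge-weighted mean
#' grey level of the 3 x 3 neighbourhood: `sum(g * I) / sum(g)` with `g`
#' the Sobel edge magnitude. EBCM is large for an image full of edges and
#' small for one made of smooth plateaus; on [0, 1] images it lies in
#' [0, 1] and is exactly 0 for a constant image.
#'
#' Degenerate-pixel conventions: where the neighbourhood edge weight
#' `sum(g)` is 0, `e` is taken equal to the pixel value (so `c = 0`: a
#' neighbourhood with no edges contributes no contrast); where `I + e = 0`,
#' `c = 0` (the limit along I = e).
#'
#' @param image numeric matrix with values in [0, 1].
#' @param mask optional logical matrix; when supplied, the average runs
#'   only over `mask` pixels (edge values still use the full image).
#' @return scalar in [0, 1].
#' @seealso [selectBandPair()], which ranks band pairs by this measure.
#' @examples
#' ebcm(matrix(0.5, 8, 8))                       # no edges -> 0
#' ebcm(matrix(runif(64), 8, 8)) > 0.1           # speckle -> many edges
#' @export
ebcm <- function(image, mask = NULL) {
  stopifnot(is.matrix(image))
  if (min(image) < -1e-9 || max(image) > 1 + 1e-9)
    stop("ebcm expects grey levels in [0, 1]")
  image <- pmin(pmax(image, 0), 1)
  g <- sobelMagnitude(image)
  ones <- matrix(1, 3, 3)
  num <- .conv3(g * image, ones)
  den <- .conv3(g, ones)
  e <- image
  pos <- den > 0
  e[pos] <- num[pos] / den[pos]
  s <- image + e
  cmap <- matrix(0, nrow(image), ncol(image))
  nz <- s > 0
  cmap[nz] <- abs(image[nz] - e[nz]) / s[nz]
  if (is.null(mask)) mean(cmap) else mean(cmap[mask])
}

# form and rescale one band-pair combination; returns NULL when constant
.combineBands <- function(bi, bj, combiner, maskIdx = NULL) {
  d <- switch(combiner,
    difference = bi - bj,
    absdiff = abs(bi - bj),
    ratio = (bi + 1e-6) / (bj + 1e-6))
  vals <- if (is.null(maskIdx)) d else d[maskIdx]
  r <- .rescale01(d, min(vals), max(vals))
  if (is.null(r)) return(NULL)
  pmin(pmax(r, 0), 1)   # out-of-mask pixels may fall outside [0,1]
}

#' Unsupervised spectral band-pair selection
#'
#' For every candidate pair of bands, forms the combination image (signed
#' difference `band_i - band_j` by default), rescales it to [0, 1] and scores it with
#' [ebcm()]; pairs are ranked by ascending score and the minimizer's
#' difference image is returned. Minimizing (not maximizing) edge contrast
#' picks the pair whose combination is "blurry" -- a few flat, well
#' separated plateaus -- rather than one that etches every detail, which is
#' what a thresholding stage wants. A pair of identical bands yields a
#' constant difference and hence the absolute minimum score of 0. Ties are
#' broken by the lexicographically smaller (i, j). Fully deterministic.
#'
#' When `mask` is supplied the score average and the difference-image
#' rescaling use only pixels inside the mask (restriction to a
#' previous-stage foreground).
#'
#' @param cube a [PreprocessedCube-class] (band-normalized; grey levels
#'   must be nonnegative) or any [SpectralCube-class] with values in
#'   [0, 1].
#' @param candidates optional integer matrix with columns (i, j) of band
#'   pairs to score; default all `choose(W, 2)` unordered pairs.
#' @param mask optional [BinaryMask-class], nonempty.
#' @param combiner `"difference"` (signed difference, min-max rescaled:
#'   the rescale restores nonnegativity and, unlike the absolute value,
#'   keeps regions that shift in opposite directions distinguishable),
#'   `"absdiff"`, or `"ratio"`.
#' @return a list with elements `ranking` (data.frame `i`, `j`, `ebcm`,
#'   ascending), `pair` (winning (i, j)), and `diffImage` (the winner's
#'   combination image rescaled to [0, 1]).
#' @examples
#' tt <- makePhantom(phantomPreset("creme", m = 48))
#' sel <- selectBandPair(normalizeBands(tt@cube))
#' head(sel$ranking)
#' @export
selectBandPair <- function(cube, candidates = NULL, mask = NULL,
                           combiner = c("difference", "absdiff", "ratio")) {
  stopifnot(is(cube, "SpectralCube"))
  combiner <- match.arg(combiner)
  d <- cube@data
  W <- dim(d)[3]
  if (W < 2L) stop("band-pair selection needs at least 2 bands")
  maskIdx <- NULL
  maskMat <- NULL
  if (!is.null(mask)) {
    stopifnot(is(mask, "BinaryMask"))
    .stopIfEmpty(mask, "restriction mask")
    if (!all(dim(mask@data) == dim(d)[1:2]))
      stop("mask shape does not match the cube")
    maskMat <- mask@data
    maskIdx <- which(maskMat)
  }
  if (is.null(candidates)) {
    candidates <- t(utils::combn(W, 2L))
  } else {
    candidates <- matrix(as.integer(candidates), ncol = 2L)
    if (any(candidates < 1L) || any(candidates > W) ||
        any(candidates[, 1] >= candidates[, 2]))
      stop("candidates must be pairs (i, j) with 1 <= i < j <= W")
  }
  nPair <- nrow(candidates)
  scores <- numeric(nPair)
  anyContrast <- FALSE
  for (p in seq_len(nPair)) {
    img <- .combineBands(d[, , candidates[p, 1]], d[, , candidates[p, 2]],
                         combiner, maskIdx)
    if (is.null(img)) {
      scores[p] <- 0      # constant combination: no edges at all
    } else {
      anyContrast <- TRUE
      scores[p] <- ebcm(img, maskMat)
    }
  }
  if (!anyContrast) stop("no contrast in cube: every candidate pair is constant")
  o <- order(scores, candidates[, 1], candidates[, 2])
  ranking <- data.frame(i = candidates[o, 1], j = candidates[o, 2],
                        ebcm = scores[o])
  win <- c(ranking$i[1], ranking$j[1])
  img <- .combineBands(d[, , win[1]], d[, , win[2]], combiner, maskIdx)
  if (is.null(img)) img <- matrix(0, dim(d)[1], dim(d)[2])
  list(ranking = ranking, pair = as.integer(win), diffImage = img)
}
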