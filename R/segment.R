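#' @importFrom EBImage bwlabel fillHull
NULL

# connected-component cleanup: drop components < minSize, fill holes < maxHole
.cleanupMask <- function(mask, minSize, maxHole) {
  if (minSize > 0L && any(mask)) {
    lab <- EBImage::bwlabel(mask * 1)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= minSize)
    mask <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  }
  if (maxHole > 0L && any(mask)) {
    holes <- EBImage::fillHull(mask * 1) > 0 & !mask
    if (any(holes)) {
      lab <- EBImage::bwlabel(holes * 1)
      sizes <- tabulate(lab[lab > 0])
      fill <- which(sizes < maxHole)
      mask <- mask | matrix(lab %in% fill, nrow(mask), ncol(mask))
    }
  }
  mask
}

# identify which side of a Bayes threshold is the food sample
.foregroundSide <- function(diffImage, t, restrict, rule) {
  if (rule %in% c("above", "below")) return(rule)
  m <- nrow(diffImage); n <- ncol(diffImage)
  inside <- if (is.null(restrict)) matrix(TRUE, m, n) else restrict
  if (rule == "central") {
    # central window of 25% area: half side-length per axis
    rows <- (floor(m / 4) + 1L):floor(3 * m / 4)
    cols <- (floor(n / 4) + 1L):floor(3 * n / 4)
    win <- matrix(FALSE, m, n)
    win[rows, cols] <- TRUE
    win <- win & inside
    if (!any(win)) win <- inside   # degenerate window: fall back
    inside <- win
  }
  nAbove <- sum(diffImage[inside] > t)
  nBelow <- sum(inside) - nAbove
  if (nAbove >= nBelow) "above" else "below"
}

#' Run one stage of the segmentation cascade
#'
#' Selects the band pair minimizing the edge-based contrast measure
#' (restricted to `restrict` when given), fits a 1-vs-2 component Gaussian
#' mixture to the winning difference image's intensities by
#' [selectModel()], derives the threshold ([bayesThreshold()] for two
#' components, [kurtosisThreshold()] for one), identifies the foreground
#' side, and thresholds the difference image into a mask. Optional
#' connected-component cleanup is applied when configured.
#'
#' @param cube a band-normalized [PreprocessedCube-class].
#' @param restrict optional nonempty [BinaryMask-class]; the stage then
#'   operates only on pixels inside it (stage 2 of the cascade).
#' @param config a [PipelineConfig-class].
#' @param label label given to the output mask.
#' @return a [StageResult-class].
#' @seealso [runPipeline()]
#' @export
segmentStage <- function(cube, restrict = NULL, config = pipelineConfig(),
                         label = "custom") {
  stopifnot(is(cube, "PreprocessedCube"), is(config, "PipelineConfig"))
  restrictMat <- NULL
  if (!is.null(restrict)) {
    stopifnot(is(restrict, "BinaryMask"))
    .stopIfEmpty(restrict, "restriction mask")
    restrictMat <- restrict@data
    if (sum(restrictMat) < 10)
      stop("restriction mask too small to fit a mixture (",
           sum(restrictMat), " pixels)")
  }
  sel <- selectBandPair(cube, mask = restrict, combiner = config@combiner)
  diffImage <- sel$diffImage
  vals <- if (is.null(restrictMat)) as.vector(diffImage) else
    diffImage[restrictMat]
  model <- selectModel(vals, config@fit)
  if (model@ncomp == 2L) {
    # bimodality guard: a Bayes crossing is only meaningful between
    # genuinely separated populations
    D <- abs(diff(model@means)) /
      sqrt(mean(model@variances))
    if (D < config@minSeparation)
      model <- fitEM(vals, 1L, config@fit)
  }
  if (model@ncomp >= 2L) {
    decision <- bayesThreshold(model)
    side <- .foregroundSide(diffImage, decision@threshold, restrictMat,
                            config@foregroundRule)
    decision@foregroundSide <- side
  } else {
    decision <- kurtosisThreshold(vals, model, config@fit)
    side <- decision@foregroundSide
  }
  t <- decision@threshold
  sideMat <- if (side == "above") diffImage > t else diffImage <= t
  if (!is.null(restrictMat)) sideMat <- sideMat & restrictMat
  sideMat <- .cleanupMask(sideMat, config@cleanupMinSize, config@cleanupMaxHole)
  new("StageResult", pair = sel$pair, ranking = sel$ranking,
      diffImage = diffImage, decision = decision,
      mask = BinaryMask(sideMat, label = label))
}

#' Apply a binary mask to a cube
#'
#' Excluded pixels are set to NaN in every band; included pixels are
#' unchanged.
#'
#' @param cube a [SpectralCube-class].
#' @param mask a nonempty [BinaryMask-class] of matching spatial shape.
#' @return a [SpectralCube-class] with NaN at excluded pixels.
#' @examples
#' cube <- SpectralCube(array(runif(27), c(3, 3, 3)))
#' msk <- BinaryMask(matrix(c(rep(TRUE, 5), rep(FALSE, 4)), 3, 3))
#' sum(is.nan(cubeData(applyMask(cube, msk))))
#' @export
applyMask <- function(cube, mask) {
  stopifnot(is(cube, "SpectralCube"), is(mask, "BinaryMask"))
  .stopIfEmpty(mask)
  if (!all(dim(mask@data) == dim(cube@data)[1:2]))
    stop("mask shape does not match the cube")
  d <- cube@data
  excl <- which(!mask@data)
  W <- dim(d)[3]
  mn <- prod(dim(d)[1:2])
  for (w in seq_len(W)) d[excl + (w - 1) * mn] <- NaN
  new("SpectralCube", data = d, wavelengths = cube@wavelengths,
      sourceId = cube@sourceId)
}

#' Run the full two-stage segmentation cascade
#'
#' The complete automated pipeline: per-band min-max normalization, SNV
#' (retained in the result for spectral export), stage 1 (band selection +
#' mixture threshold on the full image: background removal), stage 2 (the
#' same restricted to the stage-1 foreground: fat/connective-tissue
#' removal; skippable for products without such a class), final mask =
#' intersection of the stage masks, applied to all bands of the input
#' cube. A stage-2 failure degrades gracefully to the stage-1 mask with a
#' logged warning. Fully deterministic for a given cube and config.
#'
#' Band selection and thresholding operate on the band-normalized (not the
#' SNV) representation: the contrast measure needs nonnegative grey
#' levels, and SNV output is signed.
#'
#' @param cube a [SpectralCube-class].
#' @param config a [PipelineConfig-class].
#' @return a [SegmentationResult-class].
#' @examples
#' tt <- makePhantom(phantomPreset("creme", m = 48))
#' res <- runPipeline(tt@cube)
#' areaFraction(finalMask(res))
#' @export
runPipeline <- function(cube, config = pipelineConfig()) {
  stopifnot(is(cube, "SpectralCube"), is(config, "PipelineConfig"))
  validObject(cube)
  log <- character(0)
  pc <- normalizeBands(cube)
  snvCube <- snv(pc)
  stage1 <- segmentStage(pc, restrict = NULL, config = config,
                         label = "foreground_stage1")
  log <- c(log, sprintf("stage1: bands (%d,%d), %s threshold %.6g, %d px",
                        stage1@pair[1], stage1@pair[2],
                        stage1@decision@method, stage1@decision@threshold,
                        sum(stage1@mask@data)))
  if (isEmptyMask(stage1@mask))
    stop("stage 1 produced an empty foreground mask")
  stage2 <- NULL
  finalData <- stage1@mask@data
  if (!config@skipStage2) {
    stage2 <- tryCatch(
      segmentStage(pc, restrict = stage1@mask, config = config,
                   label = "informative_final"),
      error = function(e) {
        warning("stage 2 failed (", conditionMessage(e),
                "); falling back to the stage-1 mask")
        NULL
      })
    if (!is.null(stage2)) {
      if (isEmptyMask(stage2@mask)) {
        log <- c(log, "stage2: empty mask, falling back to stage-1 mask")
        stage2 <- NULL
      } else {
        finalData <- stage1@mask@data & stage2@mask@data
        log <- c(log, sprintf(
          "stage2: bands (%d,%d), %s threshold %.6g, %d px",
          stage2@pair[1], stage2@pair[2], stage2@decision@method,
          stage2@decision@threshold, sum(stage2@mask@data)))
      }
    } else {
      log <- c(log, "stage2: failed, falling back to stage-1 mask")
    }
  } else {
    log <- c(log, "stage2: skipped by config")
  }
  final <- BinaryMask(finalData, label = "informative_final")
  new("SegmentationResult", stage1 = stage1, stage2 = stage2,
      finalMask = final, maskedCube = applyMask(cube, final),
      snvCube = snvCube, config = config, log = log)
}
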