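#' Informative-area fraction of a mask
#'
#' Ratio of included pixels to the total image area, in [0, 1]. An
#' empty-flagged mask gives 0.
#'
#' @param mask a [BinaryMask-class].
#' @return scalar in [0, 1].
#' @examples
#' areaFraction(BinaryMask(matrix(TRUE, 4, 4)))
#' @export
areaFraction <- function(mask) {
  stopifnot(is(mask, "BinaryMask"))
  sum(mask@data) / length(mask@data)
}

#' Linear regression of paired area fractions
#'
#' Ordinary least squares `y = a*x + b` between area fractions measured by
#' two methods on the same samples, with goodness of fit (R-square, RMSE of
#' the residuals) and the Pearson correlation with its exact two-sided
#' t-distribution p-value (n - 2 degrees of freedom).
#'
#' @param x,y numeric vectors of equal length >= 3; `x` must not be
#'   constant.
#' @return list with `a` (slope), `b` (intercept), `r_square`, `rmse`,
#'   `r`, `p_value`, `n`.
#' @examples
#' regressAreas(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3))$a
#' @export
regressAreas <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 samples")
  if (sd(x) < 1e-300) stop("zero variance in x")
  fit <- lm(y ~ x)
  res <- fit$residuals
  ssTot <- sum((y - mean(y))^2)
  r2 <- if (ssTot < 1e-300) 1 else 1 - sum(res^2) / ssTot
  ct <- suppressWarnings(cor.test(x, y, method = "pearson"))
  list(a = unname(fit$coefficients[2]), b = unname(fit$coefficients[1]),
       r_square = r2, rmse = sqrt(mean(res^2)),
       r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Binary colocalization of two masks
#'
#' Percentages of overlap with `basis` taken as the reference
#' ("ground-truth") mask: `coloc_pct = |A intersect B| / |B| * 100`,
#' `excl_a_pct = |A \\ B| / |B| * 100` (area detected only by A),
#' `excl_b_pct = |B \\ A| / |B| * 100` (area detected only by the basis;
#' `coloc_pct + excl_b_pct = 100` by construction). Dice and Jaccard
#' coefficients are included as symmetric convenience summaries.
#'
#' @param a a [BinaryMask-class] (the method under evaluation).
#' @param basis a nonempty [BinaryMask-class] (the reference).
#' @return one-row data.frame with columns `coloc_pct`, `excl_a_pct`,
#'   `excl_b_pct`, `dice`, `jaccard`.
#' @seealso [colocalizeMany()] for set-level aggregation.
#' @examples
#' b <- BinaryMask(matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2))
#' colocalize(b, b)$coloc_pct
#' @export
colocalize <- function(a, basis) {
  stopifnot(is(a, "BinaryMask"), is(basis, "BinaryMask"))
  .stopIfEmpty(basis, "basis mask")
  if (!all(dim(a@data) == dim(basis@data)))
    stop("mask shapes do not match")
  A <- a@data; B <- basis@data
  nB <- sum(B)
  inter <- sum(A & B)
  onlyA <- sum(A & !B)
  onlyB <- sum(B & !A)
  union <- inter + onlyA + onlyB
  data.frame(coloc_pct = 100 * inter / nB,
             excl_a_pct = 100 * onlyA / nB,
             excl_b_pct = 100 * onlyB / nB,
             dice = if (sum(A) + nB > 0) 2 * inter / (sum(A) + nB) else 0,
             jaccard = if (union > 0) inter / union else 0)
}

#' Colocalization over a sample set
#'
#' Applies [colocalize()] to paired lists of masks and aggregates each
#' percentage to its mean and standard error (sample sd / sqrt(n)) across
#' samples.
#'
#' @param as list of [BinaryMask-class] (method under evaluation).
#' @param bases list of reference [BinaryMask-class], same length.
#' @return list with `samples` (per-sample data.frame) and `summary`
#'   (data.frame with rows `mean` and `se`).
#' @export
colocalizeMany <- function(as, bases) {
  if (length(as) != length(bases)) stop("as and bases must have equal length")
  if (length(as) == 0L) stop("empty sample set")
  perSample <- do.call(rbind, Map(colocalize, as, bases))
  mu <- colMeans(perSample)
  se <- apply(perSample, 2, sd) / sqrt(nrow(perSample))
  summary <- rbind(mean = mu, se = se)
  list(samples = perSample, summary = as.data.frame(summary))
}

#' Per-band reflectance summary over a mask
#'
#' Mean and standard deviation of the reflectance at each wavelength over
#' the included pixels; NaN entries (pixels excluded by a previous mask
#' application) are ignored.
#'
#' @param cube a [SpectralCube-class].
#' @param mask a nonempty [BinaryMask-class] of matching spatial shape.
#' @return data.frame with columns `wavelength`, `mean`, `sd`.
#' @examples
#' tt <- makePhantom(phantomPreset("creme", m = 32))
#' head(bandSummary(tt@cube, tt@truthSample))
#' @export
bandSummary <- function(cube, mask) {
  stopifnot(is(cube, "SpectralCube"), is(mask, "BinaryMask"))
  .stopIfEmpty(mask)
  if (!all(dim(mask@data) == dim(cube@data)[1:2]))
    stop("mask shape does not match the cube")
  idx <- which(mask@data)
  W <- dim(cube@data)[3]
  mn <- prod(dim(cube@data)[1:2])
  means <- numeric(W); sds <- numeric(W)
  for (w in seq_len(W)) {
    v <- cube@data[idx + (w - 1) * mn]
    v <- v[!is.nan(v)]
    if (length(v) == 0L) stop("mask covers only NaN pixels in band ", w)
    means[w] <- mean(v)
    sds[w] <- if (length(v) > 1L) sd(v) else 0
  }
  data.frame(wavelength = cube@wavelengths, mean = means, sd = sds)
}
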