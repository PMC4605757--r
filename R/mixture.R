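#' @importFrom stats dnorm quantile lm cor.test sd pnorm
NULL

# histogram binning: equal-width bins over the data range
.binValues <- function(values, nBins) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) stop("no finite values to fit")
  lo <- min(values); hi <- max(values)
  if (hi - lo < 1e-300)
    return(list(centers = lo, counts = length(values)))
  br <- seq(lo, hi, length.out = nBins + 1L)
  idx <- findInterval(values, br, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(idx, nbins = nBins)
  keep <- counts > 0
  list(centers = ((br[-1] + br[-length(br)]) / 2)[keep],
       counts = counts[keep])
}

# weighted type-1 quantile
.wquantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) x[which(cw >= p - 1e-12)[1]], numeric(1))
}

#' Fit a 1-D Gaussian mixture by EM
#'
#' Weighted (histogram-binned) EM for a C-component univariate Gaussian
#' mixture. Raw intensities are reduced to an `nBins`-bin weighted
#' histogram, so a megapixel image fits in milliseconds and the fit is a
#' pure function of the histogram. Initialization is deterministic --
#' means at evenly spaced weighted quantiles `(2k - 1) / (2C)`, equal
#' weights, variances at the data variance -- so there is no random
#' restart and identical inputs give identical fits. The log-likelihood is
#' nondecreasing over iterations (EM guarantee; recorded in
#' `loglikTrace`); iteration stops when its relative change drops below
#' `emTol` or after `maxIter` iterations. Component variances are floored
#' at `varianceFloor` times the data variance to prevent collapse on
#' spike-shaped histograms.
#'
#' @param values numeric sample of intensities, or bin centers when
#'   `counts` is given.
#' @param C number of components (>= 1).
#' @param config a [FitConfig-class].
#' @param counts optional bin counts (weights) matching `values`.
#' @return a [Mixture1D-class], components sorted by ascending mean, with
#'   its [messageLength()] score filled in.
#' @details All-identical data is degenerate: the fit collapses to a
#'   single component at the common value with the floor variance and the
#'   `"degenerate"` flag, whatever C was requested. At least `10 * C`
#'   effective observations are required.
#' @examples
#' x <- c(rnorm(5000, 0.3, 0.02), rnorm(5000, 0.7, 0.02))
#' fit <- fitEM(x, C = 2)
#' mixtureMeans(fit)
#' @export
fitEM <- function(values, C, config = fitConfig(), counts = NULL) {
  stopifnot(is(config, "FitConfig"))
  C <- as.integer(C)
  if (C < 1L) stop("C must be >= 1")
  if (is.null(counts)) {
    b <- .binValues(values, config@nBins)
    x <- b$centers; w <- as.numeric(b$counts)
  } else {
    if (length(counts) != length(values))
      stop("counts must match values in length")
    keep <- counts > 0
    x <- values[keep]; w <- as.numeric(counts[keep])
  }
  n <- sum(w)
  if (n < 10 * C)
    stop("need at least 10*C effective observations, got ", n)

  wm <- sum(w * x) / n
  v0 <- sum(w * (x - wm)^2) / n
  if (v0 < 1e-300) {
    # all observations identical: single floored component
    floorVar <- 1e-12
    fit <- new("Mixture1D", weights = 1, means = wm, variances = floorVar,
               ncomp = 1L, loglik = sum(w * dnorm(x, wm, sqrt(floorVar), log = TRUE)),
               loglikTrace = numeric(0), n = n, converged = TRUE,
               flags = "degenerate")
    fit@messageLength <- messageLength(fit)
    return(fit)
  }
  floorVar <- config@varianceFloor * v0

  mu <- .wquantile(x, w, (2 * seq_len(C) - 1) / (2 * C))
  if (anyDuplicated(mu))
    mu <- mu + seq(-1, 1, length.out = C) * 1e-6 * (max(x) - min(x))
  sig2 <- rep(v0, C)
  pi <- rep(1 / C, C)

  ll <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(config@maxIter)) {
    ld <- vapply(seq_len(C),
                 function(m) dnorm(x, mu[m], sqrt(sig2[m]), log = TRUE) +
                   log(pi[m]),
                 numeric(length(x)))
    ld <- matrix(ld, ncol = C)
    mx <- do.call(pmax, c(as.data.frame(ld), list(na.rm = TRUE)))
    lse <- mx + log(rowSums(exp(ld - mx)))
    llNew <- sum(w * lse)
    trace <- c(trace, llNew)
    if (is.finite(ll) &&
        abs(llNew - ll) <= config@emTol * (abs(llNew) + .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    ll <- llNew
    r <- exp(ld - lse)
    Nm <- colSums(w * r)
    Nm <- pmax(Nm, 1e-300)
    pi <- Nm / sum(Nm)
    mu <- colSums(w * r * x) / Nm
    dev <- (matrix(x, length(x), C) - matrix(mu, length(x), C, byrow = TRUE))^2
    sig2 <- pmax(colSums(w * r * dev) / Nm, floorVar)
  }

  o <- order(mu)
  fit <- new("Mixture1D", weights = pi[o] / sum(pi[o]), means = mu[o],
             variances = sig2[o], ncomp = C, loglik = trace[length(trace)],
             loglikTrace = trace, n = n, converged = converged,
             flags = character(0))
  fit@messageLength <- messageLength(fit)
  fit
}

#' Minimum message length (MML) score of a fitted mixture
#'
#' Information-theoretic model-selection score trading data fit against
#' parameter-coding cost:
#' \deqn{ML = \frac{N_p}{2}\sum_m \ln\frac{n\pi_m}{12}
#'   + \frac{C}{2}\ln\frac{n}{12} + \frac{C(N_p+1)}{2} - \log L}
#' with \eqn{N_p = 2} free parameters per univariate Gaussian component.
#' Lower is better. Components with zero weight are excluded from the sum
#' and from the count C.
#'
#' @param model a fitted [Mixture1D-class].
#' @return scalar MML score.
#' @seealso [selectModel()], which minimizes this over candidate C.
#' @examples
#' x <- rnorm(2000, 0.5, 0.05)
#' messageLength(fitEM(x, 1)) < messageLength(fitEM(x, 2))
#' @export
messageLength <- function(model) {
  stopifnot(is(model, "Mixture1D"))
  Np <- 2
  nz <- model@weights > 0
  Cnz <- sum(nz)
  (Np / 2) * sum(log(model@n * model@weights[nz] / 12)) +
    (Cnz / 2) * log(model@n / 12) +
    Cnz * (Np + 1) / 2 -
    model@loglik
}

#' Select the mixture order by MML
#'
#' Fits C = 1 .. `cMax` components by [fitEM()] and returns the fit with
#' the smallest [messageLength()] (ties to the smaller C). This is the
#' automatic decision of whether an intensity histogram is explained by
#' one population or by a mixture of two (informative area vs surround, or
#' lean vs fat).
#'
#' @param values numeric sample of intensities.
#' @param config a [FitConfig-class].
#' @return the winning [Mixture1D-class].
#' @examples
#' x <- c(rnorm(10000, 0.3, 0.02), rnorm(10000, 0.7, 0.02))
#' nComponents(selectModel(x))   # 2
#' @export
selectModel <- function(values, config = fitConfig()) {
  stopifnot(is(config, "FitConfig"))
  b <- .binValues(values, config@nBins)
  fits <- list()
  for (C in seq_len(config@cMax)) {
    fits[[C]] <- fitEM(b$centers, C, config, counts = b$counts)
    if ("degenerate" %in% fits[[C]]@flags) return(fits[[C]])
  }
  scores <- vapply(fits, messageLength, numeric(1))
  fits[[which.min(scores)]]
}

#' Bayes-rule threshold between two mixture components
#'
#' The intensity t at which the two weighted component densities cross,
#' `pi_1 N(t; mu_1, s_1^2) = pi_2 N(t; mu_2, s_2^2)`, taking the root of
#' the underlying quadratic that lies in [mu_1, mu_2]; classification by t
#' then equals MAP classification for every intensity between the means.
#' Under extreme weight/variance imbalance no root may lie in the
#' interval, in which case the posterior crossover is located by dense
#' grid search on [mu_1, mu_2].
#'
#' @param model a [Mixture1D-class] with C = 2 and distinct means.
#' @return a [ThresholdDecision-class] with `method = "bayes"` (the
#'   `foregroundSide` defaults to `"above"`; [segmentStage()] re-assigns
#'   it by its foreground rule).
#' @examples
#' fit <- fitEM(c(rnorm(5000, 0.3, 0.02), rnorm(5000, 0.7, 0.02)), 2)
#' bayesThreshold(fit)
#' @export
bayesThreshold <- function(model) {
  stopifnot(is(model, "Mixture1D"))
  if (model@ncomp != 2L) stop("bayes threshold requires C = 2")
  mu <- model@means; v <- model@variances; pi <- model@weights
  if (abs(mu[2] - mu[1]) < 1e-300) stop("components not separated")

  A <- 1 / (2 * v[2]) - 1 / (2 * v[1])
  B <- mu[1] / v[1] - mu[2] / v[2]
  Cc <- mu[2]^2 / (2 * v[2]) - mu[1]^2 / (2 * v[1]) +
    log(pi[1] / pi[2]) + 0.5 * log(v[2] / v[1])

  t <- NA_real_
  if (abs(A) < 1e-14 * max(1 / v)) {
    # equal variances: linear equation; writing it as midpoint + weight
    # correction makes the symmetric case exact
    t <- (mu[1] + mu[2]) / 2 + v[1] * log(pi[1] / pi[2]) / (mu[2] - mu[1])
  } else {
    disc <- B^2 - 4 * A * Cc
    if (disc >= 0) {
      roots <- (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
      inside <- roots[roots >= mu[1] - 1e-12 & roots <= mu[2] + 1e-12]
      if (length(inside) > 0) t <- inside[1]
    }
  }
  if (!is.finite(t)) {
    # posterior crossover by dense grid search
    grid <- seq(mu[1], mu[2], length.out = 100000L)
    diffLog <- (log(pi[1]) + dnorm(grid, mu[1], sqrt(v[1]), log = TRUE)) -
      (log(pi[2]) + dnorm(grid, mu[2], sqrt(v[2]), log = TRUE))
    t <- grid[which.min(abs(diffLog))]
  }
  t <- min(max(t, mu[1]), mu[2])
  new("ThresholdDecision", threshold = t, method = "bayes",
      CSelected = 2L, foregroundSide = "above", mixture = model)
}

# sample skewness, central-moment (denominator n) form
.skewness <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 < 1e-300) return(0)
  mean((x - m)^3) / m2^1.5
}

#' Tail-rejection threshold for a unimodal histogram
#'
#' When model selection keeps a single Gaussian there is no second
#' population to separate; instead the heavier tail of the intensity
#' distribution (pointed to by the sign of the sample skewness) is
#' rejected at `mu + k*sigma` (positive skew: upper tail) or
#' `mu - k*sigma` (negative skew: lower tail), with mu, sigma taken from
#' the fitted component and k = `kurtosisK`. A perfectly symmetric sample
#' (zero skewness) rejects nothing: the threshold is +Inf with foreground
#' below.
#'
#' @param values the intensities the model was fitted on (used for the
#'   skewness).
#' @param model a [Mixture1D-class] with C = 1.
#' @param config a [FitConfig-class] (supplies `kurtosisK`).
#' @return a [ThresholdDecision-class] with `method = "kurtosis"`;
#'   `foregroundSide` is the non-rejected side.
#' @examples
#' x <- c(rnorm(5000, 0.5, 0.05), rnorm(100, 0.95, 0.01))  # upper tail
#' kurtosisThreshold(x, fitEM(x, 1))
#' @export
kurtosisThreshold <- function(values, model, config = fitConfig()) {
  stopifnot(is(model, "Mixture1D"), is(config, "FitConfig"))
  if (model@ncomp != 1L) stop("kurtosis threshold requires C = 1")
  sk <- .skewness(values)
  mu <- model@means[1]
  sigma <- sqrt(model@variances[1])
  k <- config@kurtosisK
  if (abs(sk) < 1e-10) {
    t <- Inf
    side <- "below"
  } else if (sk > 0) {
    t <- mu + k * sigma
    side <- "below"
  } else {
    t <- mu - k * sigma
    side <- "above"
  }
  new("ThresholdDecision", threshold = t, method = "kurtosis",
      CSelected = 1L, foregroundSide = side, mixture = model)
}
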