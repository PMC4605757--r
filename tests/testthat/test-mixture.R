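test_that("EM recovers well-separated two-component parameters", {
  set.seed(31)
  x <- c(rnorm(10000, 0.3, 0.02), rnorm(10000, 0.7, 0.02))
  fit <- fitEM(x, 2)
  expect_lt(max(abs(mixtureMeans(fit) - c(0.3, 0.7))), 0.01)
  expect_lt(max(abs(mixtureWeights(fit) - 0.5)), 0.03)
  expect_lt(max(abs(sqrt(mixtureVariances(fit)) - 0.02)), 0.005)
  expect_true(fit@converged)
})

test_that("single-component EM is the closed-form weighted mean/variance", {
  set.seed(32)
  centers <- runif(40)
  counts <- sample(1:50, 40, replace = TRUE)
  fit <- fitEM(centers, 1, counts = counts)
  n <- sum(counts)
  wm <- sum(counts * centers) / n
  expect_equal(mixtureMeans(fit), wm, tolerance = 1e-9)
  expect_equal(mixtureVariances(fit), sum(counts * (centers - wm)^2) / n,
               tolerance = 1e-9)
})

test_that("EM log-likelihood is nondecreasing on every run", {
  set.seed(33)
  for (rep in 1:10) {
    x <- c(rnorm(3000, runif(1, 0.2, 0.4), runif(1, 0.01, 0.1)),
           rnorm(3000, runif(1, 0.5, 0.9), runif(1, 0.01, 0.1)))
    fit <- fitEM(x, 2)
    tr <- fit@loglikTrace
    expect_true(all(diff(tr) >= -1e-8 * pmax(abs(tr[-length(tr)]), 1)))
  }
})

test_that("binned EM agrees with an established raw-sample fitter", {
  suppressMessages(library(mclust))
  set.seed(34)
  x <- c(rnorm(8000, 0.35, 0.03), rnorm(12000, 0.75, 0.05))
  fit <- fitEM(x, 2)
  mc <- Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_lt(max(abs(sort(mc$parameters$mean) - mixtureMeans(fit))), 0.005)
  expect_lt(max(abs(sort(mc$parameters$pro) - sort(mixtureWeights(fit)))),
            0.02)
})

test_that("degenerate all-identical data collapses to a flagged single component", {
  fit <- fitEM(rep(0.4, 100), 2)
  expect_identical(nComponents(fit), 1L)
  expect_true("degenerate" %in% fit@flags)
  expect_equal(mixtureMeans(fit), 0.4)
  expect_error(fitEM(runif(5), 1), "10")
})

test_that("message length penalizes components at fixed likelihood", {
  mk <- function(C, ll, n = 1000) {
    w <- rep(1 / C, C)
    new("Mixture1D", weights = w, means = seq(0, 1, length.out = C),
        variances = rep(0.01, C), ncomp = as.integer(C), loglik = ll,
        loglikTrace = ll, n = n, converged = TRUE, flags = character(0))
  }
  expect_lt(messageLength(mk(1, 500)), messageLength(mk(2, 500)))
  expect_lt(messageLength(mk(2, 500)), messageLength(mk(3, 500)))
})

test_that("MML chooses the generating order: bimodal 2, unimodal 1", {
  set.seed(35)
  x2 <- c(rnorm(10000, 0.3, 0.02), rnorm(10000, 0.7, 0.02))
  f1 <- fitEM(x2, 1); f2 <- fitEM(x2, 2)
  expect_lt(messageLength(f2), messageLength(f1))
  expect_identical(nComponents(selectModel(x2)), 2L)
  x1 <- rnorm(20000, 0.5, 0.05)
  g1 <- fitEM(x1, 1); g2 <- fitEM(x1, 2)
  expect_lt(messageLength(g1), messageLength(g2))
  expect_identical(nComponents(selectModel(x1)), 1L)
})

test_that("bayes threshold: symmetric case is the exact midpoint", {
  mk <- function(w, mu, v) new("Mixture1D", weights = w, means = mu,
    variances = v, ncomp = 2L, loglik = 0, loglikTrace = 0, n = 1000,
    converged = TRUE, flags = character(0))
  dec <- bayesThreshold(mk(c(0.5, 0.5), c(0.3, 0.7), c(0.002, 0.002)))
  expect_identical(dec@threshold, 0.5)
  expect_identical(dec@method, "bayes")
  # defining property: weighted densities are equal at the threshold
  set.seed(36)
  for (rep in 1:20) {
    w1 <- runif(1, 0.2, 0.8)
    mdl <- mk(c(w1, 1 - w1), sort(runif(2, 0.2, 0.8)),
              runif(2, 0.01, 0.08)^2)
    if (diff(mdl@means) < 0.1) next
    dec <- bayesThreshold(mdl)
    f1 <- mdl@weights[1] * dnorm(dec@threshold, mdl@means[1],
                                 sqrt(mdl@variances[1]))
    f2 <- mdl@weights[2] * dnorm(dec@threshold, mdl@means[2],
                                 sqrt(mdl@variances[2]))
    expect_lt(abs(f1 - f2), 1e-9)
  }
  expect_error(bayesThreshold(mk(c(0.5, 0.5), c(0.4, 0.4), c(0.01, 0.01))),
               "not separated")
})

test_that("bayes threshold matches the dense-grid posterior crossover", {
  set.seed(37)
  for (rep in 1:25) {
    w1 <- runif(1, 0.2, 0.8)
    mu <- c(runif(1, 0.2, 0.4), runif(1, 0.6, 0.8))
    sg <- runif(2, 0.01, 0.1)
    mdl <- new("Mixture1D", weights = c(w1, 1 - w1), means = mu,
               variances = sg^2, ncomp = 2L, loglik = 0, loglikTrace = 0,
               n = 1000, converged = TRUE, flags = character(0))
    t <- bayesThreshold(mdl)@threshold
    tg <- bayesGridOracle(c(w1, 1 - w1), mu, sg, nGrid = 1e6)
    expect_lt(abs(t - tg), 1e-5)
  }
})

test_that("tail rejection follows the skewness sign", {
  set.seed(38)
  fitc <- fitConfig()
  # contaminated upper tail: threshold between the bulk and the clump,
  # excluding nearly all of the contaminant
  x <- c(rnorm(20000, 0.5, 0.05), rnorm(400, 0.95, 0.005))
  m1 <- fitEM(x, 1)
  dec <- kurtosisThreshold(x, m1, fitc)
  expect_identical(dec@foregroundSide, "below")
  expect_gt(dec@threshold, 0.5); expect_lt(dec@threshold, 0.95)
  expect_gt(mean(x[x > 0.85] > dec@threshold), 0.90)
  # mirrored contamination gives the mirrored rule
  xm <- 1 - x
  decm <- kurtosisThreshold(xm, fitEM(xm, 1), fitc)
  expect_identical(decm@foregroundSide, "above")
  expect_equal(decm@threshold, 1 - dec@threshold, tolerance = 1e-6)
  # perfectly symmetric sample rejects nothing
  xs <- c(0.3, 0.4, 0.5, 0.6, 0.7)
  decs <- kurtosisThreshold(xs, fitEM(rep(xs, 10), 1), fitc)
  expect_identical(decs@threshold, Inf)
})

test_that("fits are deterministic functions of data and config", {
  set.seed(39)
  x <- c(rnorm(5000, 0.3, 0.05), rnorm(5000, 0.8, 0.03))
  f1 <- fitEM(x, 2); f2 <- fitEM(x, 2)
  expect_identical(mixtureMeans(f1), mixtureMeans(f2))
  expect_identical(f1@loglikTrace, f2@loglikTrace)
})
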