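test_that("sobel magnitude matches hand-derived expectations", {
  expect_lt(max(sobelMagnitude(matrix(0.4, 6, 6))), 1e-12)
  # vertical step: nonzero magnitudes only in the two columns adjacent to
  # the step
  step <- cbind(matrix(0, 8, 4), matrix(1, 8, 4))
  g <- sobelMagnitude(step)
  expect_true(all(g[, 4:5] == 4))   # |Gx| = 4 across the step edge
  expect_true(all(g[, c(1:3, 6:8)] == 0))
  # magnitude is isotropic under axis swap
  set.seed(5)
  for (rep in 1:5) {
    img <- matrix(runif(7 * 9), 7, 9)
    expect_equal(sobelMagnitude(t(img)), t(sobelMagnitude(img)),
                 tolerance = 1e-12)
  }
  expect_error(sobelMagnitude(matrix(0, 2, 5)), "3 x 3")
})

test_that("vectorized EBCM equals the literal nested-loop reference", {
  set.seed(11)
  for (rep in 1:12) {
    m <- sample(3:20, 1); n <- sample(3:20, 1)
    img <- matrix(runif(m * n), m, n)
    expect_equal(ebcm(img), ebcmOracle(img), tolerance = 1e-12)
  }
  # structured images too: checkerboard and a step
  cb <- matrix((row(diag(8)) + col(diag(8))) %% 2, 8, 8)
  expect_equal(ebcm(cb), ebcmOracle(cb), tolerance = 1e-12)
  step <- cbind(matrix(0, 9, 5), matrix(1, 9, 4))
  expect_equal(ebcm(step), ebcmOracle(step), tolerance = 1e-12)
})

test_that("EBCM is 0 for constant images, bounded by [0, 1], symmetric", {
  for (v in c(0, 0.3, 1)) expect_equal(ebcm(matrix(v, 10, 10)), 0)
  set.seed(12)
  for (rep in 1:10) {
    img <- matrix(runif(11 * 13), 11, 13)
    val <- ebcm(img)
    expect_gte(val, 0); expect_lte(val, 1)
    expect_equal(ebcm(t(img)), val, tolerance = 1e-12)
    expect_equal(ebcm(img[11:1, 13:1]), val, tolerance = 1e-12)
  }
})

test_that("band selection minimizes EBCM deterministically", {
  # one informative pair among noise bands wins
  dc <- diskCube(m = 48, W = 5, seed = 1)
  pc <- normalizeBands(dc$cube)
  sel <- selectBandPair(pc)
  expect_identical(sel$pair, c(1L, 2L))
  expect_true(all(diff(sel$ranking$ebcm) >= 0))
  expect_equal(nrow(sel$ranking), choose(5, 2))
  expect_true(all(sel$diffImage >= 0 & sel$diffImage <= 1))
  # duplicate bands give a constant difference: absolute minimum, score 0
  d <- cubeData(dc$cube)
  d[, , 3] <- d[, , 1]
  sel2 <- selectBandPair(normalizeBands(SpectralCube(d, wavelengths = 1:5)))
  expect_identical(sel2$pair, c(1L, 3L))
  expect_equal(sel2$ranking$ebcm[1], 0)
  # restricting candidates forces the winner
  sel3 <- selectBandPair(pc, candidates = cbind(4L, 5L))
  expect_identical(sel3$pair, c(4L, 5L))
  # two runs are identical
  expect_identical(selectBandPair(pc)$ranking, sel$ranking)
})

test_that("band selection is consistent under band relabeling", {
  dc <- diskCube(m = 32, W = 4, seed = 2)
  pc <- normalizeBands(dc$cube)
  perm <- c(3L, 1L, 4L, 2L)   # old band k -> new position match(k, perm)
  dp <- cubeData(dc$cube)[, , perm]
  pcp <- normalizeBands(SpectralCube(dp, wavelengths = 1:4))
  sel <- selectBandPair(pc)
  selp <- selectBandPair(pcp)
  expect_setequal(perm[selp$pair], sel$pair)
})

test_that("a cube with no contrast in any pair is rejected", {
  d <- array(0.5, c(8, 8, 3))
  cube <- new("PreprocessedCube", data = d, wavelengths = as.numeric(1:3),
              sourceId = "", stage = "bandnorm")
  expect_error(selectBandPair(cube), "no contrast")
})

test_that("masked band selection reduces to the full one for a full mask", {
  dc <- diskCube(m = 32, W = 4, seed = 3)
  pc <- normalizeBands(dc$cube)
  full <- BinaryMask(matrix(TRUE, 32, 32))
  expect_identical(selectBandPair(pc, mask = full)$ranking,
                   selectBandPair(pc)$ranking)
  expect_error(selectBandPair(pc, mask = BinaryMask(matrix(FALSE, 32, 32))),
               "empty")
})

test_that("masked selection finds the fat-contrast pair the full image hides", {
  # pairs (1,3) and (2,3) are the only ones that move the fat blobs, but
  # band 3 also carries packaging texture, so on the full frame the clean
  # fat-blind pair (1,2) wins; restricted to the sample mask the texture
  # is invisible and the fat-contrast pair must take over
  set.seed(21)
  m <- 96
  rows <- matrix(seq_len(m), m, m); cols <- t(rows)
  disk <- (rows - 48.5)^2 + (cols - 48.5)^2 <= 38^2
  blobs <- function(region, k, r) {
    out <- matrix(FALSE, m, m)
    for (i in 1:k) {
      ci <- sample(which(region), 1)
      out <- out | ((rows - ((ci - 1) %% m + 1))^2 +
                    (cols - ((ci - 1) %/% m + 1))^2 <= r^2)
    }
    out & region
  }
  fat <- blobs(disk, 4, 5)
  s1 <- blobs(!disk, 3, 4)   # per-band shadow spots on the packaging
  s2 <- blobs(!disk, 3, 4)
  s3 <- blobs(!disk, 3, 4)
  tex <- (runif(m * m) - 0.5) * 0.6 * !disk
  d <- array(0, c(m, m, 3))
  d[, , 1] <- 0.5 + 0.3 * disk - 0.3 * s1 + rnorm(m * m, 0, 0.003)
  d[, , 2] <- 0.5 - 0.3 * s2 + rnorm(m * m, 0, 0.003)
  d[, , 3] <- 0.5 + 0.3 * disk + 0.3 * fat - 0.3 * s3 + tex +
    rnorm(m * m, 0, 0.01)
  pc <- normalizeBands(SpectralCube(pmax(d, 0), wavelengths = 1:3))
  sep <- function(x) {
    lean <- disk & !fat
    abs(mean(x[fat]) - mean(x[lean])) /
      sqrt((var(x[fat]) + var(x[lean])) / 2)
  }
  full <- selectBandPair(pc)
  expect_identical(full$pair, c(1L, 2L))
  expect_lt(sep(full$diffImage), 1)        # the full-image winner is fat-blind
  masked <- selectBandPair(pc, mask = BinaryMask(disk))
  expect_true(3L %in% masked$pair)         # only band 3 carries fat contrast
  expect_gt(sep(masked$diffImage), 5)
})
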