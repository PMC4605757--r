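test_that("area fraction counts included pixels", {
  expect_equal(areaFraction(BinaryMask(matrix(TRUE, 10, 10))), 1)
  block <- matrix(FALSE, 1200, 120)   # scaled-down 720x1200-in-1200x1200
  block[1:720, ] <- TRUE
  expect_equal(areaFraction(BinaryMask(block)), 0.6)
  expect_equal(areaFraction(BinaryMask(matrix(FALSE, 5, 5))), 0)
})

test_that("area regression matches the closed-form normal-equations oracle", {
  r <- regressAreas(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3))
  expect_equal(r$a, 1); expect_equal(r$b, 0, tolerance = 1e-12)
  expect_equal(r$r_square, 1); expect_equal(r$rmse, 0, tolerance = 1e-12)
  expect_equal(r$r, 1)
  x <- c(0.2, 0.5, 0.9, 0.4)
  r2 <- regressAreas(x, 2 * x + 1)
  expect_equal(r2$a, 2); expect_equal(r2$b, 1)
  set.seed(51)
  for (rep in 1:5) {
    x <- runif(50); y <- 0.8 * x + rnorm(50, 0, 0.1)
    got <- regressAreas(x, y)
    want <- regressOracle(x, y)
    for (f in names(want)) expect_equal(got[[f]], want[[f]], tolerance = 1e-10)
  }
  expect_error(regressAreas(rep(0.5, 5), runif(5)), "variance")
  expect_error(regressAreas(1:2 / 10, 1:2 / 10), "3")
})

test_that("colocalization percentages match a per-pixel counting oracle", {
  b <- BinaryMask(cbind(matrix(TRUE, 8, 4), matrix(FALSE, 8, 4)))
  self <- colocalize(b, b)
  expect_equal(self$coloc_pct, 100)
  expect_equal(self$excl_a_pct, 0); expect_equal(self$excl_b_pct, 0)
  half <- BinaryMask(cbind(matrix(TRUE, 8, 2), matrix(FALSE, 8, 6)))
  r <- colocalize(half, b)
  expect_equal(r$coloc_pct, 50); expect_equal(r$excl_b_pct, 50)
  expect_equal(r$excl_a_pct, 0)
  set.seed(52)
  for (rep in 1:10) {
    A <- matrix(runif(100) > 0.4, 10, 10)
    B <- matrix(runif(100) > 0.4, 10, 10)
    if (!any(B)) next
    got <- colocalize(BinaryMask(A), BinaryMask(B))
    nI <- 0; nA <- 0; nB <- 0
    for (i in 1:10) for (j in 1:10) {
      if (A[i, j] && B[i, j]) nI <- nI + 1
      if (A[i, j] && !B[i, j]) nA <- nA + 1
      if (!A[i, j] && B[i, j]) nB <- nB + 1
    }
    expect_identical(got$coloc_pct, 100 * nI / sum(B))
    expect_identical(got$excl_a_pct, 100 * nA / sum(B))
    expect_identical(got$excl_b_pct, 100 * nB / sum(B))
    # basis partition: colocalized and basis-exclusive shares sum to 100
    expect_equal(got$coloc_pct + got$excl_b_pct, 100)
  }
  expect_error(colocalize(b, BinaryMask(matrix(FALSE, 8, 8))), "empty")
})

test_that("set-level colocalization aggregates mean and standard error", {
  set.seed(53)
  as <- list(); bs <- list()
  for (k in 1:6) {
    as[[k]] <- BinaryMask(matrix(runif(64) > 0.3, 8, 8))
    bs[[k]] <- BinaryMask(matrix(runif(64) > 0.3, 8, 8))
  }
  out <- colocalizeMany(as, bs)
  expect_identical(nrow(out$samples), 6L)
  expect_equal(out$summary["mean", "coloc_pct"],
               mean(out$samples$coloc_pct))
  expect_equal(out$summary["se", "coloc_pct"],
               sd(out$samples$coloc_pct) / sqrt(6))
})

test_that("band summaries match a per-pixel loop and ignore NaN", {
  set.seed(54)
  cube <- SpectralCube(array(runif(8 * 8 * 5), c(8, 8, 5)),
                       wavelengths = (1:5) * 100)
  msk <- matrix(runif(64) > 0.4, 8, 8)
  bs <- bandSummary(cube, BinaryMask(msk))
  for (w in 1:5) {
    vals <- c()
    for (i in 1:8) for (j in 1:8)
      if (msk[i, j]) vals <- c(vals, cubeData(cube)[i, j, w])
    expect_equal(bs$mean[w], mean(vals), tolerance = 1e-12)
    expect_equal(bs$sd[w], sd(vals), tolerance = 1e-12)
  }
  # NaN-masked pixels are ignored
  masked <- applyMask(cube, BinaryMask(msk))
  bsFull <- bandSummary(masked, BinaryMask(matrix(TRUE, 8, 8)))
  expect_equal(bsFull$mean, bs$mean)
  # noiseless phantom: per-band mean over a region is exactly its value
  spec <- phantomPreset("creme", m = 32, seed = 1)
  spec@noiseSd <- 0; spec@gainRange <- c(1, 1)
  tt <- makePhantom(spec)
  bsp <- bandSummary(tt@cube, tt@truthSample)
  expect_equal(bsp$mean, spec@signatures[2, ], ignore_attr = TRUE)
  expect_true(all(bsp$sd < 1e-12))
})

test_that("reports serialize to JSON and round-trip", {
  x <- c(0.2, 0.5, 0.9, 0.4); y <- 2 * x + 0.1
  r <- regressAreas(x, y)
  p <- file.path(tempdir(), "report.json")
  jsonlite::write_json(r, p, auto_unbox = TRUE, digits = NA)
  back <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_equal(back$a, r$a)
  expect_equal(back$p_value, r$p_value)
})
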