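# independent reference implementations used as oracles; written as
# literal nested loops / closed forms, never sharing code with the package

# edge-based contrast measure, literal per-pixel loops with clamped
# border indices (equivalent to one-pixel edge padding)
ebcmOracle <- function(img) {
  m <- nrow(img); n <- ncol(img)
  cl <- function(i, lim) min(max(i, 1L), lim)
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  g <- matrix(0, m, n)
  for (i in 1:m) for (j in 1:n) {
    gx <- 0; gy <- 0
    for (di in -1:1) for (dj in -1:1) {
      v <- img[cl(i + di, m), cl(j + dj, n)]
      gx <- gx + kx[di + 2, dj + 2] * v
      gy <- gy + kx[dj + 2, di + 2] * v
    }
    g[i, j] <- sqrt(gx^2 + gy^2)
  }
  total <- 0
  for (i in 1:m) for (j in 1:n) {
    sg <- 0; sgi <- 0
    for (di in -1:1) for (dj in -1:1) {
      ii <- cl(i + di, m); jj <- cl(j + dj, n)
      sg <- sg + g[ii, jj]
      sgi <- sgi + g[ii, jj] * img[ii, jj]
    }
    e <- if (sg > 0) sgi / sg else img[i, j]
    s <- img[i, j] + e
    total <- total + (if (s > 0) abs(img[i, j] - e) / s else 0)
  }
  total / (m * n)
}

# posterior crossover of a 2-component 1-D Gaussian mixture by dense grid
# search between the means
bayesGridOracle <- function(w, mu, sigma, nGrid = 1e6) {
  grid <- seq(mu[1], mu[2], length.out = nGrid)
  f1 <- w[1] * dnorm(grid, mu[1], sigma[1])
  f2 <- w[2] * dnorm(grid, mu[2], sigma[2])
  grid[which.min(abs((f1 - f2) / (f1 + f2)))]
}

# ordinary least squares + Pearson test from the normal equations and the
# exact t distribution
regressOracle <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  a <- sxy / sxx
  b <- mean(y) - a * mean(x)
  res <- y - (a * x + b)
  r <- sxy / sqrt(sxx * sum((y - mean(y))^2))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(a = a, b = b,
       r_square = 1 - sum(res^2) / sum((y - mean(y))^2),
       rmse = sqrt(mean(res^2)), r = r,
       p_value = 2 * pt(-abs(tstat), df = n - 2))
}

diceCoef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# a two-band cube in which pair (1,2) separates a centred disk from its
# surround; any extra bands are pure noise
diskCube <- function(m = 48, W = 4, seed = 1, noise = 0.01) {
  set.seed(seed)
  ctr <- (m + 1) / 2
  rows <- matrix(seq_len(m), m, m)
  cols <- t(rows)
  disk <- (rows - ctr)^2 + (cols - ctr)^2 <= (0.3 * m)^2
  data <- array(0, c(m, m, W))
  data[, , 1] <- 0.2 + rnorm(m * m, 0, noise)
  data[, , 2] <- 0.2 + 0.4 * disk + rnorm(m * m, 0, noise)
  if (W > 2) for (w in 3:W) data[, , w] <- matrix(runif(m * m), m, m)
  list(cube = SpectralCube(pmax(data, 0), wavelengths = seq_len(W) * 100),
       disk = disk)
}
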