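# shared numeric helpers (internal)

# pad a matrix by one pixel on each side, replicating the border row/column
# (for a 1-pixel pad, edge replication and symmetric reflection coincide)
.padEdge <- function(x) {
  m <- nrow(x); n <- ncol(x)
  x[c(1L, seq_len(m), m), c(1L, seq_len(n), n)]
}

# 3x3 cross-correlation with edge padding; k indexed [row offset, col offset]
.conv3 <- function(x, k) {
  m <- nrow(x); n <- ncol(x)
  p <- .padEdge(x)
  out <- matrix(0, m, n)
  for (di in 0:2) for (dj in 0:2) {
    kv <- k[di + 1L, dj + 1L]
    if (kv != 0) out <- out + kv * p[di + seq_len(m), dj + seq_len(n)]
  }
  out
}

# evaluate code under a fixed RNG seed, restoring global RNG state afterwards
.withSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# min-max rescale to [0,1]; returns NULL if the input is constant
.rescale01 <- function(x, lo = min(x), hi = max(x)) {
  if (!is.finite(lo) || !is.finite(hi) || hi - lo < 1e-300) return(NULL)
  (x - lo) / (hi - lo)
}

.stopIfEmpty <- function(mask, what = "mask") {
  if (isEmptyMask(mask)) stop(what, " is empty")
  invisible(TRUE)
}
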