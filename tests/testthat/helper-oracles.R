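# Independent reference implementations used to cross-check the package.

# Dense random search over nonnegative weight vectors: returns the smallest
# residual norm found among nCand candidates spanning several scales.
randomSearchResidual <- function(A, b, nCand = 2000) {
  n <- ncol(A)
  best <- Inf
  for (k in seq_len(nCand)) {
    x <- rexp(n) * sample(c(0.01, 0.1, 1, 10), 1) * rbinom(n, 1, 0.7)
    r <- sqrt(sum((b - A %*% x)^2))
    if (r < best) best <- r
  }
  best
}

# Recursive enumeration of all one-to-one assignments of estimate slots to
# truth slots, minimizing the same T1-relative-error cost as the package
# (zero-amplitude truth slots cost 0, missing estimate vs real truth 1).
enumAlignCost <- function(estT1, truthT1) {
  J <- length(truthT1)
  pairCost <- function(i, j) {
    if (is.na(truthT1[j])) 0
    else if (is.na(estT1[i])) 1
    else abs(estT1[i] - truthT1[j]) / truthT1[j]
  }
  rec <- function(j, used) {
    if (j > J) return(0)
    best <- Inf
    for (i in setdiff(seq_len(J), used)) {
      c0 <- pairCost(i, j) + rec(j + 1, c(used, i))
      if (c0 < best) best <- c0
    }
    best
  }
  rec(1, integer())
}

# Plain-loop evaluation of the absolute-value IR model SSE.
sseByLoop <- function(amp, t1, ti, y) {
  total <- 0
  for (i in seq_along(ti)) {
    m <- 0
    for (j in seq_along(amp)) m <- m + amp[j] * (1 - 2 * exp(-ti[i] / t1[j]))
    total <- total + (y[i] - abs(m))^2
  }
  total
}

# Loop-based sum-then-abs combination of signed voxel blocks.
refSumAbs <- function(blocks) {
  out <- matrix(0, nrow(blocks[[1]]), ncol(blocks[[1]]))
  for (v in seq_len(nrow(out))) {
    for (i in seq_len(ncol(out))) {
      s <- 0
      for (b in blocks) s <- s + b[v, i]
      out[v, i] <- abs(s)
    }
  }
  out
}

# Small noiseless helper curves on the default grid.
tiGrid <- function() seq(100, 5000, by = 100)
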