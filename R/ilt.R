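#' @include AllClasses.R
NULL

#' Default candidate T1 grid for the spectrum method
#'
#' 100 candidate T1 values spanning the range commonly encountered in T1
#' relaxometry. The grid starts at 50 ms rather than 0 because the
#' inversion-recovery kernel is singular at T1 = 0.
#'
#' @param n Number of candidate values (default 100).
#' @param range Lower/upper T1 bounds in ms (default `c(50, 5000)`).
#' @param spacing `"linear"` (default) or `"log"`.
#' @return Numeric vector of candidate T1 values, strictly increasing.
#' @export
defaultT1Grid <- function(n = 100, range = c(50, 5000),
                          spacing = c("linear", "log")) {
  spacing <- match.arg(spacing)
  stopifnot(n >= 2, range[1] > 0, range[2] > range[1])
  if (spacing == "linear") seq(range[1], range[2], length.out = n)
  else exp(seq(log(range[1]), log(range[2]), length.out = n))
}

#' Inversion-recovery transformation kernel
#'
#' Builds the N x J matrix with entries `1 - 2 exp(-TI_i / T1_j)` linking a
#' candidate T1 grid to the inversion-time grid.
#'
#' @param tiMs Inversion times (ms), nonnegative.
#' @param t1GridMs Candidate T1 values (ms), strictly positive.
#' @return Numeric matrix, `length(tiMs)` x `length(t1GridMs)`.
#' @examples
#' buildKernel(c(693.147), 1000)  # ~0 at the null point
#' @export
buildKernel <- function(tiMs, t1GridMs) {
  tiMs <- as.numeric(tiMs)
  t1GridMs <- as.numeric(t1GridMs)
  if (any(t1GridMs <= 0))
    stop("candidate T1 grid must start above 0")
  if (any(tiMs < 0)) stop("inversion times must be nonnegative")
  1 - 2 * exp(-outer(tiMs, 1 / t1GridMs))
}

#' Nonnegative least squares by active sets
#'
#' Lawson–Hanson active-set solution of
#' \eqn{\min_{x \ge 0} \|Ax - b\|^2}. The passive-set subproblems are solved
#' with a rank-tolerant pivoted QR (`lm.fit`), so the solver also handles
#' underdetermined systems such as a fine candidate-T1 grid with fewer
#' inversion times than grid bins.
#'
#' @param A Numeric matrix (m x n).
#' @param b Numeric right-hand side of length m.
#' @param tol Dual-feasibility tolerance; defaults to
#'   `10 * .Machine$double.eps * max(dim(A)) * max(|A|)`.
#' @return List with `x` (nonnegative solution) and `residualNorm`
#'   (Euclidean norm of `b - Ax`).
#' @examples
#' A <- matrix(c(1, 0, 0, 1, 1, 1), 3, 2)
#' nnlsSolve(A, c(1, -1, 1))$x
#' @export
nnlsSolve <- function(A, b, tol = NULL) {
  A <- as.matrix(A)
  b <- as.numeric(b)
  stopifnot(nrow(A) == length(b))
  n <- ncol(A)
  if (is.null(tol)) tol <- 10 * .Machine$double.eps * max(dim(A)) * max(abs(A))
  x <- rep(0, n)
  P <- logical(n)
  w <- as.numeric(crossprod(A, b))
  outer <- 0L
  inner <- 0L
  maxInner <- 50L * n
  while (any(!P) && max(w[!P]) > tol && outer < 3L * n) {
    outer <- outer + 1L
    cand <- which(!P)
    P[cand[which.max(w[cand])]] <- TRUE
    repeat {
      z <- rep(0, n)
      cf <- stats::lm.fit(A[, P, drop = FALSE], b)$coefficients
      cf[is.na(cf)] <- 0  # rank-deficient passive set: drop aliased columns
      z[P] <- cf
      if (all(z[P] > 0) || inner >= maxInner) {
        x <- pmax(z, 0)
        break
      }
      inner <- inner + 1L
      q <- which(P & z <= 0)
      alpha <- min(x[q] / (x[q] - z[q]))
      x <- pmax(x + alpha * (z - x), 0)
      P <- P & x > 0
      x[!P] <- 0
      if (!any(P)) break
    }
    w <- as.numeric(crossprod(A, b - A %*% x))
  }
  list(x = x, residualNorm = sqrt(sum((b - as.numeric(A %*% x))^2)))
}

#' Grid-based inverse Laplace transform of an IR curve
#'
#' Estimates a nonnegative T1 weight spectrum by solving
#' \deqn{\hat g = \arg\min_{g \ge 0} \tfrac12 \|A g - y\|^2}
#' with the Lawson–Hanson nonnegative least-squares algorithm, where A is the
#' inversion-recovery kernel over the candidate grid. The signal must be
#' polarity-restored (signed) and is scaled to unit maximum absolute value
#' before inversion so that the extraction threshold is scale-free.
#'
#' @param curve A signed-real [IRCurve-class] (or numeric vector of signed
#'   samples when `tiMs` is given).
#' @param t1GridMs Candidate T1 grid; defaults to [defaultT1Grid()].
#' @param threshold Extraction threshold on the normalized weights
#'   (default 0.075).
#' @param tiMs Inversion times, only when `curve` is a bare numeric vector.
#' @return A [T1Spectrum-class] with nonnegative weights, the normalization
#'   scale and the residual norm.
#' @examples
#' ti <- seq(100, 5000, by = 100)
#' y <- irSignal(ComponentSet(1, 1500), ti)
#' sp <- fitILT(IRCurve(ti, y, "signed_real"))
#' extractComponents(sp)
#' @export
fitILT <- function(curve, t1GridMs = defaultT1Grid(), threshold = 0.075,
                   tiMs = NULL) {
  if (is(curve, "IRCurve")) {
    if (signalKind(curve) != "signed_real")
      stop("fitILT expects a polarity-restored (signed_real) curve")
    y <- signalValues(curve)
    tiMs <- inversionTimes(curve)
  } else {
    y <- as.numeric(curve)
    if (is.null(tiMs)) stop("tiMs is required when curve is a bare vector")
  }
  if (any(!is.finite(y))) stop("signal contains non-finite samples")
  scale <- max(abs(y))
  if (scale == 0) {
    return(new("T1Spectrum", t1Grid = as.numeric(t1GridMs),
               weights = rep(0, length(t1GridMs)), threshold = threshold,
               scale = 0, residualNorm = 0))
  }
  A <- buildKernel(tiMs, t1GridMs)
  sol <- nnlsSolve(A, y / scale)
  new("T1Spectrum", t1Grid = as.numeric(t1GridMs),
      weights = pmax(sol$x, 0), threshold = threshold, scale = scale,
      residualNorm = sol$residualNorm)
}

#' @describeIn extractComponents Contiguous supra-threshold runs become
#'   components (weight-weighted mean T1, summed amplitude in data units).
setMethod("extractComponents", "T1Spectrum", function(spectrum,
                                                      mergeRuns = TRUE) {
  above <- spectrum@weights > spectrum@threshold
  if (!any(above)) return(ComponentSet())
  w <- spectrum@weights
  g <- spectrum@t1Grid
  scale <- if (spectrum@scale > 0) spectrum@scale else 1
  if (!mergeRuns) {
    idx <- which(above)
    return(ComponentSet(amplitudes = w[idx] * scale, t1 = g[idx]))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  amp <- numeric(length(runs))
  t1 <- numeric(length(runs))
  for (k in seq_along(runs)) {
    idx <- starts[runs[k]]:ends[runs[k]]
    amp[k] <- sum(w[idx]) * scale
    t1[k] <- sum(w[idx] * g[idx]) / sum(w[idx])
  }
  ComponentSet(amplitudes = amp, t1 = t1)
})

#' Fit one voxel with the inverse Laplace transform method
#'
#' Convenience wrapper: polarity-restores a magnitude curve (global-minimum
#' null index), runs [fitILT()], extracts components and reports the SSE of
#' the implied magnitude model.
#'
#' @param y Numeric magnitude samples of one voxel.
#' @param tiMs Inversion times (ms).
#' @param t1GridMs Candidate grid; defaults to [defaultT1Grid()].
#' @param threshold Extraction threshold (default 0.075).
#' @param mergeRuns Merge contiguous supra-threshold bins (default TRUE).
#' @return A [FitResult-class] with `method = "ilt"`; the spectrum is kept in
#'   `details$spectrum`.
#' @export
fitILTVoxel <- function(y, tiMs, t1GridMs = defaultT1Grid(),
                        threshold = 0.075, mergeRuns = TRUE) {
  signed <- restorePolarity(IRCurve(tiMs, as.numeric(y), "magnitude"))
  sp <- fitILT(signed, t1GridMs = t1GridMs, threshold = threshold)
  comps <- extractComponents(sp, mergeRuns = mergeRuns)
  sse <- if (nComponents(comps) > 0)
    sum((as.numeric(y) - magnitudeIRSignal(comps, tiMs))^2)
  else sum(as.numeric(y)^2)
  new("FitResult", method = "ilt", components = comps, sse = sse,
      nStartsUsed = 1L, converged = TRUE, details = list(spectrum = sp))
}
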