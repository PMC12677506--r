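#' @include AllClasses.R
NULL

#' Linear box bounds for nonlinear multiexponential fitting
#'
#' @param curve Optional magnitude [IRCurve-class] or numeric vector used to
#'   scale the amplitude upper bound.
#' @param ampLo,ampHi Amplitude bounds (signal units); `ampHi` defaults to
#'   twice the maximum of the curve, or 2 when no curve is given.
#' @param t1LoMs,t1HiMs T1 bounds in ms (defaults 50 and 5000).
#' @return A list of class `fitBounds`.
#' @export
fitBounds <- function(curve = NULL, ampLo = 0, ampHi = NULL,
                      t1LoMs = 50, t1HiMs = 5000) {
  if (is.null(ampHi)) {
    y <- if (is(curve, "IRCurve")) signalValues(curve) else curve
    ampHi <- if (is.null(y)) 2 else 2 * max(abs(as.numeric(y)))
  }
  stopifnot(ampLo >= 0, ampHi > ampLo, t1LoMs > 0, t1HiMs > t1LoMs)
  structure(list(ampLo = ampLo, ampHi = ampHi,
                 t1LoMs = t1LoMs, t1HiMs = t1HiMs),
            class = "fitBounds")
}

#' Sum of squared errors of the absolute-value IR model
#'
#' The objective minimized by the nonlinear fitters:
#' \deqn{F = \sum_i \big(y(TI_i) - |\textstyle\sum_j A_j (1 - 2 e^{-TI_i/T_{1j}})|\big)^2.}
#' The data are magnitude values and no polarity restoration is performed.
#'
#' @param components A [ComponentSet-class] of candidate parameters.
#' @param y Numeric magnitude samples (or a magnitude [IRCurve-class]).
#' @param tiMs Inversion times; taken from the curve when one is supplied.
#' @return Scalar SSE.
#' @examples
#' ti <- seq(100, 5000, 100)
#' cs <- ComponentSet(c(1, 1), c(641, 2733))
#' objectiveSSE(cs, magnitudeIRSignal(cs, ti), ti)  # 0
#' @export
objectiveSSE <- function(components, y, tiMs = NULL) {
  if (is(y, "IRCurve")) {
    tiMs <- inversionTimes(y)
    y <- signalValues(y)
  }
  y <- as.numeric(y)
  if (length(y) != length(tiMs))
    stop("signal and inversion-time grids differ in length")
  sum((y - magnitudeIRSignal(components, tiMs))^2)
}

# One bounded Levenberg-Marquardt run of the absolute-value model from a
# given start; par layout c(A_1..A_J, T1_1..T1_J). The analytic Jacobian
# uses sign(model) through the absolute value (the objective is non-smooth
# exactly at the nulls; the subgradient there is taken as +1).
nlsFitOnce <- function(y, tiMs, start, bounds, control) {
  J <- length(start) / 2
  lower <- c(rep(bounds$ampLo, J), rep(bounds$t1LoMs, J))
  upper <- c(rep(bounds$ampHi, J), rep(bounds$t1HiMs, J))
  resid <- function(p) {
    K <- 1 - 2 * exp(-outer(tiMs, 1 / p[(J + 1):(2 * J)]))
    y - abs(as.numeric(K %*% p[1:J]))
  }
  jac <- function(p) {
    A <- p[1:J]
    T1 <- p[(J + 1):(2 * J)]
    E <- exp(-outer(tiMs, 1 / T1))
    K <- 1 - 2 * E
    m <- as.numeric(K %*% A)
    s <- ifelse(m >= 0, 1, -1)
    # r = y - |m|  =>  dr/dA_j = -s K_ij, dr/dT1_j = s 2 A_j t_i E_ij / T1_j^2
    cbind(-s * K, s * 2 * E * outer(tiMs, A / T1^2))
  }
  fit <- suppressWarnings(
    minpack.lm::nls.lm(par = pmin(pmax(start, lower), upper),
                       lower = lower, upper = upper,
                       fn = resid, jac = jac, control = control))
  list(par = fit$par, sse = sum(fit$fvec^2),
       converged = fit$info %in% 1:4)
}

nlsControl <- function() {
  minpack.lm::nls.lm.control(ftol = 1e-8, ptol = 1e-8, gtol = 1e-8,
                             maxfev = 2000, maxiter = 200)
}

parToComponents <- function(par) {
  J <- length(par) / 2
  ComponentSet(amplitudes = par[1:J], t1 = par[(J + 1):(2 * J)])
}

#' Multistart bounded nonlinear least-squares fit (MUL)
#'
#' Fits the absolute-value inversion-recovery model with a fixed number of
#' components J by bounded Levenberg–Marquardt from `nStarts` starting
#' points drawn uniformly within the bounds; the solution with minimal SSE
#' is returned. J is never altered by this method.
#'
#' Starts are drawn sequentially under the seed, so the start set for
#' `nStarts = k` is a prefix of the set for any larger count: the returned
#' SSE is non-increasing in `nStarts`.
#'
#' @param y Magnitude samples of one voxel (numeric vector or magnitude
#'   [IRCurve-class]).
#' @param tiMs Inversion times (ms); taken from the curve if one is given.
#' @param J Number of components to fit (>= 1).
#' @param bounds A [fitBounds()] list; defaults to bounds scaled to the
#'   curve.
#' @param nStarts Number of random starts (default 32).
#' @param seed Integer seed for the start draws.
#' @param maxJ Guard on the largest permitted J (default 6).
#' @return A [FitResult-class] with `method = "mul"`, components sorted
#'   ascending by T1.
#' @examples
#' ti <- seq(100, 5000, 100)
#' y <- magnitudeIRSignal(ComponentSet(c(1, 1), c(641, 2733)), ti)
#' fitMUL(y, ti, J = 2, seed = 1)
#' @export
fitMUL <- function(y, tiMs = NULL, J, bounds = NULL, nStarts = 32,
                   seed = NULL, maxJ = 6) {
  if (is(y, "IRCurve")) {
    tiMs <- inversionTimes(y)
    y <- signalValues(y)
  }
  y <- as.numeric(y)
  J <- as.integer(J)
  if (J < 1) stop("J must be at least 1")
  if (J > maxJ) stop("J exceeds the configured maximum of ", maxJ)
  stopifnot(nStarts >= 1)
  if (is.null(bounds)) bounds <- fitBounds(y)
  control <- nlsControl()
  withSeed(seed, {
    best <- NULL
    for (s in seq_len(nStarts)) {
      start <- c(runif(J, bounds$ampLo, bounds$ampHi),
                 runif(J, bounds$t1LoMs, bounds$t1HiMs))
      fit <- nlsFitOnce(y, tiMs, start, bounds, control)
      if (is.null(best) || fit$sse < best$sse) best <- fit
    }
    new("FitResult", method = "mul", components = parToComponents(best$par),
        sse = best$sse, nStartsUsed = as.integer(nStarts),
        converged = best$converged, details = list(bounds = bounds))
  })
}

# Semi-random TOM starting point for a given J: T1 entries equally spaced
# over the configured gray/white-matter range with +/-10% uniform jitter,
# equal amplitudes max(y)/J.
tomStart <- function(y, J, bounds, t1StartRange, jitterFrac) {
  t1 <- seq(t1StartRange[1], t1StartRange[2], length.out = J) *
    runif(J, 1 - jitterFrac, 1 + jitterFrac)
  c(rep(max(y) / J, J), t1)
}

#' Sequential model-order fit with a single semi-random start (TOM)
#'
#' Fits the absolute-value inversion-recovery model once for each number of
#' components J from 2 up to `jMax`, each from a single semi-random starting
#' point whose T1 entries sample the range of commonly occurring gray- and
#' white-matter relaxation times at 3 T (default 700–2200 ms, with ±10%
#' uniform jitter), and returns the candidate with minimal SSE. Ties within
#' `1e-12` are broken toward smaller J (parsimony).
#'
#' @inheritParams fitMUL
#' @param jMax Largest number of components to consider (>= 2).
#' @param t1StartRange Range the T1 start values sample (ms).
#' @param jitterFrac Fractional uniform jitter on the start values.
#' @return A [FitResult-class] with `method = "tom"`; per-candidate SSEs are
#'   kept in `details$candidateSSE` (named by J).
#' @export
fitTOM <- function(y, tiMs = NULL, jMax = 4, bounds = NULL, seed = NULL,
                   t1StartRange = c(700, 2200), jitterFrac = 0.1, maxJ = 6) {
  if (is(y, "IRCurve")) {
    tiMs <- inversionTimes(y)
    y <- signalValues(y)
  }
  y <- as.numeric(y)
  jMax <- as.integer(jMax)
  if (jMax < 2) stop("jMax must be at least 2")
  if (jMax > maxJ) stop("jMax exceeds the configured maximum of ", maxJ)
  if (is.null(bounds)) bounds <- fitBounds(y)
  control <- nlsControl()
  withSeed(seed, {
    fits <- vector("list", jMax - 1L)
    sses <- numeric(jMax - 1L)
    for (k in seq_along(fits)) {
      J <- k + 1L
      start <- tomStart(y, J, bounds, t1StartRange, jitterFrac)
      fits[[k]] <- nlsFitOnce(y, tiMs, start, bounds, control)
      sses[k] <- fits[[k]]$sse
    }
    best <- 1L
    for (k in seq_along(sses)[-1])
      if (sses[k] < sses[best] - 1e-12) best <- k
    sel <- fits[[best]]
    names(sses) <- as.character(seq_along(sses) + 1L)
    new("FitResult", method = "tom", components = parToComponents(sel$par),
        sse = sel$sse, nStartsUsed = as.integer(jMax - 1L),
        converged = sel$converged,
        details = list(candidateSSE = sses, bounds = bounds))
  })
}
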