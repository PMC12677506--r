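#' @include AllClasses.R
NULL

#' Relative error in percent
#'
#' @param est Estimated value.
#' @param truth True value, nonzero.
#' @return `100 * |est - truth| / |truth|`.
#' @examples
#' relativeErrorPct(800, 1000)  # 20
#' @export
relativeErrorPct <- function(est, truth) {
  if (any(truth == 0))
    stop("relative error is undefined for zero truth; use maxMeanErrorPct")
  100 * abs(est - truth) / abs(truth)
}

#' Pad a component set with zero-amplitude slots
#'
#' Appends artificial components with amplitude 0 (and no defined T1) until
#' the set has `expectedJ` slots, so that fits expecting more components
#' than the data contains can be scored against a ground truth that includes
#' a zero component.
#'
#' @param components A [ComponentSet-class].
#' @param expectedJ Target length, >= the current number of components.
#' @return A [ComponentSet-class] of length `expectedJ`.
#' @examples
#' augmentZeroComponent(ComponentSet(c(1, 1), c(641, 2733)), 3)
#' @export
augmentZeroComponent <- function(components, expectedJ) {
  expectedJ <- as.integer(expectedJ)
  J <- nComponents(components)
  if (expectedJ < J)
    stop("expectedJ must be at least the current number of components")
  if (expectedJ == J) return(components)
  ComponentSet(amplitudes = c(amplitudes(components), rep(0, expectedJ - J)),
               t1 = c(t1Values(components), rep(NA_real_, expectedJ - J)))
}

#' Modified maximum mean error for amplitudes, in percent
#'
#' Error measure used for amplitude comparisons whenever the voxel's ground
#' truth contains a zero-amplitude component (where the relative error is
#' undefined): the absolute amplitude deviation normalized by the voxel's
#' maximum ground-truth amplitude. Reduces to the relative error when the
#' truth amplitude equals that maximum.
#'
#' @param estAmp Estimated amplitude(s).
#' @param truthAmp Paired true amplitude(s).
#' @param truthAmps All ground-truth amplitudes of the voxel (the
#'   normalizing context); must contain a positive value.
#' @return `100 * |estAmp - truthAmp| / max(truthAmps)`.
#' @examples
#' maxMeanErrorPct(0.3, 0, c(1, 0))        # 30
#' maxMeanErrorPct(1, 0, c(2, 1, 0))       # 50
#' @export
maxMeanErrorPct <- function(estAmp, truthAmp, truthAmps) {
  mx <- max(truthAmps)
  if (mx <= 0) stop("all ground-truth amplitudes are zero")
  100 * abs(estAmp - truthAmp) / mx
}

# Cost of pairing estimate slot i with truth slot j: T1 relative error;
# zero-amplitude truth slots cost 0, a padded estimate slot against a real
# truth component costs 1 (100%).
alignCostMatrix <- function(estT1, truthT1) {
  J <- length(truthT1)
  C <- matrix(0, J, J)
  for (i in seq_len(J)) {
    for (j in seq_len(J)) {
      C[i, j] <- if (is.na(truthT1[j])) 0
      else if (is.na(estT1[i])) 1
      else abs(estT1[i] - truthT1[j]) / truthT1[j]
    }
  }
  C
}

#' Align estimated components to ground truth
#'
#' Finds the one-to-one pairing of estimate slots to truth slots that
#' minimizes the total T1 relative error, by exhaustive search over all
#' permutations (intended for J <= 5). Ties are broken toward the
#' lexicographically smallest permutation. Both sets must have equal length;
#' pad with [augmentZeroComponent()] first if needed.
#'
#' @param estimate Estimated [ComponentSet-class].
#' @param truth Ground-truth [ComponentSet-class] of the same length.
#' @return List with `permutation` (estimate slot paired with each truth
#'   slot), `cost` (total alignment cost), and `pairs` (data.frame with
#'   columns trueT1, estT1, trueAmp, estAmp).
#' @examples
#' al <- alignComponents(ComponentSet(c(1, 1), c(650, 2700)),
#'                       ComponentSet(c(1, 1), c(641, 2733)))
#' al$pairs
#' @export
alignComponents <- function(estimate, truth) {
  J <- nComponents(truth)
  if (nComponents(estimate) != J)
    stop("estimate and truth must have equal length; pad with augmentZeroComponent")
  if (J == 0)
    return(list(permutation = integer(), cost = 0,
                pairs = data.frame(trueT1 = numeric(), estT1 = numeric(),
                                   trueAmp = numeric(), estAmp = numeric())))
  if (J > 6) stop("exhaustive alignment supports at most 6 components")
  C <- alignCostMatrix(t1Values(estimate), t1Values(truth))
  perms <- lexPermutations(J)
  best <- 1L
  bestCost <- Inf
  for (r in seq_len(nrow(perms))) {
    cost <- sum(C[cbind(perms[r, ], seq_len(J))])
    if (cost < bestCost) {
      bestCost <- cost
      best <- r
    }
  }
  p <- perms[best, ]
  list(permutation = p, cost = bestCost,
       pairs = data.frame(trueT1 = t1Values(truth),
                          estT1 = t1Values(estimate)[p],
                          trueAmp = amplitudes(truth),
                          estAmp = amplitudes(estimate)[p]))
}

#' Score one fit against one voxel's ground truth
#'
#' Pads estimate and truth to a common length (at least `expectedJ`),
#' aligns them with [alignComponents()], and computes per-component errors:
#' T1 relative errors over truth slots with a defined T1 (a missing
#' estimate counts as 100%), and amplitude errors as relative errors, or as
#' the modified maximum mean error whenever any truth amplitude in the
#' voxel is zero.
#'
#' @param estimate Estimated [ComponentSet-class] (or a [FitResult-class]).
#' @param truth Ground-truth [ComponentSet-class].
#' @param expectedJ Expected number of components; defaults to the true
#'   count. Set to `nComponents(truth) + 1` for the zero-component
#'   condition.
#' @return List with `pairs` (aligned data.frame including per-pair error
#'   columns `relErrT1Pct`, `errAmpPct`), `meanRelErrT1Pct`,
#'   `meanErrAmpPct`, and `nEstComponents` (count before padding).
#' @export
scoreVoxelFit <- function(estimate, truth, expectedJ = nComponents(truth)) {
  if (is(estimate, "FitResult")) estimate <- fittedComponents(estimate)
  nEst <- nComponents(estimate)
  if (nEst > 6) {  # keep the 6 largest-amplitude components (alignment cap)
    keep <- order(amplitudes(estimate), decreasing = TRUE)[1:6]
    estimate <- ComponentSet(amplitudes(estimate)[keep], t1Values(estimate)[keep])
  }
  L <- max(expectedJ, nComponents(estimate), nComponents(truth))
  est <- augmentZeroComponent(estimate, L)
  tru <- augmentZeroComponent(truth, L)
  al <- alignComponents(est, tru)
  pairs <- al$pairs
  realT1 <- !is.na(pairs$trueT1) & pairs$trueAmp > 0
  pairs$relErrT1Pct <- NA_real_
  pairs$relErrT1Pct[realT1] <- ifelse(
    is.na(pairs$estT1[realT1]), 100,
    100 * abs(pairs$estT1[realT1] - pairs$trueT1[realT1]) / pairs$trueT1[realT1])
  estAmp <- ifelse(is.na(pairs$estAmp), 0, pairs$estAmp)
  if (any(pairs$trueAmp == 0)) {
    pairs$errAmpPct <- maxMeanErrorPct(estAmp, pairs$trueAmp, pairs$trueAmp)
  } else {
    pairs$errAmpPct <- relativeErrorPct(estAmp, pairs$trueAmp)
  }
  list(pairs = pairs,
       meanRelErrT1Pct = if (any(realT1)) mean(pairs$relErrT1Pct[realT1]) else NA_real_,
       meanErrAmpPct = mean(pairs$errAmpPct),
       nEstComponents = nEst)
}

#' Fit every voxel of a composite dataset with one method
#'
#' @param dataset A [CompositeDataset-class].
#' @param method `"ilt"`, `"mul"` or `"tom"`.
#' @param seed Integer seed; each voxel derives a child seed from it.
#' @param J Number of components for `"mul"`; defaults to the true count.
#' @param jMax Maximum components for `"tom"`; defaults to
#'   `max(2, true count)`.
#' @param nStarts Random starts for `"mul"` (default 32).
#' @param t1GridMs,threshold Spectrum grid and threshold for `"ilt"`.
#' @param bounds Optional [fitBounds()] shared by all voxels.
#' @param ... Passed through to the underlying fitter.
#' @return List of [FitResult-class], one per voxel.
#' @export
fitDataset <- function(dataset, method = c("ilt", "mul", "tom"), seed = 1,
                       J = NULL, jMax = NULL, nStarts = 32,
                       t1GridMs = defaultT1Grid(), threshold = 0.075,
                       bounds = NULL, ...) {
  method <- match.arg(method)
  sig <- voxelSignals(dataset)
  ti <- inversionTimes(dataset)
  nTrue <- ncol(dataset@truthT1)
  if (is.null(J)) J <- max(1L, nTrue)
  if (is.null(jMax)) jMax <- max(2L, nTrue)
  lapply(seq_len(nrow(sig)), function(v) {
    vseed <- childSeed(seed, v)
    switch(method,
      ilt = fitILTVoxel(sig[v, ], ti, t1GridMs = t1GridMs,
                        threshold = threshold, ...),
      mul = fitMUL(sig[v, ], ti, J = J, bounds = bounds, nStarts = nStarts,
                   seed = vseed, ...),
      tom = fitTOM(sig[v, ], ti, jMax = jMax, bounds = bounds,
                   seed = vseed, ...))
  })
}

#' Evaluate per-voxel fits of a composite dataset
#'
#' @param dataset A [CompositeDataset-class] with ground truth.
#' @param fits List of [FitResult-class], one per voxel (from
#'   [fitDataset()]).
#' @param zeroComponent If `TRUE`, score under the zero-component condition:
#'   the expected count is the true count plus one and the ground truth is
#'   augmented with a zero-amplitude component.
#' @return data.frame of per-voxel records with columns `combinationId`,
#'   `voxel`, `method`, `nTrueComponents`, `nEstComponents`,
#'   `meanRelErrT1Pct`, `meanErrAmpPct`, `datasetT1Ratio`.
#' @export
evaluateDataset <- function(dataset, fits, zeroComponent = FALSE) {
  if (ncol(dataset@truthT1) == 0)
    stop("dataset carries no ground truth; evaluation is disabled")
  stopifnot(length(fits) == nrow(voxelSignals(dataset)))
  ratio <- dataset@meanT1Ratio
  rows <- lapply(seq_along(fits), function(v) {
    truth <- truthComponents(dataset, v)
    expectedJ <- nComponents(truth) + if (zeroComponent) 1L else 0L
    sc <- scoreVoxelFit(fits[[v]], truth, expectedJ = expectedJ)
    data.frame(combinationId = combinationId(dataset), voxel = v,
               method = fits[[v]]@method,
               nTrueComponents = nComponents(truth),
               nEstComponents = sc$nEstComponents,
               meanRelErrT1Pct = sc$meanRelErrT1Pct,
               meanErrAmpPct = sc$meanErrAmpPct,
               datasetT1Ratio = ratio)
  })
  do.call(rbind, rows)
}

#' Summarize evaluation records
#'
#' Groups per-voxel records into the two headline tables: mean T1 and
#' amplitude errors by method and true component count, and mean estimated
#' components per dataset and method.
#'
#' @param records data.frame from [evaluateDataset()] (rows from several
#'   datasets/methods may be concatenated).
#' @return List with `errorsByComponents` and `componentsByDataset`
#'   data.frames.
#' @export
summarizeErrors <- function(records) {
  stopifnot(nrow(records) > 0)
  key1 <- interaction(records$method, records$nTrueComponents, drop = TRUE)
  errorsByComponents <- do.call(rbind, lapply(split(records, key1), function(g)
    data.frame(method = g$method[1], nTrueComponents = g$nTrueComponents[1],
               nVoxels = nrow(g),
               meanRelErrT1Pct = mean(g$meanRelErrT1Pct, na.rm = TRUE),
               meanErrAmpPct = mean(g$meanErrAmpPct, na.rm = TRUE))))
  key2 <- interaction(records$method, records$combinationId, drop = TRUE)
  componentsByDataset <- do.call(rbind, lapply(split(records, key2), function(g)
    data.frame(method = g$method[1], combinationId = g$combinationId[1],
               datasetT1Ratio = g$datasetT1Ratio[1],
               nTrueComponents = g$nTrueComponents[1],
               meanEstComponents = mean(g$nEstComponents))))
  rownames(errorsByComponents) <- rownames(componentsByDataset) <- NULL
  list(errorsByComponents = errorsByComponents,
       componentsByDataset = componentsByDataset)
}

#' Regression of relative error on the T1 ratio
#'
#' Ordinary least squares of the per-voxel mean relative T1 error (%) on the
#' dataset-level mean T1 ratio, fitted separately per method over the
#' supplied records (voxel-level observations).
#'
#' @param records data.frame from [evaluateDataset()].
#' @return data.frame with one row per method: `slope` (percent per unit
#'   ratio), `intercept`, `rSquared`, `pValue` (two-sided, slope), `n`.
#' @export
errorRatioRegression <- function(records) {
  records <- records[is.finite(records$meanRelErrT1Pct), , drop = FALSE]
  out <- lapply(split(records, records$method, drop = TRUE), function(g) {
    if (length(unique(round(g$datasetT1Ratio, 6))) < 3)
      stop("regression needs at least 3 distinct T1 ratio values")
    fit <- stats::lm(meanRelErrT1Pct ~ datasetT1Ratio, data = g)
    sm <- summary(fit)
    data.frame(method = g$method[1],
               slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               rSquared = sm$r.squared,
               pValue = sm$coefficients[2, 4],
               n = nrow(g))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
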