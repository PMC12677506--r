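#' @include AllGenerics.R
NULL

setClassUnion("numericOrComplex", c("numeric", "complex"))

#' Single-voxel inversion-recovery curve
#'
#' One voxel's signal over a strictly increasing inversion-time grid. The
#' representation records where the curve sits in the processing chain:
#' `"complex"` raw data, `"signed_real"` after polarity restoration, or
#' `"magnitude"` after taking absolute values.
#'
#' @slot ti Numeric vector of inversion times (ms), strictly increasing.
#' @slot values Sample vector, numeric or complex, same length as `ti`.
#' @slot kind One of `"complex"`, `"signed_real"`, `"magnitude"`.
#' @seealso [IRCurve()], [restorePolarity()]
#' @export
setClass("IRCurve",
  slots = c(ti = "numeric", values = "numericOrComplex", kind = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@ti) != length(object@values))
      msg <- c(msg, "ti and values must have equal length")
    if (length(object@ti) > 1 && any(diff(object@ti) <= 0))
      msg <- c(msg, "ti must be strictly increasing")
    if (length(object@kind) != 1 ||
        !object@kind %in% c("complex", "signed_real", "magnitude"))
      msg <- c(msg, "kind must be one of complex, signed_real, magnitude")
    else {
      if (object@kind == "complex" && !is.complex(object@values))
        msg <- c(msg, "complex representation requires complex values")
      if (object@kind != "complex" && is.complex(object@values))
        msg <- c(msg, "signed_real/magnitude representation requires numeric values")
      if (object@kind == "magnitude" && !is.complex(object@values) &&
          any(object@values < 0))
        msg <- c(msg, "magnitude representation requires nonnegative values")
    }
    if (length(msg)) msg else TRUE
  })

#' Construct an inversion-recovery curve
#'
#' @param ti Numeric vector of inversion times (ms), strictly increasing.
#' @param values Samples, numeric or complex, one per inversion time.
#' @param kind Representation: `"complex"`, `"signed_real"` or `"magnitude"`.
#' @return An [IRCurve-class] object.
#' @examples
#' IRCurve(seq(100, 500, by = 100), c(-0.8, -0.4, 0, 0.3, 0.5), "signed_real")
#' @export
IRCurve <- function(ti, values, kind = c("signed_real", "magnitude", "complex")) {
  kind <- match.arg(kind)
  new("IRCurve", ti = as.numeric(ti), values = values, kind = kind)
}

setMethod("inversionTimes", "IRCurve", function(x) x@ti)
setMethod("signalValues", "IRCurve", function(x) x@values)
setMethod("signalKind", "IRCurve", function(x) x@kind)

setMethod("show", "IRCurve", function(object) {
  cat(sprintf("IRCurve: %d samples (%s), TI %g-%g ms\n",
              length(object@ti), object@kind,
              min(object@ti), max(object@ti)))
})

#' Discrete multiexponential component set
#'
#' Amplitudes and longitudinal relaxation times of J discrete components of
#' an inversion-recovery signal. Components are kept in canonical order:
#' ascending T1, with padded zero-amplitude slots (T1 = NA) last. Padded
#' slots arise from zero-component augmentation during evaluation and carry
#' amplitude 0 with no defined T1.
#'
#' @slot amplitudes Numeric vector of amplitudes A_j (signal units, >= 0).
#' @slot t1 Numeric vector of T1 values (ms, > 0), NA only for amplitude-0
#'   padded slots.
#' @seealso [ComponentSet()], [irSignal()], [augmentZeroComponent()]
#' @export
setClass("ComponentSet",
  slots = c(amplitudes = "numeric", t1 = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@amplitudes) != length(object@t1))
      msg <- c(msg, "amplitudes and t1 must have equal length")
    if (any(object@amplitudes < 0, na.rm = TRUE))
      msg <- c(msg, "amplitudes must be nonnegative")
    fin <- !is.na(object@t1)
    if (any(object@t1[fin] <= 0))
      msg <- c(msg, "t1 values must be positive")
    if (any(!fin & object@amplitudes != 0))
      msg <- c(msg, "NA t1 is only allowed for zero-amplitude padded slots")
    if (sum(fin) > 1 && any(diff(object@t1[fin]) < 0))
      msg <- c(msg, "t1 must be sorted ascending (canonical order)")
    if (any(fin) && any(!fin) && min(which(!fin)) < max(which(fin)))
      msg <- c(msg, "padded slots must come after real components")
    if (length(msg)) msg else TRUE
  })

#' Construct a component set
#'
#' Components are sorted ascending by T1 (NA-T1 padded slots last) so that
#' all reporting uses the canonical order.
#'
#' @param amplitudes Numeric amplitudes, >= 0.
#' @param t1 Numeric T1 values in ms (> 0), NA allowed only with amplitude 0.
#' @return A [ComponentSet-class].
#' @examples
#' ComponentSet(amplitudes = c(1, 1), t1 = c(2733, 641))  # reordered to 641, 2733
#' @export
ComponentSet <- function(amplitudes = numeric(), t1 = numeric()) {
  amplitudes <- as.numeric(amplitudes)
  t1 <- as.numeric(t1)
  ord <- order(t1, na.last = TRUE)
  new("ComponentSet", amplitudes = amplitudes[ord], t1 = t1[ord])
}

setMethod("amplitudes", "ComponentSet", function(x) x@amplitudes)
setMethod("t1Values", "ComponentSet", function(x) x@t1)
setMethod("nComponents", "ComponentSet", function(x) length(x@amplitudes))
setMethod("length", "ComponentSet", function(x) length(x@amplitudes))

setMethod("show", "ComponentSet", function(object) {
  J <- length(object@amplitudes)
  cat(sprintf("ComponentSet with %d component%s\n", J, if (J == 1) "" else "s"))
  if (J > 0)
    print(data.frame(amplitude = object@amplitudes, t1_ms = object@t1))
})

#' Nonnegative T1 weight spectrum
#'
#' Output of the grid-based inverse Laplace transform: nonnegative weights
#' over a candidate T1 grid, obtained by nonnegative least squares on the
#' unit-max-normalized signal. `scale` is the normalization factor (maximum
#' absolute signal value) used to map weights back to data units.
#'
#' @slot t1Grid Candidate T1 values (ms), strictly increasing, > 0.
#' @slot weights Nonnegative spectral weights, one per grid bin (normalized
#'   signal units).
#' @slot threshold Extraction threshold applied to the weights.
#' @slot scale Signal normalization factor (data units).
#' @slot residualNorm Euclidean norm of the NNLS residual (normalized units).
#' @seealso [fitILT()], [extractComponents()]
#' @export
setClass("T1Spectrum",
  slots = c(t1Grid = "numeric", weights = "numeric", threshold = "numeric",
            scale = "numeric", residualNorm = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@t1Grid) != length(object@weights))
      msg <- c(msg, "t1Grid and weights must have equal length")
    if (any(object@t1Grid <= 0))
      msg <- c(msg, "t1Grid must be positive")
    if (length(object@t1Grid) > 1 && any(diff(object@t1Grid) <= 0))
      msg <- c(msg, "t1Grid must be strictly increasing")
    if (any(object@weights < -1e-12))
      msg <- c(msg, "weights must be nonnegative")
    if (length(msg)) msg else TRUE
  })

setMethod("nComponents", "T1Spectrum", function(x)
  nComponents(extractComponents(x)))

setMethod("show", "T1Spectrum", function(object) {
  nz <- sum(object@weights > object@threshold)
  cat(sprintf(
    "T1Spectrum: %d bins over [%g, %g] ms, %d above threshold %g, residual %.3g\n",
    length(object@t1Grid), min(object@t1Grid), max(object@t1Grid), nz,
    object@threshold, object@residualNorm))
})

#' Composite multiexponential dataset with known ground truth
#'
#' A set of voxel-level magnitude inversion-recovery signals built by signed
#' summation of polarity-restored single-component region blocks, together
#' with the per-voxel true amplitudes and T1 values. Mirrors one row of the
#' composite-dataset overview table.
#'
#' @slot combinationId Character label, e.g. `"Comb-3"`.
#' @slot ti Inversion-time grid (ms).
#' @slot signals Numeric matrix, voxels x inversion times, magnitude values.
#' @slot truthT1 Numeric matrix, voxels x components, true T1 (ms); may have
#'   zero columns when ground truth is unavailable.
#' @slot truthAmp Numeric matrix, voxels x components, true amplitudes.
#' @slot meanT1Ratio Scalar mean consecutive T1 ratio (NA without truth).
#' @seealso [buildCompositeSuite()], [meanT1Ratio()]
#' @export
setClass("CompositeDataset",
  slots = c(combinationId = "character", ti = "numeric", signals = "matrix",
            truthT1 = "matrix", truthAmp = "matrix", meanT1Ratio = "numeric"),
  validity = function(object) {
    msg <- character()
    if (ncol(object@signals) != length(object@ti))
      msg <- c(msg, "signals must have one column per inversion time")
    if (any(object@signals < 0))
      msg <- c(msg, "signals must be magnitude (nonnegative)")
    hasTruth <- ncol(object@truthT1) > 0
    if (hasTruth) {
      if (nrow(object@truthT1) != nrow(object@signals) ||
          !identical(dim(object@truthT1), dim(object@truthAmp)))
        msg <- c(msg, "truth matrices must be voxels x components, matching signals")
      if (any(object@truthT1 <= 0))
        msg <- c(msg, "true T1 values must be positive")
      if (!is.na(object@meanT1Ratio) && object@meanT1Ratio < 1)
        msg <- c(msg, "meanT1Ratio must be >= 1")
    }
    if (length(msg)) msg else TRUE
  })

setMethod("combinationId", "CompositeDataset", function(x) x@combinationId)
setMethod("inversionTimes", "CompositeDataset", function(x) x@ti)
setMethod("voxelSignals", "CompositeDataset", function(x) x@signals)

setMethod("truthComponents", "CompositeDataset", function(x, voxel) {
  if (ncol(x@truthT1) == 0)
    stop("dataset carries no ground truth")
  voxel <- as.integer(voxel)
  if (voxel < 1 || voxel > nrow(x@signals))
    stop("voxel index out of range")
  ComponentSet(amplitudes = x@truthAmp[voxel, ], t1 = x@truthT1[voxel, ])
})

setMethod("show", "CompositeDataset", function(object) {
  cat(sprintf(
    "CompositeDataset %s: %d voxels, %d TIs, %s true components, mean T1 ratio %s\n",
    object@combinationId, nrow(object@signals), length(object@ti),
    if (ncol(object@truthT1)) ncol(object@truthT1) else "no",
    if (is.na(object@meanT1Ratio)) "NA" else sprintf("%.2f", object@meanT1Ratio)))
})

#' Result of one multiexponential fit
#'
#' @slot method One of `"ilt"`, `"mul"`, `"tom"`.
#' @slot components Estimated [ComponentSet-class], sorted ascending by T1.
#' @slot sse Sum of squared errors of the fit (0 for unset).
#' @slot nStartsUsed Number of optimizer starts evaluated.
#' @slot converged Whether the reported solution converged.
#' @slot details Method-specific extras (e.g. per-candidate SSE for the
#'   sequential model-order selector, the T1 spectrum for the grid method).
#' @export
setClass("FitResult",
  slots = c(method = "character", components = "ComponentSet", sse = "numeric",
            nStartsUsed = "integer", converged = "logical", details = "list"),
  validity = function(object) {
    msg <- character()
    if (!object@method %in% c("ilt", "mul", "tom"))
      msg <- c(msg, "method must be one of ilt, mul, tom")
    if (length(object@sse) != 1 || is.na(object@sse) || object@sse < 0)
      msg <- c(msg, "sse must be a nonnegative scalar")
    if (length(msg)) msg else TRUE
  })

setMethod("nComponents", "FitResult", function(x) nComponents(x@components))
setMethod("amplitudes", "FitResult", function(x) amplitudes(x@components))
setMethod("t1Values", "FitResult", function(x) t1Values(x@components))

#' Estimated components of a fit
#'
#' @param fit A [FitResult-class].
#' @return The estimated [ComponentSet-class].
#' @export
fittedComponents <- function(fit) fit@components

#' Sum of squared errors of a fit
#'
#' @param fit A [FitResult-class].
#' @return Scalar SSE.
#' @export
fitSSE <- function(fit) fit@sse

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult [%s]: %d components, SSE %.4g, %d start%s%s\n",
              object@method, nComponents(object@components), object@sse,
              object@nStartsUsed, if (object@nStartsUsed == 1) "" else "s",
              if (isTRUE(object@converged)) "" else " (not converged)"))
})
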