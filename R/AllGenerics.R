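#' @include AllGenerics.R
NULL

#' Inversion-time grid of an object
#'
#' @param x An object carrying an inversion-time axis.
#' @return Numeric vector of inversion times in milliseconds.
#' @export
setGeneric("inversionTimes", function(x) standardGeneric("inversionTimes"))

#' Signal samples of a curve
#'
#' @param x An [IRCurve-class] object.
#' @return The sample vector (numeric or complex, depending on the
#'   representation).
#' @export
setGeneric("signalValues", function(x) standardGeneric("signalValues"))

#' Signal representation of a curve
#'
#' @param x An [IRCurve-class] object.
#' @return One of `"complex"`, `"signed_real"`, `"magnitude"`.
#' @export
setGeneric("signalKind", function(x) standardGeneric("signalKind"))

#' Component amplitudes
#'
#' @param x A [ComponentSet-class] or [FitResult-class].
#' @return Numeric vector of amplitudes (signal units).
#' @export
setGeneric("amplitudes", function(x) standardGeneric("amplitudes"))

#' Component T1 values
#'
#' @param x A [ComponentSet-class] or [FitResult-class].
#' @return Numeric vector of T1 values in milliseconds (NA for padded
#'   zero-amplitude slots).
#' @export
setGeneric("t1Values", function(x) standardGeneric("t1Values"))

#' Number of components
#'
#' @param x A [ComponentSet-class], [FitResult-class] or
#'   [T1Spectrum-class].
#' @return Integer count of components.
#' @export
setGeneric("nComponents", function(x) standardGeneric("nComponents"))

#' Restore the polarity of an inversion-recovery signal
#'
#' Re-signs an inversion-recovery curve so that samples before the estimated
#' null point are negative, recovering the signed recovery curve from complex
#' or magnitude-only data.
#'
#' For a complex curve the null index is estimated from the crossing of
#' `|Re|` and `|Im|`: the first index at which `|Re| - |Im|` changes sign is
#' located and the nearer of the two bracketing samples is taken. Samples
#' strictly preceding the null index are negated; the sample at the null index
#' is kept positive. If no crossing exists the index of the global minimum
#' magnitude is used and a warning is emitted. For a magnitude curve the null
#' index is the global minimum directly.
#'
#' @param curve An [IRCurve-class] with representation `"complex"` or
#'   `"magnitude"`.
#' @return An [IRCurve-class] with representation `"signed_real"`.
#' @examples
#' ti <- seq(100, 5000, by = 100)
#' cs <- ComponentSet(amplitudes = 1, t1 = 1000)
#' z <- complex(real = irSignal(cs, ti), imaginary = rep(0, length(ti)))
#' sig <- restorePolarity(IRCurve(ti, z, "complex"))
#' head(signalValues(sig))
#' @export
setGeneric("restorePolarity", function(curve) standardGeneric("restorePolarity"))

#' Mean consecutive T1 ratio of a dataset's ground truth
#'
#' For every voxel the ratios of consecutive sorted true T1 values are
#' averaged; the result is the mean over voxels. With zero per-voxel
#' dispersion this reduces to the mean of consecutive ratios of the component
#' means.
#'
#' @param x A [CompositeDataset-class] or a numeric matrix of per-voxel true
#'   T1 values (voxels in rows, components in columns).
#' @return Scalar mean T1 ratio (> 1 for distinct components).
#' @examples
#' meanT1Ratio(matrix(c(641, 2733), nrow = 1))  # 4.263...
#' @export
setGeneric("meanT1Ratio", function(x) standardGeneric("meanT1Ratio"))

#' Identifier of a composite dataset
#'
#' @param x A [CompositeDataset-class].
#' @return Character label (e.g. `"Comb-3"`).
#' @export
setGeneric("combinationId", function(x) standardGeneric("combinationId"))

#' Voxel signal matrix of a composite dataset
#'
#' @param x A [CompositeDataset-class].
#' @return Numeric matrix, voxels in rows, inversion times in columns.
#' @export
setGeneric("voxelSignals", function(x) standardGeneric("voxelSignals"))

#' Ground-truth components of one voxel
#'
#' @param x A [CompositeDataset-class].
#' @param voxel Integer voxel index.
#' @return A [ComponentSet-class] with the voxel's true amplitudes and T1s.
#' @export
setGeneric("truthComponents", function(x, voxel) standardGeneric("truthComponents"))

#' Extract discrete components from a T1 spectrum
#'
#' Grid bins with weight above the spectrum's threshold are grouped into
#' maximal contiguous runs; each run becomes one component whose T1 is the
#' weight-weighted mean of its bins and whose amplitude is the sum of its
#' (de-normalized) weights. With `mergeRuns = FALSE` every surviving bin is
#' reported as its own component.
#'
#' @param spectrum A [T1Spectrum-class].
#' @param mergeRuns Logical; merge contiguous supra-threshold bins into one
#'   component (default `TRUE`).
#' @return A [ComponentSet-class]; an empty set (0 components) is a valid
#'   outcome when no weight exceeds the threshold.
#' @export
setGeneric("extractComponents", function(spectrum, mergeRuns = TRUE)
  standardGeneric("extractComponents"))
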