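#' @include AllClasses.R
NULL

#' Default inversion-time grid
#'
#' 50 inversion times spanning 100 to 5000 ms, spaced by 100 ms — the
#' acquisition grid the composite suite emulates.
#'
#' @return Numeric vector of 50 inversion times (ms).
#' @export
defaultTiGrid <- function() seq(100, 5000, by = 100)

#' Composite-suite combination table
#'
#' The ten region combinations of the composite ground-truth suite: six
#' two-component, three three-component and one four-component dataset, built
#' from the four retained component mean T1 values 641, 1039, 1540 and
#' 2733 ms.
#'
#' @return Named list mapping combination id to its component mean T1 values
#'   (ms, ascending).
#' @export
suiteCombinations <- function() {
  list(
    "Comb-1"  = c(641, 1039),
    "Comb-2"  = c(641, 1540),
    "Comb-3"  = c(641, 2733),
    "Comb-4"  = c(1039, 1540),
    "Comb-5"  = c(1039, 2733),
    "Comb-6"  = c(1540, 2733),
    "Comb-7"  = c(641, 1039, 1540),
    "Comb-8"  = c(641, 1039, 2733),
    "Comb-9"  = c(1039, 1540, 2733),
    "Comb-10" = c(641, 1039, 1540, 2733)
  )
}

#' Configuration of the synthetic composite suite
#'
#' Collects the generator settings: the inversion-time grid, the noise level
#' as SNR in dB (relative to the maximum noiseless signal magnitude per
#' voxel, per real/imaginary channel), the fractional per-voxel T1 dispersion
#' within a region, the common component amplitude, the voxel count per
#' region block, and the combination table.
#'
#' @param tiMs Inversion-time grid (ms), strictly increasing.
#' @param snrDb Signal-to-noise ratio in dB; `Inf` disables noise.
#' @param dispersion Fractional SD of per-voxel T1 about the region mean
#'   (default 0.01; 0 allowed, must be < 0.2).
#' @param amplitude Component amplitude shared by all regions (signal units).
#' @param nVoxels Voxels per region block (default 36, a 6 x 6 window).
#' @param combinations Named list of component mean T1 vectors; defaults to
#'   [suiteCombinations()].
#' @return A list of class `suiteConfig`.
#' @export
suiteConfig <- function(tiMs = defaultTiGrid(), snrDb = 30, dispersion = 0.01,
                        amplitude = 1, nVoxels = 36,
                        combinations = suiteCombinations()) {
  stopifnot(length(tiMs) > 1, all(diff(tiMs) > 0),
            dispersion >= 0, dispersion < 0.2,
            amplitude > 0, nVoxels >= 1,
            is.list(combinations), length(combinations) > 0,
            !is.null(names(combinations)))
  structure(list(tiMs = as.numeric(tiMs), snrDb = snrDb,
                 dispersion = dispersion, amplitude = amplitude,
                 nVoxels = as.integer(nVoxels), combinations = combinations),
            class = "suiteConfig")
}

#' Generate one region block of noisy complex IR signals
#'
#' Emulates the 6 x 6 voxel window extracted from one phantom compartment:
#' each voxel draws its true T1 from a truncated normal around the region
#' mean, evaluates the noiseless single-component inversion-recovery curve
#' along the real axis, and adds independent zero-mean Gaussian noise to the
#' real and imaginary channels with SD set so that
#' `20 log10(max |noiseless| / SD) = snrDb`.
#'
#' @param meanT1Ms Region mean T1 (ms, > 0).
#' @param tiMs Inversion-time grid (ms).
#' @param snrDb SNR in dB (> 0); `Inf` for noiseless signals.
#' @param dispersion Fractional SD of per-voxel T1 (>= 0, < 0.2).
#' @param amplitude Signal amplitude.
#' @param nVoxels Number of voxels in the block.
#' @param seed Integer seed; fixed seed gives identical output.
#' @return List with `signals` (complex matrix, voxels x inversion times),
#'   `trueT1` (per-voxel true T1, ms) and `amplitude`.
#' @examples
#' blk <- generateRoiBlock(641, seq(100, 5000, 100), snrDb = 30, seed = 7)
#' dim(blk$signals)
#' @export
generateRoiBlock <- function(meanT1Ms, tiMs = defaultTiGrid(), snrDb = 30,
                             dispersion = 0.01, amplitude = 1, nVoxels = 36,
                             seed = NULL) {
  stopifnot(meanT1Ms > 0, dispersion >= 0, dispersion < 0.2, amplitude > 0)
  if (!is.infinite(snrDb) && snrDb <= 0)
    stop("snrDb must be positive")
  tiMs <- as.numeric(tiMs)
  N <- length(tiMs)
  withSeed(seed, {
    t1 <- rnorm(nVoxels, meanT1Ms, dispersion * meanT1Ms)
    while (any(t1 <= 0))  # truncate positive; essentially never at dispersion < 0.2
      t1[t1 <= 0] <- rnorm(sum(t1 <= 0), meanT1Ms, dispersion * meanT1Ms)
    signals <- matrix(complex(real = 0, imaginary = 0), nVoxels, N)
    for (v in seq_len(nVoxels)) {
      s0 <- amplitude * (1 - 2 * exp(-tiMs / t1[v]))
      noiseSd <- if (is.infinite(snrDb)) 0 else max(abs(s0)) / 10^(snrDb / 20)
      signals[v, ] <- complex(real = s0 + rnorm(N, 0, noiseSd),
                              imaginary = rnorm(N, 0, noiseSd))
    }
    list(signals = signals, trueT1 = t1, amplitude = amplitude)
  })
}

# Polarity-restore every voxel of a complex block. Returns a signed matrix
# with attribute "nFallback": the number of voxels where no |Re|/|Im|
# crossing existed and the minimum-magnitude fallback was used (a routine
# occurrence for noisy voxels whose null falls between grid points).
restoreBlock <- function(signals, tiMs) {
  nFallback <- 0L
  out <- t(apply(signals, 1, function(row) {
    withCallingHandlers(
      signalValues(restorePolarity(IRCurve(tiMs, row, "complex"))),
      warning = function(w) {
        nFallback <<- nFallback + 1L
        invokeRestart("muffleWarning")
      })
  }))
  attr(out, "nFallback") <- nFallback
  out
}

#' Combine polarity-restored region blocks into magnitude voxel signals
#'
#' Voxel-wise (positional) sum of the signed signals across blocks, followed
#' by taking absolute values — only the magnitude of the combined data is
#' retained, emulating magnitude-only image reconstruction.
#'
#' @param blocks List of signed-real numeric matrices (voxels x inversion
#'   times), all of identical dimension, each already polarity-restored.
#' @return Numeric matrix of magnitude signals, voxels x inversion times.
#' @export
combineRois <- function(blocks) {
  stopifnot(is.list(blocks), length(blocks) >= 1)
  dims <- lapply(blocks, dim)
  if (length(unique(dims)) != 1 || any(vapply(blocks, is.complex, logical(1))))
    stop("blocks must be signed-real matrices of identical dimension")
  out <- abs(Reduce(`+`, blocks))
  attributes(out) <- list(dim = dim(out))
  out
}

#' Build the composite ground-truth suite
#'
#' Generates one noisy complex block per distinct component mean T1,
#' polarity-restores every voxel, then forms each configured combination by
#' positional signed summation of its blocks with magnitude retention. Block
#' noise is drawn once per suite, so combinations sharing a component reuse
#' the same underlying block — mirroring a single extraction of each region
#' window. The result is a pure function of `(config, seed)`.
#'
#' @param config A [suiteConfig()] list.
#' @param seed Integer master seed.
#' @return Named list of [CompositeDataset-class] objects, one per
#'   combination.
#' @examples
#' suite <- buildCompositeSuite(suiteConfig(dispersion = 0), seed = 1)
#' suite[["Comb-3"]]
#' @export
buildCompositeSuite <- function(config = suiteConfig(), seed = 1) {
  stopifnot(inherits(config, "suiteConfig"))
  means <- sort(unique(unlist(config$combinations)))
  blocks <- vector("list", length(means))
  names(blocks) <- as.character(means)
  for (k in seq_along(means)) {
    blk <- generateRoiBlock(means[k], tiMs = config$tiMs, snrDb = config$snrDb,
                            dispersion = config$dispersion,
                            amplitude = config$amplitude,
                            nVoxels = config$nVoxels,
                            seed = childSeed(seed, k))
    blk$restored <- restoreBlock(blk$signals, config$tiMs)
    blocks[[k]] <- blk
  }
  out <- lapply(names(config$combinations), function(id) {
    comp <- config$combinations[[id]]
    if (!all(as.character(comp) %in% names(blocks)))
      stop("unknown combination id or component mean: ", id)
    if (length(comp) < 2)
      stop("unknown or degenerate combination '", id,
           "': at least two component means are required")
    sel <- blocks[as.character(comp)]
    signals <- combineRois(lapply(sel, `[[`, "restored"))
    truthT1 <- do.call(cbind, lapply(sel, `[[`, "trueT1"))
    dimnames(truthT1) <- NULL
    truthAmp <- matrix(config$amplitude, nrow(truthT1), ncol(truthT1))
    new("CompositeDataset", combinationId = id, ti = config$tiMs,
        signals = signals, truthT1 = truthT1, truthAmp = truthAmp,
        meanT1Ratio = meanT1Ratio(truthT1))
  })
  names(out) <- names(config$combinations)
  out
}

#' @describeIn meanT1Ratio Per-voxel matrix of true T1 values (voxels x
#'   components).
setMethod("meanT1Ratio", "matrix", function(x) {
  if (ncol(x) < 2)
    stop("mean T1 ratio needs at least two components")
  perVoxel <- apply(x, 1, function(t1) {
    t1 <- sort(t1)
    mean(t1[-1] / t1[-length(t1)])
  })
  mean(perVoxel)
})

#' @describeIn meanT1Ratio Ground truth of a composite dataset.
setMethod("meanT1Ratio", "CompositeDataset", function(x) {
  if (ncol(x@truthT1) == 0)
    stop("dataset carries no ground truth")
  meanT1Ratio(x@truthT1)
})
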