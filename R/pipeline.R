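#' @include AllClasses.R
NULL

#' Full-run configuration
#'
#' Bundles every setting of an end-to-end run: suite generation, the methods
#' to fit, per-method settings and the output directory. All defaults mirror
#' the emulated study conditions: 50 inversion times (100–5000 ms), SNR
#' 30 dB, 100-bin candidate grid, extraction threshold 0.075, 32 random
#' starts.
#'
#' @param outDir Output directory (created if missing).
#' @param seed Integer master seed; mandatory so no run is silently
#'   nondeterministic.
#' @param methods Character subset of `c("ilt", "mul", "tom")`.
#' @param tiMs Inversion-time grid (ms).
#' @param snrDb SNR in dB.
#' @param dispersion Fractional per-voxel T1 dispersion.
#' @param nVoxels Voxels per region block.
#' @param combinations Named list of component means per combination.
#' @param gridSize Number of candidate T1 bins for the spectrum method.
#' @param threshold Spectrum extraction threshold.
#' @param nStarts Random starts for the multistart fitter.
#' @param zeroComponent Also evaluate the zero-component condition (skipped
#'   for the multistart fitter, which cannot select the component count).
#' @return List of class `pipelineConfig`.
#' @export
pipelineConfig <- function(outDir = tempfile("mexpT1-run-"), seed = 1,
                           methods = c("ilt", "mul", "tom"),
                           tiMs = defaultTiGrid(), snrDb = 30,
                           dispersion = 0.01, nVoxels = 36,
                           combinations = suiteCombinations(),
                           gridSize = 100, threshold = 0.075, nStarts = 32,
                           zeroComponent = TRUE) {
  if (is.null(seed)) stop("a seed is required")
  bad <- setdiff(methods, c("ilt", "mul", "tom"))
  if (length(bad)) stop("unknown method(s): ", paste(bad, collapse = ", "))
  structure(list(outDir = outDir, seed = as.integer(seed), methods = methods,
                 tiMs = as.numeric(tiMs), snrDb = snrDb,
                 dispersion = dispersion, nVoxels = as.integer(nVoxels),
                 combinations = combinations, gridSize = gridSize,
                 threshold = threshold, nStarts = nStarts,
                 zeroComponent = isTRUE(zeroComponent)),
            class = "pipelineConfig")
}

#' Read a run configuration from a YAML file
#'
#' Recognized top-level keys match the arguments of [pipelineConfig()];
#' `combinations` may be a mapping from combination id to a list of
#' component mean T1 values. Unknown keys are rejected.
#'
#' @param path Path to a YAML file.
#' @param outDir Optional override of the output directory.
#' @return A `pipelineConfig` list.
#' @export
readPipelineConfig <- function(path, outDir = NULL) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipelineConfig))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  if (!is.null(raw$combinations))
    raw$combinations <- lapply(raw$combinations, as.numeric)
  if (!is.null(outDir)) raw$outDir <- outDir
  do.call(pipelineConfig, raw)
}

# Format a numeric vector as a ';'-joined field for flat CSV storage.
packNum <- function(x) paste(format(x, digits = 15, trim = TRUE), collapse = ";")

writeTable <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

#' Serialize a composite dataset to CSV
#'
#' Writes `<id>_signals.csv` (voxels x inversion times; column names encode
#' the TI grid as `ti_<ms>`) and, when ground truth is present,
#' `<id>_truth.csv` (columns `t1_<j>` and `amp_<j>`).
#'
#' @param dataset A [CompositeDataset-class].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
saveCompositeDataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  id <- combinationId(dataset)
  sig <- as.data.frame(voxelSignals(dataset))
  names(sig) <- paste0("ti_", format(inversionTimes(dataset), trim = TRUE))
  paths <- writeTable(sig, file.path(dir, paste0(id, "_signals.csv")))
  if (ncol(dataset@truthT1) > 0) {
    J <- ncol(dataset@truthT1)
    truth <- cbind(as.data.frame(dataset@truthT1),
                   as.data.frame(dataset@truthAmp))
    names(truth) <- c(paste0("t1_", seq_len(J)), paste0("amp_", seq_len(J)))
    paths <- c(paths, writeTable(truth, file.path(dir, paste0(id, "_truth.csv"))))
  }
  invisible(paths)
}

#' Load a composite dataset from CSV
#'
#' Counterpart of [saveCompositeDataset()]. A missing truth file yields a
#' dataset without ground truth (evaluation disabled) and a warning.
#'
#' @param dir Directory holding the files.
#' @param id Combination id (file prefix).
#' @return A [CompositeDataset-class].
#' @export
loadCompositeDataset <- function(dir, id) {
  sigPath <- file.path(dir, paste0(id, "_signals.csv"))
  if (!file.exists(sigPath)) stop("no signals file for '", id, "' in ", dir)
  sig <- utils::read.csv(sigPath, check.names = FALSE)
  ti <- suppressWarnings(as.numeric(sub("^ti_", "", names(sig))))
  if (any(is.na(ti)))
    stop("malformed signal columns: names must be ti_<ms>")
  if (any(diff(ti) <= 0))
    stop("malformed TI grid: inversion times must be strictly increasing")
  truthPath <- file.path(dir, paste0(id, "_truth.csv"))
  if (file.exists(truthPath)) {
    truth <- utils::read.csv(truthPath)
    t1Cols <- grep("^t1_", names(truth))
    ampCols <- grep("^amp_", names(truth))
    if (length(t1Cols) == 0 || length(t1Cols) != length(ampCols))
      stop("malformed truth file: expected matching t1_<j> and amp_<j> columns")
    truthT1 <- as.matrix(truth[, t1Cols, drop = FALSE])
    truthAmp <- as.matrix(truth[, ampCols, drop = FALSE])
    ratio <- if (ncol(truthT1) >= 2) meanT1Ratio(truthT1) else NA_real_
  } else {
    warning("no truth file for '", id, "'; evaluation will be disabled")
    truthT1 <- truthAmp <- matrix(numeric(), nrow(sig), 0)
    ratio <- NA_real_
  }
  new("CompositeDataset", combinationId = id, ti = ti,
      signals = unname(as.matrix(sig)), truthT1 = unname(truthT1),
      truthAmp = unname(truthAmp), meanT1Ratio = ratio)
}

# Flatten one voxel's FitResult into a CSV row.
fitRow <- function(fit, id, voxel) {
  cs <- fittedComponents(fit)
  data.frame(combinationId = id, voxel = voxel, method = fit@method,
             nEstComponents = nComponents(cs),
             sse = fit@sse, nStartsUsed = fit@nStartsUsed,
             converged = fit@converged,
             t1Ms = packNum(t1Values(cs)), amplitudes = packNum(amplitudes(cs)))
}

#' Run the full simulation–fit–evaluation pipeline
#'
#' Generates the composite suite, fits every voxel with each configured
#' method (component counts set to the per-dataset truth; the sequential
#' selector additionally refit with one extra slot for the zero-component
#' condition), evaluates all fits, and writes the suite manifest, per-voxel
#' fit log, evaluation records, summary tables, the error-versus-ratio
#' regression (when at least three distinct ratios are available) and a YAML
#' run log to the output directory. Re-running with an identical
#' configuration reproduces identical outputs.
#'
#' @param config A [pipelineConfig()] list.
#' @return Invisibly, a list with the suite, per-method fits, the evaluation
#'   records, summaries, the regression table and the written file paths.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  stopifnot(inherits(config, "pipelineConfig"))
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(config$outDir, 2) != 0)
    stop("output directory is not writable: ", config$outDir)
  dsDir <- file.path(config$outDir, "datasets")

  suite <- buildCompositeSuite(
    suiteConfig(tiMs = config$tiMs, snrDb = config$snrDb,
                dispersion = config$dispersion, nVoxels = config$nVoxels,
                combinations = config$combinations),
    seed = config$seed)

  manifest <- do.call(rbind, lapply(suite, function(d)
    data.frame(combinationId = combinationId(d),
               nComponents = ncol(d@truthT1),
               componentMeansMs = packNum(config$combinations[[combinationId(d)]]),
               meanT1Ratio = round(d@meanT1Ratio, 2))))
  rownames(manifest) <- NULL
  files <- writeTable(manifest, file.path(config$outDir, "manifest.csv"))
  for (d in suite) files <- c(files, saveCompositeDataset(d, dsDir))

  grid <- defaultT1Grid(n = config$gridSize)
  fitRows <- list()
  records <- list()
  allFits <- list()
  for (id in names(suite)) {
    d <- suite[[id]]
    for (m in config$methods) {
      fits <- fitDataset(d, method = m, seed = childSeed(config$seed, match(id, names(suite)) * 100 + match(m, c("ilt", "mul", "tom"))),
                         nStarts = config$nStarts, t1GridMs = grid,
                         threshold = config$threshold)
      allFits[[paste(id, m, sep = ".")]] <- fits
      fitRows <- c(fitRows, lapply(seq_along(fits), function(v)
        fitRow(fits[[v]], id, v)))
      rec <- evaluateDataset(d, fits, zeroComponent = FALSE)
      rec$zeroComponent <- FALSE
      records <- c(records, list(rec))
      if (config$zeroComponent && m %in% c("ilt", "tom")) {
        zfits <- if (m == "tom")
          fitDataset(d, method = m, jMax = ncol(d@truthT1) + 1L,
                     seed = childSeed(config$seed, match(id, names(suite)) * 100 + 50))
        else fits
        zrec <- evaluateDataset(d, zfits, zeroComponent = TRUE)
        zrec$zeroComponent <- TRUE
        records <- c(records, list(zrec))
      }
    }
  }
  fitLog <- do.call(rbind, fitRows)
  records <- do.call(rbind, records)
  files <- c(files, writeTable(fitLog, file.path(config$outDir, "fits.csv")),
             writeTable(records, file.path(config$outDir, "records.csv")))

  exact <- records[!records$zeroComponent, , drop = FALSE]
  summaries <- summarizeErrors(exact)
  files <- c(files,
             writeTable(summaries$errorsByComponents,
                        file.path(config$outDir, "errors_by_components.csv")),
             writeTable(summaries$componentsByDataset,
                        file.path(config$outDir, "components_by_dataset.csv")))

  twoComp <- exact[exact$nTrueComponents == 2, , drop = FALSE]
  regression <- NULL
  if (nrow(twoComp) > 0 &&
      length(unique(round(twoComp$datasetT1Ratio, 6))) >= 3) {
    regression <- errorRatioRegression(twoComp)
    files <- c(files, writeTable(regression,
                                 file.path(config$outDir, "regression.csv")))
  }

  log <- list(seed = config$seed, methods = config$methods,
              snrDb = config$snrDb, dispersion = config$dispersion,
              nVoxels = config$nVoxels, gridSize = config$gridSize,
              threshold = config$threshold, nStarts = config$nStarts,
              tiMs = range(config$tiMs), nTi = length(config$tiMs),
              package = as.character(utils::packageVersion("multiexpT1")),
              rVersion = R.version.string)
  yaml::write_yaml(log, file.path(config$outDir, "runlog.yaml"))
  files <- c(files, file.path(config$outDir, "runlog.yaml"))

  invisible(list(suite = suite, fits = allFits, records = records,
                 summaries = summaries, regression = regression,
                 files = files))
}
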