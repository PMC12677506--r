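test_that("alignment pairs swapped estimates with the right truth slots", {
  truth <- ComponentSet(c(1, 1), c(641, 2733))
  est <- ComponentSet(c(1, 1), c(650, 2700))  # canonical order sorts them
  al <- alignComponents(est, truth)
  expect_equal(al$pairs$estT1, c(650, 2700))
  expect_equal(al$pairs$trueT1, c(641, 2733))
  # identity when the estimate equals the truth
  al2 <- alignComponents(truth, truth)
  expect_equal(al2$cost, 0)
  expect_equal(al2$permutation, 1:2)
  # symmetric truth: equal-cost pairings resolved lexicographically
  al3 <- alignComponents(ComponentSet(c(1, 1), c(900, 1100)),
                         ComponentSet(c(1, 1), c(1000, 1000)))
  expect_equal(al3$permutation, 1:2)
  expect_error(alignComponents(ComponentSet(1, 500), truth), "equal length")
})

test_that("alignment cost equals exhaustive assignment enumeration", {
  set.seed(61)
  for (k in 1:60) {
    J <- sample(2:4, 1)
    truthT1 <- sort(runif(J, 300, 4000))
    estT1 <- runif(J, 300, 4000)
    if (k %% 4 == 0) estT1[J] <- NA  # padded estimate slot
    truth <- ComponentSet(rep(1, J), truthT1)
    estAmp <- ifelse(is.na(estT1), 0, 1)
    est <- ComponentSet(estAmp, estT1)
    al <- alignComponents(est, truth)
    expect_equal(al$cost, enumAlignCost(t1Values(est), t1Values(truth)),
                 tolerance = 1e-12)
  }
})

test_that("relative error and the zero-component error behave as documented", {
  expect_equal(relativeErrorPct(800, 1000), 20)
  expect_equal(relativeErrorPct(1000, 1000), 0)
  expect_equal(relativeErrorPct(2733, 641), 100 * (2733 - 641) / 641)
  expect_error(relativeErrorPct(1, 0), "maxMeanError")
  expect_equal(maxMeanErrorPct(0.3, 0, c(1, 0)), 30)
  expect_equal(maxMeanErrorPct(1, 0, c(2, 1, 0)), 50)
  expect_equal(maxMeanErrorPct(c(2, 1), c(2, 1), c(2, 1, 0)), c(0, 0))
  expect_error(maxMeanErrorPct(1, 0, c(0, 0)), "zero")
})

test_that("zero-component augmentation pads without phantom error", {
  truth <- ComponentSet(c(1, 1), c(641, 2733))
  aug <- augmentZeroComponent(truth, 3)
  expect_equal(nComponents(aug), 3)
  expect_equal(amplitudes(aug)[3], 0)
  expect_true(is.na(t1Values(aug)[3]))
  expect_identical(augmentZeroComponent(truth, 2), truth)
  expect_error(augmentZeroComponent(truth, 1), "at least")
  # a perfect estimator scores zero errors under augmentation
  sc <- scoreVoxelFit(truth, truth, expectedJ = 3)
  expect_equal(sc$meanRelErrT1Pct, 0)
  expect_equal(sc$meanErrAmpPct, 0)
  # an under-reporting estimate is padded and scored via the max-amp normalizer
  sc2 <- scoreVoxelFit(ComponentSet(1, 650), truth, expectedJ = 2)
  expect_equal(sc2$nEstComponents, 1)
  expect_equal(sc2$pairs$errAmpPct[2], 100)  # missing slot vs amplitude 1
})

test_that("summaries match a hand-grouped computation", {
  rec <- data.frame(
    combinationId = c("A", "A", "A", "B", "B"),
    voxel = c(1, 2, 3, 1, 2), method = c("ilt", "ilt", "mul", "ilt", "mul"),
    nTrueComponents = c(2, 2, 2, 3, 3), nEstComponents = c(1, 2, 2, 3, 2),
    meanRelErrT1Pct = c(10, 30, 20, 40, 60),
    meanErrAmpPct = c(5, 15, 10, 20, 30),
    datasetT1Ratio = c(1.5, 1.5, 1.5, 2.1, 2.1))
  sm <- summarizeErrors(rec)
  e <- sm$errorsByComponents
  expect_equal(e$meanRelErrT1Pct[e$method == "ilt" & e$nTrueComponents == 2], 20)
  expect_equal(e$nVoxels[e$method == "ilt" & e$nTrueComponents == 2], 2)
  expect_equal(e$meanRelErrT1Pct[e$method == "mul" & e$nTrueComponents == 3], 60)
  c <- sm$componentsByDataset
  expect_equal(c$meanEstComponents[c$method == "ilt" & c$combinationId == "A"], 1.5)
  # invariant to voxel ordering
  sm2 <- summarizeErrors(rec[sample(nrow(rec)), ])
  expect_equal(sm2$errorsByComponents[order(sm2$errorsByComponents$method,
                                            sm2$errorsByComponents$nTrueComponents), ],
               e[order(e$method, e$nTrueComponents), ],
               ignore_attr = TRUE)
})

test_that("error-versus-ratio regression matches closed forms", {
  # exact line
  rec <- data.frame(method = "ilt", meanRelErrT1Pct = -5 * c(1, 2, 3, 4) + 30,
                    datasetT1Ratio = c(1, 2, 3, 4))
  r <- suppressWarnings(errorRatioRegression(rec))  # exact fit warns
  expect_equal(r$slope, -5)
  expect_equal(r$intercept, 30)
  expect_equal(r$rSquared, 1)
  # six hand points against the normal equations
  x <- c(1.48, 1.62, 1.77, 2.40, 2.63, 4.26)
  set.seed(71)
  y <- 40 - 4 * x + rnorm(6, 0, 2)
  rec2 <- data.frame(method = "mul", meanRelErrT1Pct = y, datasetT1Ratio = x)
  r2 <- errorRatioRegression(rec2)
  slopeHat <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(r2$slope, slopeHat)
  expect_equal(r2$intercept, mean(y) - slopeHat * mean(x))
  # pure noise: no dependence detected
  set.seed(72)
  rec3 <- data.frame(method = "tom",
                     meanRelErrT1Pct = rnorm(300, 30, 5),
                     datasetT1Ratio = rep(x, 50))
  r3 <- errorRatioRegression(rec3)
  expect_lt(r3$rSquared, 0.05)
  expect_gt(r3$pValue, 0.01)
  expect_error(errorRatioRegression(
    data.frame(method = "ilt", meanRelErrT1Pct = 1:5,
               datasetT1Ratio = rep(2, 5))), "distinct")
})

test_that("per-dataset evaluation produces traceable voxel records", {
  suite <- buildCompositeSuite(
    suiteConfig(combinations = suiteCombinations()["Comb-3"], nVoxels = 4),
    seed = 6)
  d <- suite[[1]]
  fits <- fitDataset(d, "ilt", seed = 6)
  rec <- evaluateDataset(d, fits)
  expect_equal(nrow(rec), 4)
  expect_equal(rec$combinationId, rep("Comb-3", 4))
  expect_equal(rec$voxel, 1:4)
  expect_true(all(rec$meanErrAmpPct >= 0))
  recz <- evaluateDataset(d, fits, zeroComponent = TRUE)
  expect_true(all(recz$nTrueComponents == 2))
})
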