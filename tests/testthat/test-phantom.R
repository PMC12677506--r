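test_that("region blocks reduce to the closed-form curve without noise", {
  ti <- tiGrid()
  blk <- generateRoiBlock(641, ti, snrDb = Inf, dispersion = 0.01,
                          nVoxels = 8, seed = 3)
  for (v in 1:8) {
    expected <- abs(irSignal(ComponentSet(1, blk$trueT1[v]), ti))
    expect_equal(Mod(blk$signals[v, ]), expected, tolerance = 1e-12)
  }
})

test_that("block generation is deterministic and validates SNR", {
  ti <- tiGrid()
  a <- generateRoiBlock(1039, ti, seed = 42)
  b <- generateRoiBlock(1039, ti, seed = 42)
  expect_identical(a, b)
  expect_error(generateRoiBlock(1039, ti, snrDb = -3), "positive")
})

test_that("injected noise matches the dB convention", {
  ti <- tiGrid()
  blk <- generateRoiBlock(1000, ti, snrDb = 30, dispersion = 0,
                          nVoxels = 200, seed = 5)
  noiseless <- irSignal(ComponentSet(1, 1000), ti)
  resid <- sweep(Re(blk$signals), 2, noiseless)
  expectedSd <- max(abs(noiseless)) / 10^(30 / 20)
  expect_equal(sd(as.numeric(resid)), expectedSd, tolerance = 0.03)
  expect_equal(sd(as.numeric(Im(blk$signals))), expectedSd, tolerance = 0.03)
})

test_that("combineRois sums signed blocks and retains magnitude", {
  ti <- tiGrid()
  b1 <- matrix(irSignal(ComponentSet(1, 641), ti), 1)
  b2 <- matrix(irSignal(ComponentSet(1, 2733), ti), 1)
  expect_equal(combineRois(list(b1)), abs(b1))
  expect_equal(combineRois(list(b1, b2))[1, ],
               abs(irSignal(ComponentSet(c(1, 1), c(641, 2733)), ti)))
  expect_error(combineRois(list(b1, b2[, 1:10, drop = FALSE])), "identical")
  set.seed(9)
  n1 <- b1[rep(1, 4), ] + rnorm(200, 0, 0.05)
  n2 <- b2[rep(1, 4), ] + rnorm(200, 0, 0.05)
  expect_equal(combineRois(list(n1, n2)), refSumAbs(list(n1, n2)))
})

test_that("the default suite has the documented structure", {
  suite <- buildCompositeSuite(suiteConfig(), seed = 2)
  expect_length(suite, 10)
  expect_true(all(vapply(suite, function(d) nrow(voxelSignals(d)), 0) == 36))
  nComp <- vapply(suite, function(d) ncol(d@truthT1), 0)
  expect_equal(sum(nComp == 2), 6)
  expect_equal(sum(nComp == 3), 3)
  expect_equal(sum(nComp == 4), 1)
  expect_error(buildCompositeSuite(
    suiteConfig(combinations = list("Comb-X" = 641)), seed = 1),
    "unknown or degenerate")
})

test_that("suite serialization is reproducible byte for byte", {
  cfg <- suiteConfig(combinations = suiteCombinations()[c("Comb-1", "Comb-8")],
                     nVoxels = 6)
  d1 <- tempfile(); d2 <- tempfile()
  for (d in buildCompositeSuite(cfg, seed = 77)) saveCompositeDataset(d, d1)
  for (d in buildCompositeSuite(cfg, seed = 77)) saveCompositeDataset(d, d2)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- list.files(d2, full.names = TRUE)
  expect_identical(basename(f1), basename(f2))
  for (k in seq_along(f1))
    expect_identical(readLines(f1[k]), readLines(f2[k]))
})

test_that("meanT1Ratio matches the documented arithmetic", {
  expect_equal(meanT1Ratio(matrix(c(641, 2733), 1)), 2733 / 641)
  expect_equal(meanT1Ratio(matrix(c(641, 1039, 2733), 1)),
               mean(c(1039 / 641, 2733 / 1039)))
  expect_equal(meanT1Ratio(matrix(c(1000, 1000), 1)), 1)
  expect_error(meanT1Ratio(matrix(641, 1)), "two components")
})

test_that("suite ratios match the overview table at small dispersion", {
  expected <- c(1.62, 2.40, 4.26, 1.48, 2.63, 1.77, 1.55, 2.13, 1.63, 1.63)
  suite <- buildCompositeSuite(suiteConfig(dispersion = 0.02, snrDb = Inf),
                               seed = 13)
  got <- round(vapply(suite, function(d) d@meanT1Ratio, 0), 2)
  expect_equal(unname(got), expected, tolerance = 0.011)
})
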