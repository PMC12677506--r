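test_that("the transformation kernel matches its closed form", {
  expect_equal(buildKernel(1000 * log(2), 1000)[1, 1], 0, tolerance = 1e-12)
  expect_equal(buildKernel(0, 1000)[1, 1], -1)
  expect_equal(buildKernel(50000, 500)[1, 1], 1, tolerance = 1e-12)
  ti <- c(100, 800, 3000)
  t1 <- c(400, 2000)
  K <- buildKernel(ti, t1)
  for (i in 1:3) for (j in 1:2)
    expect_equal(K[i, j], 1 - 2 * exp(-ti[i] / t1[j]))
  expect_error(buildKernel(ti, c(0, 500)), "above 0")
})

test_that("nnlsSolve agrees with an established NNLS on overdetermined problems", {
  set.seed(31)
  for (k in 1:20) {
    A <- matrix(rnorm(15 * 4), 15, 4)
    b <- rnorm(15)
    ours <- nnlsSolve(A, b)
    ref <- pracma::lsqnonneg(A, b)
    expect_true(all(ours$x >= 0))
    expect_equal(ours$x, ref$x, tolerance = 1e-6)
  }
})

test_that("nnlsSolve beats dense random search on small problems", {
  set.seed(32)
  for (k in 1:10) {
    A <- buildKernel(sort(runif(12, 50, 5000)), seq(200, 4000, length.out = 5))
    b <- as.numeric(A %*% (rexp(5) * rbinom(5, 1, 0.6))) + rnorm(12, 0, 0.05)
    ours <- nnlsSolve(A, b)
    expect_lte(ours$residualNorm, randomSearchResidual(A, b, 500) + 1e-6)
  }
})

test_that("fitILT recovers an on-grid component and handles edge inputs", {
  ti <- tiGrid()
  grid <- defaultT1Grid()
  # signal synthesized from a single grid point
  y <- irSignal(ComponentSet(1, grid[30]), ti)
  sp <- fitILT(y, tiMs = ti)
  comps <- extractComponents(sp)
  expect_equal(nComponents(comps), 1)
  expect_equal(t1Values(comps), grid[30], tolerance = 1e-6)
  # zero signal
  sp0 <- fitILT(rep(0, length(ti)), tiMs = ti)
  expect_true(all(sp0@weights == 0))
  # optimality against the zero vector
  set.seed(41)
  yn <- y + rnorm(length(ti), 0, 0.1)
  spn <- fitILT(yn, tiMs = ti)
  A <- buildKernel(ti, grid)
  scale <- max(abs(yn))
  expect_lte(sum((yn / scale - A %*% spn@weights)^2), sum((yn / scale)^2))
  expect_true(all(spn@weights >= 0))
  expect_error(fitILT(c(yn[-1], NA), tiMs = ti), "non-finite")
})

test_that("raising the threshold never raises the component count", {
  ti <- tiGrid()
  set.seed(43)
  for (k in 1:5) {
    y <- irSignal(ComponentSet(runif(2, 0.5, 1.5), sort(runif(2, 300, 4000))),
                  ti) + rnorm(length(ti), 0, 0.05)
    counts <- vapply(c(0.01, 0.05, 0.075, 0.15, 0.4), function(th) {
      sp <- fitILT(y, tiMs = ti, threshold = th)
      nComponents(extractComponents(sp))
    }, 0)
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("extractComponents groups contiguous supra-threshold runs", {
  grid <- defaultT1Grid()
  w <- rep(0, 100)
  w[c(40, 41)] <- 0.5
  w[80] <- 0.3
  sp <- new("T1Spectrum", t1Grid = grid, weights = w, threshold = 0.075,
            scale = 1, residualNorm = 0)
  comps <- extractComponents(sp)
  expect_equal(nComponents(comps), 2)
  expect_equal(t1Values(comps)[1], (grid[40] + grid[41]) / 2)  # equal weights
  expect_equal(amplitudes(comps), c(1.0, 0.3))
  # literal bin-as-component reading
  expect_equal(nComponents(extractComponents(sp, mergeRuns = FALSE)), 3)
  # single surviving bin
  w2 <- rep(0, 100); w2[10] <- 0.2
  sp2 <- new("T1Spectrum", t1Grid = grid, weights = w2, threshold = 0.075,
             scale = 2, residualNorm = 0)
  c2 <- extractComponents(sp2)
  expect_equal(t1Values(c2), grid[10])
  expect_equal(amplitudes(c2), 0.4)  # de-normalized by the scale
  # nothing above threshold
  sp3 <- new("T1Spectrum", t1Grid = grid, weights = rep(0.05, 100),
             threshold = 0.075, scale = 1, residualNorm = 0)
  expect_equal(nComponents(extractComponents(sp3)), 0)
})

test_that("noiseless on-grid pairs with high T1 ratio are resolved exactly", {
  ti <- tiGrid()
  grid <- defaultT1Grid()
  step <- diff(grid)[1]
  for (pair in list(c(650, 2750), c(600, 2500), c(500, 2000))) {
    y <- irSignal(ComponentSet(c(1, 1), pair), ti)
    comps <- extractComponents(fitILT(y, tiMs = ti))
    expect_equal(nComponents(comps), 2)
    expect_lte(abs(t1Values(comps)[1] - pair[1]), step)
    expect_lte(abs(t1Values(comps)[2] - pair[2]), step)
  }
})
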