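test_that("objectiveSSE matches direct evaluation", {
  ti <- tiGrid()
  cs <- ComponentSet(c(1, 1), c(641, 2733))
  expect_equal(objectiveSSE(cs, magnitudeIRSignal(cs, ti), ti), 0)
  # 3-point toy with a single unit residual
  cs1 <- ComponentSet(1, 1000)
  tiToy <- c(0, 1000 * log(2), 1000 * log(2))
  expect_equal(objectiveSSE(cs1, c(1, 0, 1), tiToy), 1, tolerance = 1e-12)
  # random instances against a plain-loop oracle
  set.seed(51)
  for (k in 1:10) {
    amp <- runif(3, 0, 2)
    t1 <- sort(runif(3, 100, 4500))
    y <- runif(length(ti), 0, 2)
    expect_equal(objectiveSSE(ComponentSet(amp, t1), y, ti),
                 sseByLoop(amp, t1, ti, y))
  }
  expect_error(objectiveSSE(cs1, c(1, 0), ti), "length")
})

test_that("the multistart fitter recovers noiseless curves", {
  ti <- tiGrid()
  truth <- ComponentSet(c(1, 1), c(641, 2733))
  fit <- fitMUL(magnitudeIRSignal(truth, ti), ti, J = 2, seed = 8)
  expect_equal(t1Values(fit), c(641, 2733), tolerance = 0.01)
  expect_lt(fitSSE(fit), 1e-10)
  # single-component recovery at J = 1
  t1 <- ComponentSet(0.7, 1200)
  fit1 <- fitMUL(magnitudeIRSignal(t1, ti), ti, J = 1, seed = 8)
  expect_equal(t1Values(fit1), 1200, tolerance = 1e-4)
  expect_equal(amplitudes(fit1), 0.7, tolerance = 1e-4)
})

test_that("the multistart fitter is deterministic and bound-respecting", {
  ti <- tiGrid()
  set.seed(55)
  y <- magnitudeIRSignal(ComponentSet(c(1, 1), c(800, 2000)), ti) +
    abs(rnorm(length(ti), 0, 0.05))
  a <- fitMUL(y, ti, J = 2, seed = 99)
  b <- fitMUL(y, ti, J = 2, seed = 99)
  expect_identical(t1Values(a), t1Values(b))
  expect_identical(fitSSE(a), fitSSE(b))
  bounds <- fitBounds(y)
  expect_true(all(t1Values(a) >= bounds$t1LoMs & t1Values(a) <= bounds$t1HiMs))
  expect_true(all(amplitudes(a) >= bounds$ampLo & amplitudes(a) <= bounds$ampHi))
  expect_error(fitMUL(y, ti, J = 9, seed = 1), "maximum")
  expect_error(fitMUL(y, ti, J = 0, seed = 1), "at least 1")
})

test_that("returned SSE never increases with nested start sets", {
  ti <- tiGrid()
  set.seed(56)
  y <- magnitudeIRSignal(ComponentSet(c(1, 1), c(700, 1900)), ti) +
    abs(rnorm(length(ti), 0, 0.06))
  sses <- vapply(c(1, 4, 8, 16, 32), function(n)
    fitSSE(fitMUL(y, ti, J = 2, nStarts = n, seed = 123)), 0)
  expect_true(all(diff(sses) <= 1e-12))
})

test_that("the sequential selector picks the lowest-SSE model order", {
  ti <- tiGrid()
  set.seed(57)
  y <- magnitudeIRSignal(ComponentSet(c(1, 1), c(641, 2733)), ti) +
    abs(rnorm(length(ti), 0, 0.05))
  fit <- fitTOM(y, ti, jMax = 4, seed = 5)
  cand <- fit@details$candidateSSE
  expect_length(cand, 3)  # J = 2, 3, 4
  expect_true(nComponents(fit) %in% 2:4)
  expect_lte(fitSSE(fit), min(cand) + 1e-12)
  expect_error(fitTOM(y, ti, jMax = 1, seed = 1), "at least 2")
  # jMax = 2 degenerates to a single bounded fit with the semi-random start
  f2 <- fitTOM(y, ti, jMax = 2, seed = 5)
  expect_equal(nComponents(f2), 2)
  expect_equal(fitSSE(f2), unname(f2@details$candidateSSE["2"]))
})

test_that("selected model order stays within bounds across a dataset", {
  suite <- buildCompositeSuite(
    suiteConfig(combinations = suiteCombinations()["Comb-3"], nVoxels = 8),
    seed = 3)
  fits <- fitDataset(suite[[1]], "tom", jMax = 4, seed = 3)
  js <- vapply(fits, nComponents, 0)
  expect_true(all(js >= 2 & js <= 4))
})

test_that("a start far from the truth cannot beat the multistart optimum", {
  # self-bias: the semi-random start samples 700-2200 ms; truth far outside
  ti <- tiGrid()
  truth <- ComponentSet(c(1, 1), c(120, 4600))
  y <- magnitudeIRSignal(truth, ti)
  mul <- fitMUL(y, ti, J = 2, seed = 17)
  tom <- fitTOM(y, ti, jMax = 2, seed = 17)
  expect_lte(fitSSE(mul), fitSSE(tom) + 1e-10)
})
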