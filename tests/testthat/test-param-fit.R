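test_that("the objective sums relative node errors", {
  nodes <- expand.grid(gene = grnGenes(), stage = grnStages(),
                       stringsAsFactors = FALSE)
  ref <- transform(nodes, mean = c(10, 2, 4, 1, 8, 16))
  expect_equal(objectiveFunction(ref, ref), 0)
  one <- ref
  one$mean[1] <- 11                       # one node off by 10 percent
  expect_equal(objectiveFunction(one, ref), 0.1)
  zero <- transform(nodes, mean = 0)      # every node at zero: six unit terms
  expect_equal(objectiveFunction(zero, ref), 6)
  refZero <- ref; refZero$mean[3] <- 0
  expect_error(objectiveFunction(one, refZero), "zero reference")
  expect_error(objectiveFunction(one[-1, ], ref), "same \\(gene, stage\\)")
})

test_that("grid cardinality is the product of the value-set sizes", {
  m <- loadParameterVersion("I")
  expect_equal(gridSize(parameterGrid(m)), 1)   # empty overrides: base only
  g2 <- parameterGrid(m,
                      thetaMultipliers = list("IRF4.IRF4" = c(1, 5, 10)),
                      HCandidates = list("BCR.BCL6" = c(0.01, 0.1, 1, 10, 100)))
  expect_equal(gridSize(g2), 15)
  # property: random axis layouts
  set.seed(31)
  axes <- c("BCL6.BCL6", "IRF4.BCL6", "IRF4.IRF4", "IRF4.BLIMP1", "BCR.BCL6")
  for (rep in 1:10) {
    nAx <- sample(1:4, 1)
    pick <- sample(axes, nAx)
    sizes <- sample(1:4, nAx, replace = TRUE)
    tm <- setNames(lapply(sizes, function(s) runif(s, 0.5, 2)), pick)
    expect_equal(gridSize(parameterGrid(m, thetaMultipliers = tm)),
                 prod(sizes))
  }
  expect_error(parameterGrid(m, HCandidates = list("NOPE.BCL6" = 1)),
               "unknown grid parameter")
})

test_that("candidates enumerate deterministically in lexicographic order", {
  m <- loadParameterVersion("I")
  g <- parameterGrid(m,
                     thetaMultipliers = list("IRF4.IRF4" = c(1, 5)),
                     HCandidates = list("BCR.BCL6" = c(0.01, 0.1, 1)))
  expect_equal(gridSize(g), 6)
  th0 <- m@interactions@theta["IRF4", "IRF4"]
  got <- t(vapply(1:6, function(i) {
    cand <- gridCandidate(g, i)
    c(cand@interactions@theta["IRF4", "IRF4"],
      cand@interactions@H["BCR", "BCL6"])
  }, numeric(2)))
  # first axis (theta multiplier) varies slowest
  expect_equal(got[, 1], th0 * c(1, 1, 1, 5, 5, 5))
  expect_equal(got[, 2], rep(c(0.01, 0.1, 1), 2))
  expect_error(gridCandidate(g, 0), "out of range")
  expect_error(gridCandidate(g, 7), "out of range")
  # repeated materialization is identical
  expect_equal(gridCandidate(g, 4)@interactions@theta,
               gridCandidate(g, 4)@interactions@theta)
})

test_that("parameters are addressable by name and trigger recalibration", {
  m <- loadParameterVersion("I")
  m2 <- setParameterValue(m, "theta.IRF4.IRF4", 7)
  expect_equal(m2@interactions@theta["IRF4", "IRF4"], 7)
  expect_true(isCalibrated(m2))
  m3 <- setParameterValue(m, "s0.IRF4", 2.1)
  expect_equal(m3@genes$IRF4@s0, 2.1)
  expect_error(setParameterValue(m, "s9.IRF4", 1), "unknown parameter")
  expect_error(setParameterValue(m, "theta.IRF4", 1), "REGULATOR.TARGET")
})

test_that("the search recovers an in-grid generating candidate", {
  m <- loadParameterVersion("I")
  g <- parameterGrid(m,
                     thetaMultipliers = list("IRF4.IRF4" = c(1, 3, 10)),
                     HCandidates = list("IRF4.IRF4" = c(0.005, 0.05)))
  pr <- simulationProtocol(burnIn = 60, postStimulus = 70, nCells = 12,
                           seed = 19)
  truth <- 4L
  ref <- simulateDataset(gridCandidate(g, truth), protocol = pr)
  fit <- runGridSearch(g, ref, pr)
  expect_s4_class(fit, "FitResult")
  expect_equal(fit@index, truth)
  expect_equal(fit@of, 0)
  expect_equal(nrow(fit@ranking), 6)
  expect_true(all(fit@ranking$of >= 0))
  # a size-one grid returns its only candidate
  g1 <- parameterGrid(m)
  fit1 <- runGridSearch(g1, ref, pr)
  expect_equal(fit1@index, 1L)
})

test_that("grid subsampling is seeded and reproducible", {
  m <- loadParameterVersion("I")
  g <- parameterGrid(m,
                     thetaMultipliers = list("IRF4.IRF4" = c(1, 2, 3, 5, 10),
                                             "IRF4.BLIMP1" = c(1, 5, 10)))
  pr <- simulationProtocol(burnIn = 30, postStimulus = 70, nCells = 4,
                           seed = 2)
  ref <- simulateDataset(gridCandidate(g, 1), protocol = pr)
  f1 <- runGridSearch(g, ref, pr, subsample = 5, subsampleSeed = 9)
  f2 <- runGridSearch(g, ref, pr, subsample = 5, subsampleSeed = 9)
  expect_identical(f1@ranking$index, f2@ranking$index)
  expect_identical(f1@ranking$of, f2@ranking$of)
  expect_equal(nrow(f1@ranking), 5)
  # an oversized exhaustive request is refused without explicit subsampling
  expect_error(runGridSearch(g, ref, pr, maxExhaustive = 10),
               "pass 'subsample'")
})

test_that("a one-dimensional sweep localizes the generating value", {
  m <- singleGeneModel(s0 = 20, d0 = 0.5, s1 = 2, d1 = 1,
                       konInit = 0.3, koffInit = 0.7)
  pr <- simulationProtocol(burnIn = 100, postStimulus = 100, nCells = 25,
                           seed = 77)
  ref <- simulateDataset(m, protocol = pr)
  sp <- sweepSpec("konInit.G", lo = 0.05, hi = 1.8, points = 7, scale = "log")
  tab <- sweepParameter(sp, m, ref, pr, schedules = list())
  expect_equal(nrow(tab), 7)
  expect_false(is.unsorted(tab$value))
  # the objective is minimized at the grid point nearest the true rate
  expect_equal(which.min(tab$of), which.min(abs(tab$value - 0.3)))
  # a single-point sweep equals a direct objective evaluation
  one <- sweepParameter(sweepSpec("konInit.G", 0.3, 0.3, points = 1), m, ref,
                        pr, schedules = list())
  d <- simulateDataset(setParameterValue(m, "konInit.G", 0.3), protocol = pr)
  expect_equal(one$of, objectiveFunction(comparisonMeans(d),
                                         comparisonMeans(ref)))
  # negative log-scale intervals keep their sign
  spn <- sweepSpec("theta.BCR.G", -200, -0.1, points = 5, scale = "log")
  expect_error(validObject(spn), NA)
})
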