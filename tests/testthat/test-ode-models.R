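kpToy <- function() {
  kineticParameters(mu = c(p = 1e-6, b = 2, r = 0.1),
                    sigma = c(p = 9, b = 100, r = 2.6),
                    k = c(p = 1, b = 1, r = 1),
                    lambda = c(p = 1, b = 1, r = 1))
}

test_that("mean promoter activity is the stationary two-state fraction", {
  expect_equal(meanPromoter(1, 1), 0.5)
  expect_equal(meanPromoter(0, 2), 0)
  expect_equal(meanPromoter(0.0017, 1), 0.0017 / 1.0017)
  expect_error(meanPromoter(0, 0), "degenerate")
})

test_that("the kinetic model decays without production and finds fixed points", {
  # pure degradation: everything relaxes to zero exponentially
  kp0 <- kineticParameters(mu = c(p = 0, b = 0, r = 0),
                           sigma = c(p = 0, b = 0, r = 0),
                           k = c(p = 1, b = 1, r = 1),
                           lambda = c(p = 1, b = 1, r = 1))
  tr <- simulateKinetic(kp0, times = seq(0, 10, by = 1),
                        init = c(p = 1, b = 1, r = 1))
  expect_lt(abs(tr$p[11] - exp(-10)), 1e-5)
  expect_equal(tr$p[6], exp(-5), tolerance = 1e-4)
  expect_true(all(tr[, -1] >= 0))
  # a long relaxation ends on a state with near-zero vector field
  kp <- kpToy()
  tr2 <- simulateKinetic(kp, times = seq(0, 500, by = 10),
                         init = c(p = 0, b = 0, r = 0))
  fin <- unlist(tr2[nrow(tr2), c("p", "b", "r")])
  resid <- simulateKinetic(kp, times = c(0, 1e-4), init = fin)
  rate <- abs(unlist(resid[2, c("p", "b", "r")]) - fin) / 1e-4
  expect_lt(max(rate), 1e-4)
})

test_that("BCR stimulation lowers the steady BCL6 level of the kinetic model", {
  kp <- kpToy()
  steadyB <- function(bcrLevel) {
    tr <- simulateKinetic(kp, times = seq(0, 500, by = 10),
                          init = c(p = 0, b = 5, r = 0),
                          bcr = function(t) bcrLevel)
    tr$b[nrow(tr)]
  }
  expect_lt(steadyB(1), steadyB(0))
})

test_that("the reduced model hits the closed-form single-gene fixed point", {
  m <- singleGeneModel(s0 = 8, d0 = 0.4, s1 = 3, d1 = 1.1,
                       konInit = 0.6, koffInit = 1.4)
  tr <- simulateReduced(m, list(), times = seq(0, 200, by = 5),
                        init = list(M = 0, P = 0))
  Mstar <- 8 * 0.6 / (0.4 * (0.6 + 1.4))
  expect_equal(tr$M.G[nrow(tr)], Mstar, tolerance = 1e-5)
  expect_equal(tr$P.G[nrow(tr)], 3 * Mstar / 1.1, tolerance = 1e-5)
  expect_true(all(tr$M.G >= 0 & tr$P.G >= 0))
})

test_that("reduced trajectories are invariant to output-grid refinement", {
  m <- loadParameterVersion("I")
  fine <- simulateReduced(m, defaultSchedules(), times = seq(0, 61, by = 0.25))
  finer <- simulateReduced(m, defaultSchedules(), times = seq(0, 61, by = 0.125))
  a <- as.numeric(fine[nrow(fine), -1])
  b <- as.numeric(finer[nrow(finer), -1])
  expect_lt(max(abs(a - b) / (abs(b) + 1e-8)), 1e-3)
})

test_that("the initial-activation-rate identification inverts the fixed point", {
  expect_equal(estimateKonInit(10, s0 = 1, d0 = 0.05, koffInit = 2), 2)
  # symmetric occupancy: target = s0/(2 d0) gives kon = koff
  expect_equal(estimateKonInit(0, s0 = 1, d0 = 0.05, koffInit = 1), 0)
  expect_equal(estimateKonInit(0.034, s0 = 1, d0 = 0.05, koffInit = 1),
               0.0017 / (1 - 0.0017), tolerance = 1e-12)
  expect_error(estimateKonInit(21, s0 = 1, d0 = 0.05, koffInit = 1),
               "infeasible target")
  # round-trip: the reduced single-gene model realizes the target mean
  kon <- estimateKonInit(5, s0 = 8, d0 = 0.4, koffInit = 1.4)
  m <- singleGeneModel(s0 = 8, d0 = 0.4, s1 = 3, d1 = 1.1,
                       konInit = kon, koffInit = 1.4)
  tr <- simulateReduced(m, list(), times = c(0, 500), init = list(M = 0, P = 0))
  expect_equal(tr$M.G[2], 5, tolerance = 1e-4)
})

test_that("a non-interacting single gene is monostable", {
  m <- singleGeneModel(konInit = 0.5, koffInit = 0.5)
  rep <- detectBistability(m, schedules = defaultSchedules())
  expect_false(rep@bistable)
  expect_true(rep@converged)
  expect_equal(unname(rep@preM), unname(rep@postM), tolerance = 1e-4)
})

test_that("fast switching drives the stochastic model to the mean-field limit", {
  # scaled-down companion of the acceptance check: rates x100, one gene
  m <- singleGeneModel(s0 = 10, d0 = 0.5, s1 = 1, d1 = 1,
                       konInit = 50, koffInit = 50,
                       konMin = 0.001, konMax = 200,
                       koffMin = 0.01, koffMax = 200)
  pr <- simulationProtocol(burnIn = 50, postStimulus = 250, nCells = 4,
                           seed = 7)
  avg <- mean(vapply(1:4, function(ci) {
    tr <- simulateCell(m, list(), pr, ci)
    mean(tr$M[tr$times > 0, 1])
  }, numeric(1)))
  expect_equal(avg, (10 / 0.5) * 0.5, tolerance = 0.05)  # (s0/d0) * occupancy
})
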