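test_that("the stimulus profile follows the ramp-plateau-ramp shape", {
  bcr <- defaultSchedules()$BCR
  expect_equal(stimulusValue(bcr, 10), 1)            # plateau
  expect_equal(stimulusValue(bcr, 1.0), 0.5)         # ramp midpoint
  expect_equal(stimulusValue(bcr, 30), 0)            # after switch-off
  expect_equal(stimulusValue(bcr, c(0, 0.5, 25, 500)), c(0, 0, 0, 0))
  expect_equal(stimulusValue(bcr, 24.5), 0.5)        # ramp-down midpoint
  cd40 <- defaultSchedules()$CD40
  expect_equal(stimulusValue(cd40, 35.5), 0.5)
  expect_equal(stimulusValue(cd40, 50), 1)
  expect_equal(stimulusValue(cd40, 61), 0)
  expect_error(stimulusSchedule("BCR", 2, 1, 3, 4), "rampUpStart < rampUpEnd")
})

test_that("the promoter transition probability solves the master equation", {
  expect_equal(promoterTransitionProb(1, 0.3, 0.7, 0), 1)    # dt = 0
  expect_equal(promoterTransitionProb(0, 0.3, 0.7, 0), 0)
  expect_equal(promoterTransitionProb(0, 0.3, 0.7, 1e6), 0.3)  # stationary
  expect_equal(promoterTransitionProb(0, 1, 1, log(2) / 2), 0.25)
  expect_error(promoterTransitionProb(0, 0, 0, 1), "degenerate")
  # probabilities stay in [0, 1] over random inputs
  set.seed(5)
  for (rep in 1:50) {
    p <- promoterTransitionProb(rbinom(1, 1, 0.5), runif(1, 0, 10),
                                runif(1, 0, 10), runif(1, 0, 5))
    expect_gte(p, 0); expect_lte(p, 1)
  }
})

test_that("transition probabilities match a brute-force two-state chain", {
  # moderate replicate count here; the full-scale check runs in the
  # acceptance suite
  set.seed(99)
  n <- 20000
  for (cfg in list(c(E = 0, kon = 1.2, koff = 0.8, dt = 0.7),
                   c(E = 1, kon = 0.4, koff = 1.5, dt = 0.5))) {
    emp <- mean(vapply(seq_len(n), function(i)
      ctmcStateAt(cfg[["E"]], cfg[["kon"]], cfg[["koff"]], cfg[["dt"]]),
      numeric(1)))
    pi <- promoterTransitionProb(cfg[["E"]], cfg[["kon"]], cfg[["koff"]],
                                 cfg[["dt"]])
    se <- sqrt(pi * (1 - pi) / n)
    expect_lt(abs(emp - pi), 3 * se)
  }
})

test_that("the within-step integrator is exact for a constant promoter", {
  # stepping with any dt must match the closed-form solution at the horizon
  s0 <- 4; d0 <- 0.3; s1 <- 2; d1 <- 0.9
  M0 <- 1.5; P0 <- 0.2; Tend <- 8
  closedM <- function(t, E) s0 * E / d0 + (M0 - s0 * E / d0) * exp(-d0 * t)
  for (E in c(0L, 1L)) {
    for (dt in c(2, 0.5, 0.11)) {
      n <- ceiling(Tend / dt)
      M <- M0; P <- P0
      for (k in seq_len(n)) {
        st <- gcbnet:::.exactLinearStep(E, M, P, s0, d0, s1, d1,
                                        min(dt, Tend - (k - 1) * dt))
        M <- st$M; P <- st$P
      }
      expect_equal(M, closedM(Tend, E), tolerance = 1e-8)
      # protein reference from a high-resolution numerical integration
      ref <- deSolve::ode(c(M = M0, P = P0), times = c(0, Tend),
                          func = function(t, y, p)
                            list(c(s0 * E - d0 * y[1], s1 * y[1] - d1 * y[2])),
                          parms = NULL, rtol = 1e-12, atol = 1e-12)
      expect_equal(P, unname(ref[2, "P"]), tolerance = 1e-7)
    }
  }
  # degenerate equal-degradation case against its analytic limit
  stD <- gcbnet:::.exactLinearStep(1L, 2, 1, s0 = 3, d0 = 0.5, s1 = 1,
                                   d1 = 0.5, dt = 0.8)
  d <- 0.5; C <- 3 / d; A <- 2 - C; t <- 0.8
  expect_equal(stD$M, C + A * exp(-d * t), tolerance = 1e-12)
  expect_equal(stD$P,
               1 * exp(-d * t) + 1 * (A * t * exp(-d * t) +
                                        C * (1 - exp(-d * t)) / d),
               tolerance = 1e-9)
})

test_that("a silenced promoter leaves mRNA in pure exponential decay", {
  # konInit tiny: switch-on probability negligible, decay must be exact
  m <- singleGeneModel(s0 = 10, d0 = 0.4, s1 = 2, d1 = 1,
                       konInit = 1e-12, koffInit = 1,
                       konMin = 0, konMax = 1, koffMin = 0, koffMax = 10)
  # force a non-anchored start: run the reference stepper directly
  state <- list(t = 0, E = 0L, M = 7, P = 0)
  set.seed(1)
  for (k in 1:40) state <- stepCell(state, m, list(), dt = 0.25)
  expect_equal(state$M, 7 * exp(-0.4 * 10), tolerance = 1e-8)
})

test_that("the reference stepper and the compiled kernel agree draw-for-draw", {
  m <- loadParameterVersion("I")
  pr <- simulationProtocol(burnIn = 5, postStimulus = 5, dt = 0.1,
                           sampleEvery = 0.5, nCells = 1, seed = 77)
  tr <- simulateCell(m, defaultSchedules(), pr, 1)
  # replay: same substream, same initial state, stepped in R
  seeds <- gcbnet:::.cellSeeds(77, 1)
  set.seed(seeds[1])
  init <- gcbnet:::.initialState(m)
  state <- list(t = -5, E = init$E, M = init$M, P = init$P)
  for (k in 1:100) state <- stepCell(state, m, defaultSchedules(), 0.1)
  expect_equal(unname(tr$M[nrow(tr$M), ]), state$M, tolerance = 1e-10)
  expect_equal(unname(tr$P[nrow(tr$P), ]), state$P, tolerance = 1e-10)
  expect_equal(unname(tr$E[nrow(tr$E), ]), state$E)
})

test_that("trajectories have the expected sampling layout and stay nonnegative", {
  m <- loadParameterVersion("I")
  tr <- simulateCell(m, defaultSchedules(),
                     simulationProtocol(nCells = 1, seed = 4), 1)
  expect_length(tr$times, 2001)            # (500 + 500)/0.5 + 1
  expect_equal(tr$times[1], -500)
  expect_equal(tr$times[2001], 500)
  expect_true(all(tr$M >= 0) && all(tr$P >= 0))
  expect_true(all(tr$E %in% c(0L, 1L)))
  # snapshots sit at t = 0 and t = postStimulus
  iGC <- which(tr$times == 0)
  expect_equal(unname(tr$snapshots$GC), unname(tr$M[iGC, ]))
  expect_equal(unname(tr$snapshots$PB_PC), unname(tr$M[2001, ]))
})

test_that("datasets are reproducible and shaped one row per cell and stage", {
  m <- loadParameterVersion("I")
  pr <- simulationProtocol(burnIn = 20, postStimulus = 70, nCells = 5,
                           seed = 123)
  d1 <- simulateDataset(m, protocol = pr)
  d2 <- simulateDataset(m, protocol = pr)
  expect_identical(SummarizedExperiment::assay(d1),
                   SummarizedExperiment::assay(d2))
  expect_equal(ncol(d1), 10)               # 5 GC + 5 PB_PC columns
  expect_equal(sum(stageLabels(d1) == "GC"), 5)
  expect_equal(scaleTag(d1), "molecules")
  pr1 <- simulationProtocol(burnIn = 20, postStimulus = 70, nCells = 1,
                            seed = 123)
  expect_equal(ncol(simulateDataset(m, protocol = pr1)), 2)
  # a different seed gives different data
  pr3 <- simulationProtocol(burnIn = 20, postStimulus = 70, nCells = 5,
                            seed = 124)
  expect_false(identical(SummarizedExperiment::assay(d1),
                         SummarizedExperiment::assay(simulateDataset(m, protocol = pr3))))
})

test_that("promoter occupancy converges to its stationary value", {
  m <- singleGeneModel(konInit = 0.3, koffInit = 0.7, s0 = 1, d0 = 1,
                       s1 = 1, d1 = 2)
  pr <- simulationProtocol(burnIn = 100, postStimulus = 900, nCells = 1,
                           seed = 3)
  tr <- simulateCell(m, list(), pr, 1)
  occ <- mean(tr$E[, 1])
  # conservative standard error: treat half-hour samples of the E chain as
  # having an effective correlation time 1/(kon + koff)
  nEff <- length(tr$E[, 1]) * min(1, 0.5 * (0.3 + 0.7))
  se <- sqrt(0.3 * 0.7 / nEff)
  expect_lt(abs(occ - 0.3), 3 * se)
})
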