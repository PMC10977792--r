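test_that("the interaction function reduces to 1 without regulators", {
  ip <- grnInteractionParams(
    theta = c("IRF4.BCL6" = -100, "BCR.BCL6" = -20),
    H = c("IRF4.BCL6" = 0.1, "BCR.BCL6" = 0.01))
  # empty state, no stimuli: every factor is (1 + 0)/(1 + 0)
  expect_identical(computePhi(c(0, 0, 0), c(BCR = 0, CD40 = 0), "BCL6", ip), 1)
  # all strengths zero on the target: factors cancel exactly for any state
  ip0 <- grnInteractionParams(theta = c("IRF4.BCL6" = 0),
                              H = c("IRF4.BCL6" = 0.5))
  for (P in list(c(1, 2, 3), c(0.1, 50, 0))) {
    expect_equal(computePhi(P, c(BCR = 3, CD40 = 0), "BCL6", ip0), 1)
  }
})

test_that("a single active edge evaluates to the hand-computed factor", {
  # theta = ln 2, P at threshold, gamma = 2: (1 + 2 * 1)/(1 + 1) = 1.5
  ip <- grnInteractionParams(theta = c("IRF4.BCL6" = log(2)),
                             H = c("IRF4.BCL6" = 1))
  expect_equal(computePhi(c(0, 1, 0), c(BCR = 0, CD40 = 0), "BCL6", ip), 1.5)
  # stimulus factors use exponent 1: Q = H gives the same 1.5 regardless of gamma
  ips <- grnInteractionParams(theta = c("BCR.BCL6" = log(2)),
                              H = c("BCR.BCL6" = 0.25))
  expect_equal(computePhi(c(0, 0, 0), c(BCR = 0.25, CD40 = 0), "BCL6", ips),
               1.5)
})

test_that("interaction factors stay within their exp(theta) bounds", {
  set.seed(101)
  for (rep in 1:25) {
    th <- c("BCL6.BCL6" = runif(1, -3, 3), "IRF4.BCL6" = runif(1, -3, 3),
            "BLIMP1.BCL6" = runif(1, -3, 3), "BCR.BCL6" = runif(1, -3, 3))
    H <- c("BCL6.BCL6" = runif(1, 0.01, 2), "IRF4.BCL6" = runif(1, 0.01, 2),
           "BLIMP1.BCL6" = runif(1, 0.01, 2), "BCR.BCL6" = runif(1, 0.01, 2))
    ip <- grnInteractionParams(theta = th, H = H)
    P <- runif(3, 0, 100)
    Q <- c(BCR = runif(1, 0, 10), CD40 = 0)
    phi <- computePhi(P, Q, "BCL6", ip)
    lo <- prod(pmin(1, exp(th)))
    hi <- prod(pmax(1, exp(th)))
    expect_gte(phi, lo * (1 - 1e-12))
    expect_lte(phi, hi * (1 + 1e-12))
  }
})

test_that("non-positive thresholds are rejected", {
  expect_error(interactionParams(
    matrix(0, 3, 1, dimnames = list(c("G", "BCR", "CD40"), "G")),
    matrix(0, 3, 1, dimnames = list(c("G", "BCR", "CD40"), "G"))),
    "strictly positive")
})

test_that("the activation-rate response matches its closed form", {
  g <- calibrateBeta(geneParameters("X", 1, 1, 1, 1, konInit = 1,
                                    koffInit = 1, konMin = 0, konMax = 2))
  expect_equal(g@betaOn, 1)        # beta inverts to konInit at phi = 1
  expect_equal(computeKon(1, g), 1)               # beta*phi = 1 -> 1.0
  expect_equal(computeKon(1e-300, g), 0, tolerance = 1e-12)  # -> konMin = 0
  expect_equal(computeKon(1e300, g), 2, tolerance = 1e-12)   # saturation
  # monotone in phi
  ph <- 10^seq(-3, 3, length.out = 25)
  expect_true(all(diff(vapply(ph, computeKon, numeric(1), g = g)) > 0))
})

test_that("uncalibrated genes are refused by the rate functions", {
  g <- geneParameters("X", 1, 1, 1, 1, konInit = 0.5, koffInit = 0.5)
  expect_error(computeKon(1, g), "calibration required")
  ip <- grnInteractionParams(theta = c("IRF4.BCL6" = 1),
                             H = c("IRF4.BCL6" = 1))
  expect_error(computeKoff(c(0, 0, 0), c(BCR = 0, CD40 = 0), "BCL6", ip, g),
               "calibration required")
})

test_that("beta calibration inverts the rate response exactly", {
  # boundary cases are rejected
  expect_error(geneParameters("X", 1, 1, 1, 1, konInit = 0.001,
                              koffInit = 1, konMin = 0.001, konMax = 2),
               "konMin < konInit")
  expect_error(geneParameters("X", 1, 1, 1, 1, konInit = 2.001,
                              koffInit = 1, konMin = 0.001, konMax = 2),
               "konMin < konInit")
  # round-trip property over random admissible parameters
  set.seed(202)
  for (rep in 1:30) {
    kmin <- runif(1, 0, 0.1); kmax <- runif(1, 0.5, 5)
    kinit <- runif(1, kmin + 1e-6, kmin + kmax - 1e-6)
    omin <- runif(1, 0, 0.1); omax <- runif(1, 0.5, 5)
    oinit <- runif(1, omin + 1e-6, omin + omax - 1e-6)
    g <- calibrateBeta(geneParameters("X", 1, 1, 1, 1, konInit = kinit,
                                      koffInit = oinit, konMin = kmin,
                                      konMax = kmax, koffMin = omin,
                                      koffMax = omax))
    expect_equal(computeKon(1, g), kinit, tolerance = 1e-12)
    expect_gte(g@betaOn, 0)
    expect_gte(g@betaOff, 0)
  }
})

test_that("koff uses the negated-strength form of the interaction function", {
  ip <- grnInteractionParams(theta = c("IRF4.BCL6" = 1.3),
                             H = c("IRF4.BCL6" = 0.5))
  ipNeg <- grnInteractionParams(theta = c("IRF4.BCL6" = -1.3),
                                H = c("IRF4.BCL6" = 0.5))
  P <- c(0, 0.8, 0); Q <- c(BCR = 0, CD40 = 0)
  expect_equal(computePhi(P, Q, "BCL6", ip, negate = TRUE),
               computePhi(P, Q, "BCL6", ipNeg))
  # an activator edge lowers koff below its phi = 1 value at high regulator
  g <- calibrateBeta(geneParameters("BCL6", 1, 1, 1, 1, konInit = 0.5,
                                    koffInit = 1))
  koffBase <- computeKoff(c(0, 0, 0), Q, "BCL6", ip, g)
  expect_equal(koffBase,
               g@koffMin + g@koffMax * g@betaOff / (1 + g@betaOff))
  koffHigh <- computeKoff(c(0, 100, 0), Q, "BCL6", ip, g)
  expect_lt(koffHigh, koffBase)
})

test_that("kon is monotone in regulator levels with the sign of theta", {
  g <- calibrateBeta(geneParameters("BCL6", 1, 1, 1, 1, konInit = 0.5,
                                    koffInit = 1))
  grid <- seq(0, 5, length.out = 40)
  for (th in c(2, -2)) {
    ip <- grnInteractionParams(theta = c("IRF4.BCL6" = th),
                               H = c("IRF4.BCL6" = 0.5))
    kon <- vapply(grid, function(p) {
      phi <- computePhi(c(0, p, 0), c(BCR = 0, CD40 = 0), "BCL6", ip)
      computeKon(phi, g)
    }, numeric(1))
    if (th > 0) expect_true(all(diff(kon) >= -1e-14))
    else expect_true(all(diff(kon) <= 1e-14))
  }
})

test_that("anchored calibration pins the rates to their initial values", {
  for (tag in c("I", "II", "III")) {
    m <- loadParameterVersion(tag)
    st <- anchorState(m)
    r <- switchingRates(m, unname(st$P), c(BCR = 0, CD40 = 0))
    konInit <- vapply(m@genes, function(g) g@konInit, numeric(1))
    koffInit <- vapply(m@genes, function(g) g@koffInit, numeric(1))
    expect_equal(unname(r$kon), unname(konInit), tolerance = 1e-9)
    expect_equal(unname(r$koff), unname(koffInit), tolerance = 1e-9)
  }
})

test_that("network topology constraints are enforced", {
  expect_error(grnInteractionParams(theta = c("BCL6.IRF4" = 1),
                                    H = c("BCL6.IRF4" = 1)),
               "not present in the BCL6-IRF4-BLIMP1 topology")
  ip <- grnInteractionParams(theta = c("IRF4.BCL6" = -1),
                             H = c("IRF4.BCL6" = 1))
  # structurally absent edges sit at theta = 0, H = 1
  expect_identical(ip@theta["BCL6", "IRF4"], 0)
  expect_identical(ip@theta["BLIMP1", "IRF4"], 0)
  expect_identical(ip@theta["BLIMP1", "BLIMP1"], 0)
  expect_identical(ip@H["BCL6", "IRF4"], 1)
})
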