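# Shared builders and independent oracles for the test suite.

# A single-gene network with no interactions: constant switching rates,
# useful for closed-form and limit checks.
singleGeneModel <- function(s0 = 10, d0 = 0.5, s1 = 1, d1 = 1,
                            konInit = 0.5, koffInit = 0.5,
                            konMin = 1e-4, konMax = 10,
                            koffMin = 1e-3, koffMax = 50) {
  regs <- c("G", "BCR", "CD40")
  ip <- interactionParams(
    matrix(0, 3, 1, dimnames = list(regs, "G")),
    matrix(1, 3, 1, dimnames = list(regs, "G"))
  )
  g <- geneParameters("G", s0 = s0, d0 = d0, s1 = s1, d1 = d1,
                      konInit = konInit, koffInit = koffInit,
                      konMin = konMin, konMax = konMax,
                      koffMin = koffMin, koffMax = koffMax)
  calibrateModel(networkModel(list(g), ip))
}

# Exact simulation of a two-state continuous-time chain over [0, horizon]:
# the brute-force oracle for the promoter transition probability.
ctmcStateAt <- function(E, kon, koff, horizon) {
  t <- 0
  repeat {
    rate <- if (E == 1) koff else kon
    t <- t + stats::rexp(1, rate)
    if (t > horizon) return(E)
    E <- 1L - E
  }
}

# Greedy 1-D transport oracle: minimal cost of moving binned distribution p
# onto q with cost |i - j| in bin units. In one dimension the greedy
# left-to-right (north-west corner) plan is optimal, so this is the discrete
# 1-Wasserstein distance, independent of the cumulative-sum implementation.
greedyTransport <- function(p, q) {
  n <- length(p)
  stopifnot(length(q) == n)
  i <- 1L; j <- 1L
  cost <- 0
  p <- p; q <- q
  while (i <= n && j <= n) {
    if (p[i] <= 1e-15) { i <- i + 1L; next }
    if (q[j] <= 1e-15) { j <- j + 1L; next }
    m <- min(p[i], q[j])
    cost <- cost + m * abs(i - j)
    p[i] <- p[i] - m
    q[j] <- q[j] - m
  }
  cost
}

# Bin a sample onto explicit shared edges (relative frequencies); used to
# feed the transport oracle without touching the package's binning helper.
binOnEdges <- function(x, edges) {
  n <- length(edges) - 1L
  h <- graphics::hist(x, breaks = edges, plot = FALSE)
  h$counts / length(x)
}
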