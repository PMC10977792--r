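## Deterministic companions of the stochastic model: the protein-level
## kinetic ODE reference system, the mean-field reduction of the promoter
## model, steady-state/bistability analysis and the identification of an
## initial activation rate from a target mean mRNA level.

#' Mean promoter activity
#'
#' Stationary probability of the active promoter state of a two-state
#' promoter, `kon / (kon + koff)`.
#'
#' @param kon,koff switching rates (1/h), not both zero.
#' @return Fraction in `[0, 1]`.
#' @export
meanPromoter <- function(kon, koff) {
  if (any(kon < 0) || any(koff < 0)) stop("rates must be nonnegative")
  if (any(kon + koff == 0))
    stop("degenerate rates: kon and koff must not both be zero")
  kon / (kon + koff)
}

#' Simulate the kinetic protein-level ODE model
#'
#' Integrates the three-protein reference system (p = BLIMP1, b = BCL6,
#' r = IRF4):
#' \deqn{dp/dt = \mu_p + \sigma_p k_b^2/(k_b^2+b^2) + \sigma_p r^2/(k_r^2+r^2) - \lambda_p p}
#' \deqn{db/dt = \mu_b + \sigma_b [k_p^2/(k_p^2+p^2)][k_b^2/(k_b^2+b^2)][k_r^2/(k_r^2+r^2)] - (\lambda_b + BCR) b}
#' \deqn{dr/dt = \mu_r + \sigma_r r^2/(k_r^2+r^2) + CD40 - \lambda_r r}
#' BCR transiently represses BCL6 (extra degradation), CD40 transiently
#' activates IRF4 (extra production).
#'
#' @param params a [KineticParameters-class].
#' @param times output time grid (hours).
#' @param init named numeric vector `c(p =, b =, r =)` of initial proteins.
#' @param bcr,cd40 stimulus functions of time (default identically 0).
#' @return data.frame with columns `time`, `p`, `b`, `r`.
#' @export
simulateKinetic <- function(params, times, init, bcr = function(t) 0,
                            cd40 = function(t) 0) {
  stopifnot(is(params, "KineticParameters"))
  if (any(init < 0)) stop("initial proteins must be >= 0")
  mu <- params@mu; sg <- params@sigma; k <- params@k; lb <- params@lambda
  deriv <- function(t, y, parms) {
    p <- y[1L]; b <- y[2L]; r <- y[3L]
    hp <- k[["p"]]^2 / (k[["p"]]^2 + p^2)
    hb <- k[["b"]]^2 / (k[["b"]]^2 + b^2)
    hr <- k[["r"]]^2 / (k[["r"]]^2 + r^2)
    ar <- r^2 / (k[["r"]]^2 + r^2)
    dp <- mu[["p"]] + sg[["p"]] * hb + sg[["p"]] * ar - lb[["p"]] * p
    db <- mu[["b"]] + sg[["b"]] * hp * hb * hr - (lb[["b"]] + bcr(t)) * b
    dr <- mu[["r"]] + sg[["r"]] * ar + cd40(t) - lb[["r"]] * r
    list(c(dp, db, dr))
  }
  y0 <- c(p = unname(init[["p"]]), b = unname(init[["b"]]),
          r = unname(init[["r"]]))
  out <- deSolve::ode(y = y0, times = times, func = deriv, parms = NULL)
  if (attr(out, "istate")[1L] < 0)
    stop("kinetic model integration failed; see deSolve diagnostics")
  as.data.frame(out)
}

## mean-field vector field of the reduced model at state y = (M, P),
## with stimuli Q (named vector)
.reducedField <- function(model, M, P, Q) {
  rates <- switchingRates(model, P, Q)
  e <- rates$kon / (rates$kon + rates$koff)
  s0 <- vapply(model@genes, function(g) g@s0, numeric(1))
  d0 <- vapply(model@genes, function(g) g@d0, numeric(1))
  s1 <- vapply(model@genes, function(g) g@s1, numeric(1))
  d1 <- vapply(model@genes, function(g) g@d1, numeric(1))
  list(dM = s0 * e - d0 * M, dP = s1 * M - d1 * P, e = e)
}

#' Simulate the mean-field reduction of the stochastic model
#'
#' Replaces the binary promoter by its stationary mean
#' `kon(P, Q) / (kon(P, Q) + koff(P, Q))` evaluated continuously along the
#' trajectory:
#' `dM/dt = s0 * <E> - d0 * M`, `dP/dt = s1 * M - d1 * P`.
#'
#' @param model a calibrated [NetworkModel-class].
#' @param schedules named list of [StimulusSchedule-class] (empty list for a
#'   stimulus-free run).
#' @param times output time grid (hours; the stimulus schedule clock).
#' @param init list with numeric vectors `M` and `P` (gene order); defaults
#'   to the anchor state.
#' @return data.frame with `time`, then `M.<gene>` and `P.<gene>` columns.
#' @export
simulateReduced <- function(model, schedules = defaultSchedules(), times,
                            init = NULL) {
  if (!isCalibrated(model))
    stop("calibration required: run calibrateModel() first")
  nG <- length(model@genes)
  ids <- vapply(model@genes, function(g) g@geneId, character(1))
  if (is.null(init)) {
    st <- anchorState(model)
    init <- list(M = unname(st$M), P = unname(st$P))
  }
  deriv <- function(t, y, parms) {
    M <- pmax(y[seq_len(nG)], 0)
    P <- pmax(y[nG + seq_len(nG)], 0)
    Q <- .stimulusVector(schedules, t)
    f <- .reducedField(model, M, P, Q)
    list(c(f$dM, f$dP))
  }
  y0 <- c(init$M, init$P)
  out <- deSolve::ode(y = y0, times = times, func = deriv, parms = NULL)
  if (attr(out, "istate")[1L] < 0)
    stop("reduced model integration failed; see deSolve diagnostics")
  out <- as.data.frame(out)
  names(out) <- c("time", paste0("M.", ids), paste0("P.", ids))
  out
}

## relax the stimulus-free reduced model from (M, P) until the relative state
## change over a 50 h window drops below tol; returns state + convergence flag
.relaxReduced <- function(model, M, P, tol = 1e-6, window = 50,
                          horizon = 5000) {
  t <- 0
  repeat {
    tr <- simulateReduced(model, schedules = list(),
                          times = c(0, window), init = list(M = M, P = P))
    nG <- length(model@genes)
    Mn <- as.numeric(tr[nrow(tr), 1 + seq_len(nG)])
    Pn <- as.numeric(tr[nrow(tr), 1 + nG + seq_len(nG)])
    num <- sqrt(sum((Mn - M)^2) + sum((Pn - P)^2))
    den <- sqrt(sum(Mn^2) + sum(Pn^2)) + 1e-12
    M <- Mn; P <- Pn; t <- t + window
    if (num / den < tol) return(list(M = M, P = P, converged = TRUE))
    if (t >= horizon) return(list(M = M, P = P, converged = FALSE))
  }
}

## numerical Jacobian of the stimulus-free reduced field at (M, P)
.reducedJacobian <- function(model, M, P, rel = 1e-6, habs = 1e-9) {
  y <- c(M, P)
  nG <- length(M)
  f0 <- function(y) {
    f <- .reducedField(model, pmax(y[seq_len(nG)], 0),
                       pmax(y[nG + seq_len(nG)], 0), c(BCR = 0, CD40 = 0))
    c(f$dM, f$dP)
  }
  n <- length(y)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    h <- max(rel * abs(y[j]), habs)
    yp <- y; ym <- y
    yp[j] <- y[j] + h; ym[j] <- max(y[j] - h, 0)
    J[, j] <- (f0(yp) - f0(ym)) / (yp[j] - ym[j])
  }
  J
}

.isStableState <- function(model, M, P) {
  J <- .reducedJacobian(model, M, P)
  ev <- eigen(J, only.values = TRUE)$values
  max(Re(ev)) < 1e-9
}

#' Detect bistability of the mean-field model under the stimulus protocol
#'
#' Relaxes the stimulus-free reduced model from the anchor state to a
#' pre-stimulus steady state, runs the full stimulus protocol, relaxes again
#' to a post-stimulus steady state, and reports whether the protocol revealed
#' two distinct stable stimulus-free steady states. Both candidate states
#' must be fixed points of the stimulus-free vector field (small residual)
#' AND linearly stable (all eigenvalues of the numerical Jacobian in the left
#' half-plane) — an unstable fixed point is not counted as a steady state, so
#' a model whose pre-stimulus state loses stability is reported monostable.
#'
#' Convergence is declared when the relative state change over a 50 h window
#' falls below `convTol`; the search gives up (with `converged = FALSE`, not
#' an error) after a 5000 h horizon.
#'
#' @param model a calibrated [NetworkModel-class].
#' @param schedules named list of [StimulusSchedule-class].
#' @param tolerance relative-difference threshold above which the pre and
#'   post states count as distinct (default 0.01).
#' @param convTol convergence tolerance of the relaxations.
#' @return A [SteadyStateReport-class].
#' @examples
#' \donttest{
#' rep <- detectBistability(loadParameterVersion("I"))
#' rep@bistable
#' }
#' @export
detectBistability <- function(model, schedules = defaultSchedules(),
                              tolerance = 0.01, convTol = 1e-6) {
  if (!isCalibrated(model))
    stop("calibration required: run calibrateModel() first")
  nG <- length(model@genes)
  ids <- vapply(model@genes, function(g) g@geneId, character(1))
  st <- anchorState(model)

  ## relax to an attractor; a relaxation that parks on an unstable fixed
  ## point (possible because the anchor is an exact fixed point) is restarted
  ## from a slightly raised state — the side the bursty stochastic dynamics
  ## explores, since promoter excursions of a nearly-off gene are upward
  relaxStable <- function(M, P) {
    r <- .relaxReduced(model, M, P, tol = convTol)
    if (r$converged && !.isStableState(model, r$M, r$P))
      r <- .relaxReduced(model, r$M * 1.01 + 1e-9, r$P * 1.01 + 1e-9,
                         tol = convTol)
    r
  }
  pre <- relaxStable(unname(st$M), unname(st$P))

  ## stimulus phase: integrate through the protocol window on a fine grid so
  ## the short ramp/plateau windows are fully resolved
  tEnd <- max(vapply(schedules, function(s) s@rampDownEnd, numeric(1)), 0)
  if (length(schedules) && tEnd > 0) {
    tr <- simulateReduced(model, schedules,
                          times = seq(0, tEnd, length.out = max(245, 4 * tEnd)),
                          init = list(M = pre$M, P = pre$P))
    Ms <- as.numeric(tr[nrow(tr), 1 + seq_len(nG)])
    Ps <- as.numeric(tr[nrow(tr), 1 + nG + seq_len(nG)])
  } else {
    Ms <- pre$M; Ps <- pre$P
  }
  post <- relaxStable(Ms, Ps)

  resid <- function(M, P) {
    f <- .reducedField(model, M, P, c(BCR = 0, CD40 = 0))
    max(abs(c(f$dM, f$dP)))
  }
  preStable <- .isStableState(model, pre$M, pre$P)
  postStable <- .isStableState(model, post$M, post$P)
  relDiff <- sqrt(sum((pre$M - post$M)^2) + sum((pre$P - post$P)^2)) /
    (sqrt(sum(post$M^2) + sum(post$P^2)) + 1e-12)
  bist <- isTRUE(pre$converged && post$converged && preStable && postStable &&
                   relDiff > tolerance)
  new("SteadyStateReport",
      preM = setNames(pre$M, ids), postM = setNames(post$M, ids),
      preP = setNames(pre$P, ids), postP = setNames(post$P, ids),
      preResidual = resid(pre$M, pre$P), postResidual = resid(post$M, post$P),
      preStable = preStable, postStable = postStable,
      bistable = bist, converged = pre$converged && post$converged)
}

#' Identify an initial activation rate from a target mean mRNA level
#'
#' In the mean-field model the steady mRNA level is
#' `M* = (s0/d0) * kon/(kon + koff)`. Given a target `M*`, the occupancy is
#' `eps = d0 * M* / s0` and the activation rate that realizes it at
#' deactivation rate `koffInit` is `kon = koffInit * eps / (1 - eps)`.
#'
#' @param targetMeanMRNA target steady mRNA level (molecules).
#' @param s0 transcription rate (mRNA/h).
#' @param d0 mRNA degradation rate (1/h).
#' @param koffInit deactivation rate (1/h).
#' @return Activation rate in 1/h.
#' @examples
#' estimateKonInit(targetMeanMRNA = 10, s0 = 1, d0 = 0.05, koffInit = 1)
#' @export
estimateKonInit <- function(targetMeanMRNA, s0, d0, koffInit) {
  if (targetMeanMRNA < 0) stop("'targetMeanMRNA' must be >= 0")
  if (s0 <= 0 || d0 <= 0 || koffInit <= 0)
    stop("'s0', 'd0' and 'koffInit' must be > 0")
  eps <- d0 * targetMeanMRNA / s0
  if (eps >= 1)
    stop("infeasible target: mean mRNA demand exceeds the s0/d0 ceiling")
  koffInit * eps / (1 - eps)
}
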