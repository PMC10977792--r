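## Stochastic simulation of the promoter/mRNA/protein network: discrete-time
## Bernoulli promoter updates with exact piecewise-linear integration of the
## mRNA and protein equations, the BCR/CD40 stimulus protocol, burn-in and
## stage snapshots.

#' Stimulus intensity at a given time
#'
#' Piecewise-linear ramp-plateau-ramp profile of a [StimulusSchedule-class]:
#' zero outside `[rampUpStart, rampDownEnd]`, linear interpolation on the
#' ramps, constant `amplitude` on the plateau. Vectorized over `t`.
#'
#' @param schedule a [StimulusSchedule-class].
#' @param t time(s) in hours.
#' @return Numeric vector of intensities.
#' @examples
#' bcr <- defaultSchedules()$BCR
#' stimulusValue(bcr, c(0, 1, 10, 24.5, 30))
#' @export
stimulusValue <- function(schedule, t) {
  stopifnot(is(schedule, "StimulusSchedule"))
  vapply(t, function(tt) {
    if (tt <= schedule@rampUpStart || tt >= schedule@rampDownEnd) return(0)
    if (tt < schedule@rampUpEnd)
      return(schedule@amplitude * (tt - schedule@rampUpStart) /
               (schedule@rampUpEnd - schedule@rampUpStart))
    if (tt <= schedule@plateauEnd) return(schedule@amplitude)
    schedule@amplitude * (schedule@rampDownEnd - tt) /
      (schedule@rampDownEnd - schedule@plateauEnd)
  }, numeric(1))
}

## stimulus intensities of a schedule list at time t (named vector)
.stimulusVector <- function(schedules, t) {
  if (!length(schedules)) return(c(BCR = 0, CD40 = 0))
  vapply(schedules, stimulusValue, numeric(1), t = t)
}

#' Promoter transition probability over one step
#'
#' Probability that a two-state promoter with constant rates `kon`, `koff`
#' is active after a time `dt`, given its current state `E`, from the exact
#' solution of the two-state master equation:
#' `pi = E * exp(-dt*(kon+koff)) + kon/(kon+koff) * (1 - exp(-dt*(kon+koff)))`.
#'
#' @param E current promoter state, 0 or 1 (vectorized).
#' @param kon,koff switching rates in 1/h, not both zero.
#' @param dt step length in hours.
#' @return Probability in `[0, 1]`.
#' @examples
#' promoterTransitionProb(0, kon = 1, koff = 1, dt = log(2) / 2)  # 0.25
#' @export
promoterTransitionProb <- function(E, kon, koff, dt) {
  if (any(kon < 0) || any(koff < 0) || any(dt < 0))
    stop("'kon', 'koff' and 'dt' must be nonnegative")
  if (any(kon + koff == 0))
    stop("degenerate rates: kon and koff must not both be zero")
  if (!all(E %in% c(0, 1))) stop("'E' must be 0 or 1")
  ee <- exp(-dt * (kon + koff))
  E * ee + kon / (kon + koff) * (1 - ee)
}

## Exact update of (M, P) over dt for constant promoter state E:
## M' = s0*E - d0*M, P' = s1*M - d1*P.
.exactLinearStep <- function(E, M, P, s0, d0, s1, d1, dt) {
  C <- s0 * E / d0
  A <- M - C
  em0 <- exp(-d0 * dt)
  em1 <- exp(-d1 * dt)
  dd <- d1 - d0
  conv <- ifelse(abs(dd) < 1e-9 * pmax(d0, d1), dt * em0, (em0 - em1) / dd)
  list(M = pmax(C + A * em0, 0),
       P = pmax(P * em1 + s1 * (A * conv + C * (1 - em1) / d1), 0))
}

#' Advance one cell by one step (reference implementation)
#'
#' One step of the stochastic scheme: switching rates are evaluated at the
#' current proteins and stimuli and frozen over `[t, t + dt]`; each promoter
#' state is redrawn as Bernoulli with the master-equation transition
#' probability; with the new promoter states held constant, mRNA and protein
#' follow the exact solution of their linear equations. This pure-R stepper
#' defines the scheme; the simulators run an equivalent compiled kernel,
#' and the two paths are interchangeable draw-for-draw.
#'
#' @param state list with elements `t` (hours), `E` (0/1 vector), `M`, `P`
#'   (nonnegative vectors), one entry per gene.
#' @param model a calibrated [NetworkModel-class].
#' @param schedules list of [StimulusSchedule-class] (may be empty).
#' @param dt step in hours.
#' @return The updated state list.
#' @export
stepCell <- function(state, model, schedules, dt) {
  Q <- .stimulusVector(schedules, state$t)
  rates <- switchingRates(model, state$P, Q)
  pi <- promoterTransitionProb(state$E, rates$kon, rates$koff, dt)
  u <- stats::runif(length(pi))
  Enew <- as.integer(u < pi)
  s0 <- vapply(model@genes, function(g) g@s0, numeric(1))
  d0 <- vapply(model@genes, function(g) g@d0, numeric(1))
  s1 <- vapply(model@genes, function(g) g@s1, numeric(1))
  d1 <- vapply(model@genes, function(g) g@d1, numeric(1))
  mp <- .exactLinearStep(Enew, state$M, state$P, s0, d0, s1, d1, dt)
  list(t = state$t + dt, E = unname(Enew), M = unname(mp$M),
       P = unname(mp$P))
}

## deterministic per-cell seeds derived from the master seed
.cellSeeds <- function(seed, nCells) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, nCells)
}

## gather model slots into the argument list of the compiled kernel
.kernelArgs <- function(model, schedules) {
  getv <- function(s) vapply(model@genes, function(g) slot(g, s), numeric(1))
  stimNames <- setdiff(rownames(model@interactions@theta),
                       colnames(model@interactions@theta))
  stim <- matrix(0, nrow = length(stimNames), ncol = 5)
  rownames(stim) <- stimNames
  for (s in stimNames) {
    if (!is.null(schedules[[s]])) {
      sc <- schedules[[s]]
      stim[s, ] <- c(sc@rampUpStart, sc@rampUpEnd, sc@plateauEnd,
                     sc@rampDownEnd, sc@amplitude)
    } else {
      stim[s, ] <- c(0, 1, 1, 2, 0)  # identically zero stimulus
    }
  }
  list(
    s0 = getv("s0"), d0 = getv("d0"), s1 = getv("s1"), d1 = getv("d1"),
    konMin = getv("konMin"), konMax = getv("konMax"),
    koffMin = getv("koffMin"), koffMax = getv("koffMax"),
    logBetaOn = log(getv("betaOn")), logBetaOff = log(getv("betaOff")),
    logPhiRefOn = log(getv("phiRefOn")), logPhiRefOff = log(getv("phiRefOff")),
    theta = model@interactions@theta, H = model@interactions@H,
    gamma = model@interactions@gamma,
    pScale = unname(proteinScale(model)), stim = stim
  )
}

## initial condition: promoter states drawn Bernoulli at the anchor activity,
## mRNA/protein at the anchor means
.initialState <- function(model) {
  st <- anchorState(model)
  list(E = as.integer(stats::runif(length(st$e)) < st$e), M = unname(st$M),
       P = unname(st$P))
}

#' Simulate one cell through the full protocol
#'
#' The cell starts at the stimulus-free mean-field state implied by the
#' initial switching rates ([anchorState()]; promoter states drawn Bernoulli
#' at the anchor activity) at `t = -burnIn`, evolves without stimuli to
#' `t = 0`, then through the stimulus protocol until `t = postStimulus`.
#' States are recorded every `sampleEvery` hours. The germinal-center (GC)
#' snapshot is the state at `t = 0` (pre-stimulus), the plasmablast (PB_PC)
#' snapshot the state at `t = postStimulus`.
#'
#' @param model a calibrated [NetworkModel-class].
#' @param schedules named list of [StimulusSchedule-class].
#' @param protocol a [SimulationProtocol-class].
#' @param cellIndex which cell substream to use (1-based).
#' @return List with `times`, matrices `M`, `P`, `E` (samples x genes) and
#'   `snapshots`, a list with `GC` and `PB_PC` mRNA vectors.
#' @export
simulateCell <- function(model, schedules = defaultSchedules(),
                         protocol = simulationProtocol(), cellIndex = 1L) {
  if (!isCalibrated(model))
    stop("calibration required: run calibrateModel() first")
  validObject(protocol)
  seeds <- .cellSeeds(protocol@seed, max(protocol@nCells, cellIndex))
  set.seed(seeds[cellIndex])
  init <- .initialState(model)
  ka <- .kernelArgs(model, schedules)
  res <- .pdmpCellCpp(
    ka$s0, ka$d0, ka$s1, ka$d1, ka$konMin, ka$konMax, ka$koffMin, ka$koffMax,
    ka$logBetaOn, ka$logBetaOff, ka$logPhiRefOn, ka$logPhiRefOff,
    ka$theta, ka$H, ka$gamma, ka$pScale, ka$stim,
    protocol@burnIn, protocol@postStimulus, protocol@dt, protocol@sampleEvery,
    init$E, init$M, init$P, TRUE)
  ids <- vapply(model@genes, function(g) g@geneId, character(1))
  colnames(res$M) <- colnames(res$P) <- colnames(res$E) <- ids
  iGC <- round(protocol@burnIn / protocol@sampleEvery) + 1L
  iPB <- length(res$times)
  res$snapshots <- list(GC = res$M[iGC, ], PB_PC = res$M[iPB, ])
  res
}

#' Simulate a single-cell dataset
#'
#' Simulates `nCells` independent cells (independent RNG substreams derived
#' deterministically from the master seed) and collects the mRNA snapshots at
#' the GC stage (`t = 0`, pre-stimulus) and the PB_PC stage
#' (`t = postStimulus`) into a stage-labelled single-cell dataset on the
#' molecule scale.
#'
#' @param model a calibrated [NetworkModel-class].
#' @param schedules named list of [StimulusSchedule-class].
#' @param protocol a [SimulationProtocol-class]; `nCells` and `seed` are
#'   taken from it.
#' @return An [SCDataset()] (a `SingleCellExperiment`) with one column per
#'   cell and stage, scale tag `"molecules"`.
#' @examples
#' \donttest{
#' m <- loadParameterVersion("III")
#' d <- simulateDataset(m, protocol = simulationProtocol(nCells = 20, seed = 1))
#' datasetMeans(d)
#' }
#' @export
simulateDataset <- function(model, schedules = defaultSchedules(),
                            protocol = simulationProtocol()) {
  if (!isCalibrated(model))
    stop("calibration required: run calibrateModel() first")
  validObject(protocol)
  n <- protocol@nCells
  seeds <- .cellSeeds(protocol@seed, n)
  ids <- vapply(model@genes, function(g) g@geneId, character(1))
  ka <- .kernelArgs(model, schedules)
  iGC <- round(protocol@burnIn / protocol@sampleEvery) + 1L
  gc <- pb <- matrix(NA_real_, nrow = n, ncol = length(ids),
                     dimnames = list(NULL, ids))
  for (ci in seq_len(n)) {
    set.seed(seeds[ci])
    init <- .initialState(model)
    res <- .pdmpCellCpp(
      ka$s0, ka$d0, ka$s1, ka$d1, ka$konMin, ka$konMax, ka$koffMin,
      ka$koffMax, ka$logBetaOn, ka$logBetaOff, ka$logPhiRefOn,
      ka$logPhiRefOff, ka$theta, ka$H, ka$gamma, ka$pScale, ka$stim,
      protocol@burnIn, protocol@postStimulus, protocol@dt,
      protocol@sampleEvery, init$E, init$M, init$P, TRUE)
    gc[ci, ] <- res$M[iGC, ]
    pb[ci, ] <- res$M[nrow(res$M), ]
  }
  cellId <- sprintf("cell_%03d", seq_len(n))
  SCDataset(values = rbind(gc, pb),
            stage = rep(grnStages(), each = n),
            cellId = rep(cellId, 2L),
            scale = "molecules")
}
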