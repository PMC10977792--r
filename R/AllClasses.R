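#' @import methods
#' @importFrom stats setNames
NULL

#' Gene and stimulus names of the germinal-center differentiation network
#'
#' The three transcription factors of the network, in fixed model order
#' (index 1 = BCL6, 2 = IRF4, 3 = BLIMP1), and the two surface-receptor
#' stimuli acting on it.
#'
#' @format Character vectors.
#' @name grnNames
NULL

#' @rdname grnNames
#' @export
grnGenes <- function() c("BCL6", "IRF4", "BLIMP1")

#' @rdname grnNames
#' @export
grnStimuli <- function() c("BCR", "CD40")

#' @rdname grnNames
#' @export
grnStages <- function() c("GC", "PB_PC")

## ---------------------------------------------------------------------------
## GeneParameters
## ---------------------------------------------------------------------------

#' GeneParameters: kinetic constants of one gene
#'
#' Per-gene constants of the two-state bursty promoter model: transcription
#' rate `s0` (mRNA/h while the promoter is on), mRNA degradation `d0` (1/h),
#' translation rate `s1` (protein per mRNA per h), protein degradation `d1`
#' (1/h), the prescribed initial promoter switching rates `konInit`/`koffInit`
#' (1/h) and the bounds `konMin`, `konMax`, `koffMin`, `koffMax` of the
#' saturating switching-rate functions. `betaOn`/`betaOff` are the
#' dimensionless scalings fixed by calibration (see [calibrateBeta()]);
#' `phiRefOn`/`phiRefOff` are the interaction-function reference values at the
#' calibration state (1 unless the model is anchored, see [calibrateModel()]).
#'
#' @slot geneId gene name.
#' @slot s0,d0,s1,d1 kinetic rates (see description), all strictly positive.
#' @slot konInit,koffInit initial switching rates, 1/h.
#' @slot konMin,konMax,koffMin,koffMax switching-rate bounds, 1/h.
#' @slot betaOn,betaOff calibrated scalings (`NA` before calibration).
#' @slot phiRefOn,phiRefOff interaction-function reference values.
#' @export
setClass("GeneParameters",
  representation(
    geneId = "character",
    s0 = "numeric", d0 = "numeric", s1 = "numeric", d1 = "numeric",
    konInit = "numeric", koffInit = "numeric",
    konMin = "numeric", konMax = "numeric",
    koffMin = "numeric", koffMax = "numeric",
    betaOn = "numeric", betaOff = "numeric",
    phiRefOn = "numeric", phiRefOff = "numeric"
  ),
  prototype(
    betaOn = NA_real_, betaOff = NA_real_,
    phiRefOn = 1, phiRefOff = 1
  )
)

setValidity("GeneParameters", function(object) {
  msg <- character()
  num1 <- function(x) length(x) == 1L && is.finite(x)
  for (s in c("s0", "d0", "s1", "d1", "konInit", "koffInit",
              "konMax", "koffMax")) {
    v <- slot(object, s)
    if (!num1(v) || v <= 0) msg <- c(msg, paste0("'", s, "' must be a single strictly positive number"))
  }
  for (s in c("konMin", "koffMin")) {
    v <- slot(object, s)
    if (!num1(v) || v < 0) msg <- c(msg, paste0("'", s, "' must be a single nonnegative number"))
  }
  if (length(msg) == 0L) {
    if (!(object@konMin < object@konInit &&
          object@konInit < object@konMin + object@konMax))
      msg <- c(msg, "calibration requires konMin < konInit < konMin + konMax")
    if (!(object@koffMin < object@koffInit &&
          object@koffInit < object@koffMin + object@koffMax))
      msg <- c(msg, "calibration requires koffMin < koffInit < koffMin + koffMax")
    for (s in c("betaOn", "betaOff")) {
      v <- slot(object, s)
      if (!is.na(v) && v < 0) msg <- c(msg, paste0("'", s, "' must be >= 0 once calibrated"))
    }
    for (s in c("phiRefOn", "phiRefOff")) {
      v <- slot(object, s)
      if (!num1(v) || v <= 0) msg <- c(msg, paste0("'", s, "' must be strictly positive"))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct GeneParameters
#'
#' @param geneId gene name.
#' @param s0,d0,s1,d1 kinetic rates (mRNA/h, 1/h, protein/mRNA/h, 1/h).
#' @param konInit,koffInit initial promoter switching rates (1/h). Must lie
#'   strictly inside `(konMin, konMin + konMax)` and
#'   `(koffMin, koffMin + koffMax)` respectively.
#' @param konMin,konMax,koffMin,koffMax bounds of the switching-rate
#'   functions (1/h). The defaults are bursting-kinetics order-of-magnitude
#'   values; they are configurable because the calibration reproduces
#'   `konInit`/`koffInit` exactly at the calibration state for any admissible
#'   choice.
#' @return A [GeneParameters-class] object (uncalibrated; see
#'   [calibrateBeta()]).
#' @examples
#' g <- geneParameters("IRF4", s0 = 1, d0 = 0.05, s1 = 160, d1 = 0.173,
#'                     konInit = 0.0017, koffInit = 1)
#' @export
geneParameters <- function(geneId, s0, d0, s1, d1, konInit, koffInit,
                           konMin = 0.001, konMax = 2,
                           koffMin = 0.01, koffMax = 10) {
  new("GeneParameters", geneId = as.character(geneId),
      s0 = s0, d0 = d0, s1 = s1, d1 = d1,
      konInit = konInit, koffInit = koffInit,
      konMin = konMin, konMax = konMax,
      koffMin = koffMin, koffMax = koffMax)
}

## ---------------------------------------------------------------------------
## InteractionParams
## ---------------------------------------------------------------------------

#' InteractionParams: interaction strengths and thresholds
#'
#' Matrices over (regulator | stimulus) x target gene. `theta[w, i]` is the
#' log-scale interaction strength of regulator `w` on target gene `i`
#' (positive = activation, negative = repression, 0 = no edge); `H[w, i]` is
#' the corresponding interaction threshold (level at which the Hill factor is
#' half-way); `gamma` is the Hill exponent applied to protein regulators
#' (stimulus factors use exponent 1).
#'
#' @slot theta numeric matrix, rows = regulators (genes then stimuli),
#'   columns = target genes.
#' @slot H numeric matrix with the same dimnames, strictly positive.
#' @slot gamma positive Hill exponent (default 2).
#' @export
setClass("InteractionParams",
  representation(theta = "matrix", H = "matrix", gamma = "numeric"),
  prototype(gamma = 2)
)

setValidity("InteractionParams", function(object) {
  msg <- character()
  if (!is.numeric(object@theta) || !is.numeric(object@H))
    return("'theta' and 'H' must be numeric matrices")
  if (!identical(dim(object@theta), dim(object@H)))
    msg <- c(msg, "'theta' and 'H' must have identical dimensions")
  if (is.null(rownames(object@theta)) || is.null(colnames(object@theta)))
    msg <- c(msg, "'theta' must have regulator rownames and target colnames")
  if (any(!is.finite(object@H)) || any(object@H <= 0))
    msg <- c(msg, "all interaction thresholds H must be strictly positive")
  if (any(!is.finite(object@theta)))
    msg <- c(msg, "all theta values must be finite")
  if (length(object@gamma) != 1L || !is.finite(object@gamma) || object@gamma <= 0)
    msg <- c(msg, "'gamma' must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Construct InteractionParams for an arbitrary network
#'
#' @param theta numeric matrix (regulators x targets) of interaction
#'   strengths; rownames are regulator gene names followed by stimulus names,
#'   colnames are target gene names.
#' @param H matrix of interaction thresholds, same dimnames as `theta`.
#' @param gamma Hill exponent for protein factors (default 2).
#' @return An [InteractionParams-class] object.
#' @export
interactionParams <- function(theta, H, gamma = 2) {
  new("InteractionParams", theta = theta, H = H, gamma = gamma)
}

#' Interaction parameters of the BCL6-IRF4-BLIMP1 network
#'
#' Builds a 5 x 3 interaction matrix pair (regulators BCL6, IRF4, BLIMP1,
#' BCR, CD40 on targets BCL6, IRF4, BLIMP1) enforcing the network topology:
#' BCL6 does not act on IRF4, BLIMP1 acts neither on IRF4 nor on itself,
#' BCR acts only on BCL6 and CD40 only on IRF4. Structurally absent edges
#' carry `theta = 0` and `H = 1`.
#'
#' @param theta named numeric vector of strengths for present edges, names of
#'   the form `"REGULATOR.TARGET"` (e.g. `"IRF4.BCL6"` for the repression of
#'   BCL6 by IRF4, `"BCR.BCL6"` for the BCR stimulus edge).
#' @param H named numeric vector of thresholds, same name convention.
#' @param gamma Hill exponent (default 2).
#' @return An [InteractionParams-class] object with the fixed topology.
#' @examples
#' ip <- grnInteractionParams(
#'   theta = c("BCL6.BCL6" = -0.2, "IRF4.BCL6" = -100, "IRF4.IRF4" = 5,
#'             "IRF4.BLIMP1" = 40, "BCL6.BLIMP1" = -1, "BLIMP1.BCL6" = -20,
#'             "BCR.BCL6" = -20, "CD40.IRF4" = 40),
#'   H = c("BCL6.BCL6" = 1, "IRF4.BCL6" = 0.1, "IRF4.IRF4" = 0.01,
#'         "IRF4.BLIMP1" = 0.01, "BCL6.BLIMP1" = 0.1, "BLIMP1.BCL6" = 1,
#'         "BCR.BCL6" = 0.01, "CD40.IRF4" = 1))
#' @export
grnInteractionParams <- function(theta, H, gamma = 2) {
  genes <- grnGenes()
  regs <- c(genes, grnStimuli())
  allowed <- c("BCL6.BCL6", "IRF4.BCL6", "BLIMP1.BCL6", "BCR.BCL6",
               "IRF4.IRF4", "CD40.IRF4",
               "BCL6.BLIMP1", "IRF4.BLIMP1")
  checkEdges <- function(x, what) {
    bad <- setdiff(names(x), allowed)
    if (length(bad))
      stop("edges not present in the BCL6-IRF4-BLIMP1 topology: ",
           paste(bad, collapse = ", "), " (", what, ")")
  }
  checkEdges(theta, "theta"); checkEdges(H, "H")
  tm <- matrix(0, nrow = length(regs), ncol = length(genes),
               dimnames = list(regs, genes))
  hm <- matrix(1, nrow = length(regs), ncol = length(genes),
               dimnames = list(regs, genes))
  for (nm in names(theta)) {
    p <- strsplit(nm, ".", fixed = TRUE)[[1L]]
    tm[p[1L], p[2L]] <- theta[[nm]]
  }
  for (nm in names(H)) {
    p <- strsplit(nm, ".", fixed = TRUE)[[1L]]
    hm[p[1L], p[2L]] <- H[[nm]]
  }
  interactionParams(tm, hm, gamma = gamma)
}

## ---------------------------------------------------------------------------
## NetworkModel
## ---------------------------------------------------------------------------

#' NetworkModel: genes plus interactions
#'
#' The full regulatory-network model: an ordered list of
#' [GeneParameters-class] (model order: BCL6 = 1, IRF4 = 2, BLIMP1 = 3 for
#' the germinal-center network) and one [InteractionParams-class].
#'
#' @slot genes list of [GeneParameters-class], one per gene, in model order.
#' @slot interactions an [InteractionParams-class].
#' @export
setClass("NetworkModel",
  representation(genes = "list", interactions = "InteractionParams")
)

setValidity("NetworkModel", function(object) {
  msg <- character()
  if (!length(object@genes))
    return("'genes' must contain at least one GeneParameters")
  if (!all(vapply(object@genes, is, logical(1), "GeneParameters")))
    return("'genes' must be a list of GeneParameters")
  ids <- unname(vapply(object@genes, function(g) g@geneId, character(1)))
  if (anyDuplicated(ids)) msg <- c(msg, "duplicated gene ids")
  tg <- colnames(object@interactions@theta)
  if (!identical(ids, tg))
    msg <- c(msg, "interaction target columns must match gene order")
  if (!all(ids %in% rownames(object@interactions@theta)))
    msg <- c(msg, "every gene must appear among interaction regulators")
  if (length(msg)) msg else TRUE
})

#' Construct a NetworkModel
#'
#' @param genes list of [GeneParameters-class] in model order.
#' @param interactions an [InteractionParams-class] whose target columns
#'   match the gene order.
#' @return A [NetworkModel-class] object (uncalibrated).
#' @seealso [calibrateModel()], [loadParameterVersion()]
#' @export
networkModel <- function(genes, interactions) {
  names(genes) <- vapply(genes, function(g) g@geneId, character(1))
  new("NetworkModel", genes = genes, interactions = interactions)
}

## ---------------------------------------------------------------------------
## StimulusSchedule
## ---------------------------------------------------------------------------

#' StimulusSchedule: piecewise-linear stimulus time course
#'
#' A ramp-plateau-ramp intensity profile: zero before `rampUpStart`, linear
#' increase to `amplitude` on `[rampUpStart, rampUpEnd]`, constant until
#' `plateauEnd`, linear decrease to zero on `[plateauEnd, rampDownEnd]`, zero
#' afterwards. Times in hours relative to stimulus onset of the protocol.
#'
#' @slot stimulusId stimulus name (`"BCR"` or `"CD40"` for this network).
#' @slot rampUpStart,rampUpEnd,plateauEnd,rampDownEnd schedule breakpoints,
#'   hours.
#' @slot amplitude dimensionless peak intensity.
#' @export
setClass("StimulusSchedule",
  representation(
    stimulusId = "character",
    rampUpStart = "numeric", rampUpEnd = "numeric",
    plateauEnd = "numeric", rampDownEnd = "numeric",
    amplitude = "numeric"
  )
)

setValidity("StimulusSchedule", function(object) {
  msg <- character()
  ts <- c(object@rampUpStart, object@rampUpEnd, object@plateauEnd,
          object@rampDownEnd)
  if (any(!is.finite(ts))) return("schedule breakpoints must be finite")
  if (!(object@rampUpStart < object@rampUpEnd &&
        object@rampUpEnd <= object@plateauEnd &&
        object@plateauEnd < object@rampDownEnd))
    msg <- c(msg, "need rampUpStart < rampUpEnd <= plateauEnd < rampDownEnd")
  if (!is.finite(object@amplitude) || object@amplitude < 0)
    msg <- c(msg, "'amplitude' must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a StimulusSchedule
#'
#' @param stimulusId stimulus name.
#' @param rampUpStart,rampUpEnd,plateauEnd,rampDownEnd breakpoints in hours.
#' @param amplitude peak intensity (default 1).
#' @return A [StimulusSchedule-class].
#' @export
stimulusSchedule <- function(stimulusId, rampUpStart, rampUpEnd, plateauEnd,
                             rampDownEnd, amplitude = 1) {
  new("StimulusSchedule", stimulusId = stimulusId,
      rampUpStart = rampUpStart, rampUpEnd = rampUpEnd,
      plateauEnd = plateauEnd, rampDownEnd = rampDownEnd,
      amplitude = amplitude)
}

#' Default BCR/CD40 stimulus protocol
#'
#' BCR acts on BCL6 from 0 h until 25 h (ramp on 0.5-1.5 h, plateau until
#' 24 h, ramp down until 25 h); CD40 acts on IRF4 until 61 h (ramp 35-36 h,
#' plateau until 60 h, ramp down until 61 h). Both with unit amplitude; the
#' stimulus thresholds `H[s, i]` carry the intensity scale.
#'
#' @return Named list of two [StimulusSchedule-class] objects.
#' @export
defaultSchedules <- function() {
  list(
    BCR = stimulusSchedule("BCR", 0.5, 1.5, 24, 25),
    CD40 = stimulusSchedule("CD40", 35, 36, 60, 61)
  )
}

## ---------------------------------------------------------------------------
## SimulationProtocol
## ---------------------------------------------------------------------------

#' SimulationProtocol: burn-in, stimulus phase and sampling settings
#'
#' @slot burnIn hours of stimulus-free evolution before time 0 (default 500).
#' @slot postStimulus hours simulated after time 0 (default 500).
#' @slot dt promoter-update/integration step in hours (default 0.1).
#' @slot sampleEvery sampling interval in hours (default 0.5); must be a
#'   multiple of `dt`.
#' @slot nCells number of independent cells.
#' @slot seed master seed; per-cell substreams are derived from it.
#' @export
setClass("SimulationProtocol",
  representation(
    burnIn = "numeric", postStimulus = "numeric",
    dt = "numeric", sampleEvery = "numeric",
    nCells = "integer", seed = "integer"
  ),
  prototype(burnIn = 500, postStimulus = 500, dt = 0.1, sampleEvery = 0.5,
            nCells = 200L, seed = 1L)
)

setValidity("SimulationProtocol", function(object) {
  msg <- character()
  if (object@burnIn <= 0 || object@postStimulus <= 0)
    msg <- c(msg, "'burnIn' and 'postStimulus' must be > 0")
  if (object@dt <= 0) msg <- c(msg, "'dt' must be > 0")
  if (object@dt > object@sampleEvery)
    msg <- c(msg, "'dt' must not exceed 'sampleEvery'")
  r <- object@sampleEvery / object@dt
  if (abs(r - round(r)) > 1e-8)
    msg <- c(msg, "'sampleEvery' must be an integer multiple of 'dt'")
  for (s in c("burnIn", "postStimulus")) {
    r <- slot(object, s) / object@sampleEvery
    if (abs(r - round(r)) > 1e-8)
      msg <- c(msg, paste0("'", s, "' must be an integer multiple of 'sampleEvery'"))
  }
  if (object@nCells < 1L) msg <- c(msg, "'nCells' must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a SimulationProtocol
#'
#' @param burnIn,postStimulus,dt,sampleEvery timing settings in hours.
#' @param nCells number of cells.
#' @param seed master RNG seed.
#' @return A [SimulationProtocol-class].
#' @export
simulationProtocol <- function(burnIn = 500, postStimulus = 500, dt = 0.1,
                               sampleEvery = 0.5, nCells = 200, seed = 1) {
  new("SimulationProtocol", burnIn = burnIn, postStimulus = postStimulus,
      dt = dt, sampleEvery = sampleEvery, nCells = as.integer(nCells),
      seed = as.integer(seed))
}

## ---------------------------------------------------------------------------
## KineticParameters (deterministic reference model)
## ---------------------------------------------------------------------------

#' KineticParameters: constants of the kinetic protein-level ODE model
#'
#' Per protein x in {p (BLIMP1), b (BCL6), r (IRF4)}: basal production
#' `mu[x]`, maximum induced rate `sigma[x]`, dissociation constant `k[x]` and
#' degradation rate `lambda[x]`. No default values are shipped: the source
#' publication of this model does not accompany this package, so values are
#' user-supplied configuration.
#'
#' @slot mu,sigma,k,lambda named numeric vectors with names `c("p","b","r")`.
#' @export
setClass("KineticParameters",
  representation(mu = "numeric", sigma = "numeric", k = "numeric",
                 lambda = "numeric")
)

setValidity("KineticParameters", function(object) {
  nm <- c("p", "b", "r")
  for (s in c("mu", "sigma", "k", "lambda")) {
    v <- slot(object, s)
    if (!identical(sort(names(v)), sort(nm)))
      return(paste0("'", s, "' must be named with p, b, r"))
    if (any(!is.finite(v)) || any(v < 0))
      return(paste0("'", s, "' must be nonnegative and finite"))
  }
  if (any(object@k <= 0) || any(object@lambda <= 0))
    return("'k' and 'lambda' must be strictly positive")
  TRUE
})

#' Construct KineticParameters
#' @param mu,sigma,k,lambda named numeric vectors (names `p`, `b`, `r`).
#' @return A [KineticParameters-class].
#' @export
kineticParameters <- function(mu, sigma, k, lambda) {
  nm <- c("p", "b", "r")
  new("KineticParameters", mu = mu[nm], sigma = sigma[nm], k = k[nm],
      lambda = lambda[nm])
}

## ---------------------------------------------------------------------------
## SteadyStateReport
## ---------------------------------------------------------------------------

#' SteadyStateReport: outcome of a bistability analysis
#'
#' @slot preM,postM steady mRNA levels before / after the stimulus protocol.
#' @slot preP,postP steady protein levels.
#' @slot preResidual,postResidual max abs value of the stimulus-free vector
#'   field at the two states.
#' @slot preStable,postStable linear stability (all Jacobian eigenvalue real
#'   parts negative).
#' @slot bistable `TRUE` when two distinct stable stimulus-free steady states
#'   were found.
#' @slot converged `FALSE` when either relaxation hit the horizon without
#'   meeting the convergence criterion.
#' @export
setClass("SteadyStateReport",
  representation(
    preM = "numeric", postM = "numeric",
    preP = "numeric", postP = "numeric",
    preResidual = "numeric", postResidual = "numeric",
    preStable = "logical", postStable = "logical",
    bistable = "logical", converged = "logical"
  )
)

## ---------------------------------------------------------------------------
## ParameterGrid / SweepSpec / FitResult
## ---------------------------------------------------------------------------

#' ParameterGrid: Cartesian candidate grid around a base model
#'
#' Candidates are formed by setting interaction thresholds `H` to listed
#' values and multiplying base `theta` values by listed factors; parameters
#' not listed stay at base values. The enumeration order is deterministic:
#' theta-multiplier axes (in the order given) first, then H axes, the first
#' axis varying slowest (lexicographic).
#'
#' @slot base calibrated or uncalibrated [NetworkModel-class].
#' @slot thetaMultipliers named list of multiplier sets; names of the form
#'   `"REGULATOR.TARGET"`.
#' @slot HCandidates named list of threshold value sets, same name form.
#' @export
setClass("ParameterGrid",
  representation(base = "NetworkModel", thetaMultipliers = "list",
                 HCandidates = "list")
)

setValidity("ParameterGrid", function(object) {
  msg <- character()
  allv <- c(object@thetaMultipliers, object@HCandidates)
  if (length(allv)) {
    if (is.null(names(allv)) || any(!nzchar(names(allv))))
      msg <- c(msg, "all grid axes must be named")
    if (any(vapply(allv, length, integer(1)) == 0L))
      msg <- c(msg, "grid value sets must be non-empty")
    regs <- rownames(object@base@interactions@theta)
    tgts <- colnames(object@base@interactions@theta)
    for (nm in names(allv)) {
      p <- strsplit(nm, ".", fixed = TRUE)[[1L]]
      if (length(p) != 2L || !(p[1L] %in% regs) || !(p[2L] %in% tgts))
        msg <- c(msg, paste0("unknown grid parameter '", nm, "'"))
    }
    if (any(vapply(object@HCandidates, function(v) any(v <= 0), logical(1))))
      msg <- c(msg, "H candidates must be strictly positive")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ParameterGrid
#'
#' @param base base [NetworkModel-class].
#' @param thetaMultipliers named list of multiplier vectors applied to the
#'   base theta values (names `"REGULATOR.TARGET"`).
#' @param HCandidates named list of absolute threshold values.
#' @return A [ParameterGrid-class].
#' @seealso [gridSize()], [gridCandidate()], [fullTuningGrid()]
#' @export
parameterGrid <- function(base, thetaMultipliers = list(),
                          HCandidates = list()) {
  new("ParameterGrid", base = base, thetaMultipliers = thetaMultipliers,
      HCandidates = HCandidates)
}

#' SweepSpec: one-dimensional parameter sweep specification
#'
#' @slot parameter parameter name, e.g. `"theta.IRF4.IRF4"`, `"H.BCR.BCL6"`,
#'   `"s0.IRF4"`, `"konInit.BLIMP1"`.
#' @slot lo,hi interval bounds (`lo < hi`).
#' @slot points number of tested values (>= 2 unless `lo == hi`).
#' @slot scale `"linear"` or `"log"` spacing.
#' @export
setClass("SweepSpec",
  representation(parameter = "character", lo = "numeric", hi = "numeric",
                 points = "integer", scale = "character")
)

setValidity("SweepSpec", function(object) {
  msg <- character()
  if (object@lo > object@hi) msg <- c(msg, "'lo' must be <= 'hi'")
  if (object@lo < object@hi && object@points < 2L)
    msg <- c(msg, "'points' must be >= 2 for a non-degenerate interval")
  if (object@points < 1L) msg <- c(msg, "'points' must be >= 1")
  if (!object@scale %in% c("linear", "log"))
    msg <- c(msg, "'scale' must be 'linear' or 'log'")
  if (object@scale == "log" && object@lo * object@hi <= 0)
    msg <- c(msg, "log scale requires bounds of the same, nonzero sign")
  if (length(msg)) msg else TRUE
})

#' Construct a SweepSpec
#' @param parameter parameter name (see [SweepSpec-class]).
#' @param lo,hi tested interval.
#' @param points number of values.
#' @param scale `"linear"` or `"log"`.
#' @return A [SweepSpec-class].
#' @export
sweepSpec <- function(parameter, lo, hi, points, scale = "linear") {
  new("SweepSpec", parameter = parameter, lo = lo, hi = hi,
      points = as.integer(points), scale = scale)
}

#' FitResult: outcome of a grid search
#'
#' @slot model best candidate [NetworkModel-class].
#' @slot of objective value of the best candidate.
#' @slot index grid index of the best candidate.
#' @slot seed seed used for the candidate simulations.
#' @slot ranking data.frame with columns `index` and `of` for every evaluated
#'   candidate, in evaluation order.
#' @export
setClass("FitResult",
  representation(model = "NetworkModel", of = "numeric", index = "integer",
                 seed = "integer", ranking = "data.frame")
)

setValidity("FitResult", function(object) {
  if (length(object@of) != 1L || is.na(object@of) || object@of < 0)
    return("'of' must be a single nonnegative number")
  TRUE
})

## ---------------------------------------------------------------------------
## BinnedDistribution / KDResult
## ---------------------------------------------------------------------------

#' BinnedDistribution: probabilities on an equal-width bin grid
#'
#' @slot edges strictly increasing, equally spaced bin edges (length N + 1).
#' @slot prob bin probabilities (length N, nonnegative, summing to 1).
#' @export
setClass("BinnedDistribution",
  representation(edges = "numeric", prob = "numeric")
)

setValidity("BinnedDistribution", function(object) {
  msg <- character()
  if (length(object@edges) != length(object@prob) + 1L)
    return("need length(edges) == length(prob) + 1")
  w <- diff(object@edges)
  if (any(w <= 0)) msg <- c(msg, "edges must be strictly increasing")
  else if (max(w) - min(w) > 1e-9 * max(w))
    msg <- c(msg, "bins must have equal widths")
  if (any(object@prob < 0)) msg <- c(msg, "probabilities must be >= 0")
  if (abs(sum(object@prob) - 1) > 1e-9)
    msg <- c(msg, "probabilities must sum to 1 (within 1e-9)")
  if (length(msg)) msg else TRUE
})

#' Bin centers of a BinnedDistribution
#' @param x a [BinnedDistribution-class].
#' @return Numeric vector of bin mid-points.
#' @export
binCenters <- function(x) {
  stopifnot(is(x, "BinnedDistribution"))
  (x@edges[-1L] + x@edges[-length(x@edges)]) / 2
}

#' KDResult: pairwise Kantorovich distances across replicate datasets
#'
#' @slot pairs data.frame with columns `gene`, `stage`, `i`, `j`, `kd`: one
#'   row per unordered dataset pair and network node.
#' @slot summary data.frame with per-node `median`, `iqr` and `nPairs`.
#' @slot nDatasets,nCells study dimensions.
#' @export
setClass("KDResult",
  representation(pairs = "data.frame", summary = "data.frame",
                 nDatasets = "integer", nCells = "integer")
)

## ---------------------------------------------------------------------------
## StageProfile (synthetic qPCR data)
## ---------------------------------------------------------------------------

#' StageProfile: structure of one stage of the synthetic qPCR dataset
#'
#' Describes, for one differentiation stage, the number of cells, the exact
#' per-gene dropout (zero) counts, and the truncated-normal law of the
#' positive expression-threshold (Et) values on (0, 30].
#'
#' @slot stage stage label (`"GC"` or `"PB_PC"`).
#' @slot nCells number of cells.
#' @slot nZero named integer vector of exact zero counts per gene.
#' @slot mu,sd named numeric vectors: truncated-normal location/scale of the
#'   positive values per gene.
#' @export
setClass("StageProfile",
  representation(stage = "character", nCells = "integer", nZero = "integer",
                 mu = "numeric", sd = "numeric")
)

setValidity("StageProfile", function(object) {
  msg <- character()
  g <- names(object@nZero)
  if (is.null(g)) return("'nZero' must be named by gene")
  if (!identical(g, names(object@mu)) || !identical(g, names(object@sd)))
    msg <- c(msg, "'mu' and 'sd' must carry the same gene names as 'nZero'")
  if (any(object@nZero < 0L) || any(object@nZero > object@nCells))
    msg <- c(msg, "need 0 <= nZero <= nCells for every gene")
  if (any(object@mu <= 0) || any(object@mu >= 30))
    msg <- c(msg, "'mu' must lie in (0, 30)")
  if (any(object@sd <= 0)) msg <- c(msg, "'sd' must be > 0")
  if (object@nCells < 1L) msg <- c(msg, "'nCells' must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a StageProfile
#' @param stage stage label.
#' @param nCells number of cells.
#' @param nZero named vector of exact zero counts per gene.
#' @param mu,sd named vectors: truncated-normal parameters of the positive Et
#'   values per gene.
#' @return A [StageProfile-class].
#' @export
stageProfile <- function(stage, nCells, nZero, mu, sd) {
  new("StageProfile", stage = stage, nCells = as.integer(nCells),
      nZero = setNames(as.integer(nZero), names(nZero)),
      mu = mu, sd = sd)
}
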