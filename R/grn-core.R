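## Promoter switching-rate machinery: interaction function Phi, saturating
## kon/koff response, beta calibration and the anchored reference state.

## log((1 + e^theta * x) / (1 + x)) for x >= 0 given on the log scale,
## stable for |theta| up to several hundred. logx = -Inf encodes x = 0.
.logFactor <- function(theta, logx) {
  if (logx == -Inf) return(0)
  a <- theta + logx                       # log(e^theta * x)
  la <- if (a > 35) a + log1p(exp(-a)) else log1p(exp(a))
  lb <- if (logx > 35) logx + log1p(exp(-logx)) else log1p(exp(logx))
  la - lb
}

## log Phi_i for target gene `target`; P and Q are levels on the scale the
## thresholds H are expressed in. `sign` = +1 for the k_on form, -1 for the
## k_off form (all theta negated).
.logPhi <- function(P, Q, target, interactions, sign = 1) {
  th <- interactions@theta
  H <- interactions@H
  gamma <- interactions@gamma
  genes <- colnames(th)
  stims <- setdiff(rownames(th), genes)
  if (!target %in% colnames(th)) stop("unknown target gene: ", target)
  if (any(H[, target] <= 0)) stop("invalid interaction threshold: H must be > 0")
  lp <- 0
  for (s in stims) {
    q <- if (!is.null(names(Q)) && s %in% names(Q)) Q[[s]] else 0
    if (q < 0) stop("stimulus intensities must be >= 0")
    logx <- if (q == 0) -Inf else log(q) - log(H[s, target])
    lp <- lp + .logFactor(sign * th[s, target], logx)
  }
  for (j in seq_along(genes)) {
    p <- P[[j]]
    if (is.na(p) || p < 0) stop("protein levels must be >= 0")
    logx <- if (p == 0) -Inf else gamma * (log(p) - log(H[genes[j], target]))
    lp <- lp + .logFactor(sign * th[genes[j], target], logx)
  }
  lp
}

#' Interaction function of the promoter switching rates
#'
#' Evaluates the product of Hill-type interaction factors that modulates the
#' promoter activation rate of a target gene: one factor
#' `(1 + exp(theta) * (Q/H)) / (1 + Q/H)` per stimulus (exponent 1) and one
#' factor `(1 + exp(theta) * (P/H)^gamma) / (1 + (P/H)^gamma)` per regulator
#' protein. Each factor lies between 1 and `exp(theta)` (in whichever order),
#' so activators (`theta > 0`) increase and repressors (`theta < 0`) decrease
#' the value; absent edges (`theta = 0`) contribute exactly 1.
#'
#' Protein levels are used on the scale the thresholds `H` are expressed in;
#' the model-level simulators pass levels normalized by the per-gene maximum
#' (see [proteinScale()]).
#'
#' @param P numeric vector of regulator protein levels, ordered as the
#'   interaction matrix columns; all `>= 0`.
#' @param Q named numeric vector of stimulus intensities (missing stimuli are
#'   treated as 0); all `>= 0`.
#' @param target target gene name.
#' @param interactions an [InteractionParams-class].
#' @param negate if `TRUE`, evaluate the deactivation-rate form, in which
#'   every `theta` is replaced by `-theta`.
#' @return A single positive number.
#' @examples
#' ip <- grnInteractionParams(theta = c("IRF4.BCL6" = log(2)),
#'                            H = c("IRF4.BCL6" = 1))
#' computePhi(c(0, 1, 0), c(BCR = 0, CD40 = 0), "BCL6", ip)  # (1+2)/(1+1)
#' @export
computePhi <- function(P, Q, target, interactions, negate = FALSE) {
  exp(.logPhi(P, Q, target, interactions, sign = if (negate) -1 else 1))
}

## Saturating rate response: min + max * z/(1+z) with z = beta*phi/phiRef,
## computed through the log scale so that huge/tiny phi never overflow.
.rateResponseLog <- function(logPhi, beta, phiRef, rMin, rMax) {
  if (beta == 0) return(rMin)
  s <- log(beta) + logPhi - log(phiRef)
  rMin + rMax * stats::plogis(s)
}

.rateResponse <- function(phi, beta, phiRef, rMin, rMax) {
  .rateResponseLog(log(phi), beta, phiRef, rMin, rMax)
}

#' Promoter activation rate from the interaction function
#'
#' `konMin + konMax * z / (1 + z)` with `z = betaOn * phi / phiRefOn`:
#' monotone increasing in `phi`, bounded in `[konMin, konMin + konMax)`.
#'
#' @param phi interaction-function value (positive).
#' @param g a calibrated [GeneParameters-class] (see [calibrateBeta()]).
#' @return Activation rate in 1/h.
#' @examples
#' g <- calibrateBeta(geneParameters("X", 1, 1, 1, 1, konInit = 1,
#'                                   koffInit = 1, konMin = 0, konMax = 2))
#' computeKon(1, g)  # reproduces konInit
#' @export
computeKon <- function(phi, g) {
  stopifnot(is(g, "GeneParameters"))
  if (is.na(g@betaOn))
    stop("calibration required: run calibrateBeta() before computeKon()")
  if (phi <= 0) stop("'phi' must be > 0")
  .rateResponse(phi, g@betaOn, g@phiRefOn, g@konMin, g@konMax)
}

#' Promoter deactivation rate
#'
#' Same functional form as [computeKon()] with the interaction function
#' evaluated under negated interaction strengths and the `koff` bounds and
#' scaling, so activators of the promoter lower its deactivation rate.
#'
#' @param P,Q,target,interactions as in [computePhi()].
#' @param g a calibrated [GeneParameters-class].
#' @return Deactivation rate in 1/h.
#' @export
computeKoff <- function(P, Q, target, interactions, g) {
  stopifnot(is(g, "GeneParameters"))
  if (is.na(g@betaOff))
    stop("calibration required: run calibrateBeta() before computeKoff()")
  phi <- exp(.logPhi(P, Q, target, interactions, sign = -1))
  .rateResponse(phi, g@betaOff, g@phiRefOff, g@koffMin, g@koffMax)
}

#' Calibrate the switching-rate scalings of one gene
#'
#' Solves the saturating rate response for `beta` such that the rate equals
#' its prescribed initial value at the calibration state (where the
#' interaction function equals its stored reference value):
#' `betaOn = (konInit - konMin) / (konMax + konMin - konInit)` and the
#' analogous expression for `betaOff`.
#'
#' @param g a [GeneParameters-class] with
#'   `konMin < konInit < konMin + konMax` (and analogously for the off rate).
#' @return `g` with `betaOn`/`betaOff` filled in.
#' @examples
#' g <- geneParameters("X", 1, 1, 1, 1, konInit = 1, koffInit = 1,
#'                     konMin = 0, konMax = 2)
#' calibrateBeta(g)@betaOn  # 1
#' @export
calibrateBeta <- function(g) {
  stopifnot(is(g, "GeneParameters"))
  if (!(g@konMin < g@konInit && g@konInit < g@konMin + g@konMax))
    stop("calibration infeasible: need konMin < konInit < konMin + konMax")
  if (!(g@koffMin < g@koffInit && g@koffInit < g@koffMin + g@koffMax))
    stop("calibration infeasible: need koffMin < koffInit < koffMin + koffMax")
  g@betaOn <- (g@konInit - g@konMin) / (g@konMax + g@konMin - g@konInit)
  g@betaOff <- (g@koffInit - g@koffMin) / (g@koffMax + g@koffMin - g@koffInit)
  validObject(g)
  g
}

#' Per-gene protein normalization scale
#'
#' The maximal attainable protein level of each gene,
#' `(s0 * s1) / (d0 * d1)` (reached with the promoter permanently on). The
#' interaction thresholds `H` are expressed against protein levels divided by
#' this scale, so a normalized level of 1 means full occupancy; at steady
#' state the normalized protein level equals the mean promoter activity.
#'
#' @param model a [NetworkModel-class].
#' @return Named numeric vector, one scale per gene (protein molecules).
#' @export
proteinScale <- function(model) {
  vapply(model@genes, function(g) (g@s0 * g@s1) / (g@d0 * g@d1), numeric(1))
}

#' Mean-field state implied by the initial switching rates
#'
#' The state at which every promoter has mean activity
#' `konInit / (konInit + koffInit)` and mRNA/protein sit at the matching
#' steady levels: `M = (s0/d0) * e`, `P = proteinScale * e`. This is the
#' state the simulations are initialized at, and the state the anchored
#' calibration pins the switching rates to.
#'
#' @param model a [NetworkModel-class].
#' @return List with components `e` (promoter activities), `M` (mRNA
#'   molecules), `P` (protein molecules), each named by gene.
#' @export
anchorState <- function(model) {
  e <- vapply(model@genes,
              function(g) g@konInit / (g@konInit + g@koffInit), numeric(1))
  M <- vapply(model@genes, function(g) g@s0 / g@d0, numeric(1)) * e
  P <- proteinScale(model) * e
  list(e = e, M = M, P = P)
}

#' Calibrate a whole network model
#'
#' Calibrates `beta` for every gene ([calibrateBeta()]) and, in the default
#' `"initState"` mode, anchors the rate functions so that the switching rates
#' equal `konInit`/`koffInit` exactly at the stimulus-free mean-field state
#' implied by those initial rates ([anchorState()]): the per-gene interaction
#' function evaluated there (with normalized protein levels) is stored as the
#' reference `phiRefOn`/`phiRefOff`. With `anchor = "none"` the references
#' stay at 1, i.e. the rates equal their initial values at zero proteins and
#' zero stimuli instead.
#'
#' @param model a [NetworkModel-class].
#' @param anchor `"initState"` (default) or `"none"`.
#' @return The calibrated model.
#' @export
calibrateModel <- function(model, anchor = c("initState", "none")) {
  anchor <- match.arg(anchor)
  model@genes <- lapply(model@genes, calibrateBeta)
  if (anchor == "initState") {
    st <- anchorState(model)
    pNorm <- st$e  # normalized protein level at the anchor
    Q0 <- setNames(numeric(length(setdiff(rownames(model@interactions@theta),
                                          colnames(model@interactions@theta)))),
                   setdiff(rownames(model@interactions@theta),
                           colnames(model@interactions@theta)))
    for (i in seq_along(model@genes)) {
      id <- model@genes[[i]]@geneId
      model@genes[[i]]@phiRefOn <-
        exp(.logPhi(pNorm, Q0, id, model@interactions, sign = 1))
      model@genes[[i]]@phiRefOff <-
        exp(.logPhi(pNorm, Q0, id, model@interactions, sign = -1))
    }
  } else {
    for (i in seq_along(model@genes)) {
      model@genes[[i]]@phiRefOn <- 1
      model@genes[[i]]@phiRefOff <- 1
    }
  }
  validObject(model)
  model
}

#' Is a model calibrated?
#' @param model a [NetworkModel-class].
#' @return `TRUE` when every gene has calibrated scalings.
#' @export
isCalibrated <- function(model) {
  all(vapply(model@genes,
             function(g) !is.na(g@betaOn) && !is.na(g@betaOff), logical(1)))
}

#' Switching rates of every gene at a given state
#'
#' Evaluates `kon` and `koff` for each gene at raw protein levels `P`
#' (molecules; internally normalized by [proteinScale()]) and stimulus
#' intensities `Q`.
#'
#' @param model a calibrated [NetworkModel-class].
#' @param P numeric vector of protein molecule numbers, in gene order.
#' @param Q named numeric vector of stimulus intensities.
#' @return List with numeric vectors `kon` and `koff` (1/h), named by gene.
#' @export
switchingRates <- function(model, P, Q = c(BCR = 0, CD40 = 0)) {
  if (!isCalibrated(model))
    stop("calibration required: run calibrateModel() first")
  pNorm <- P / proteinScale(model)
  kon <- koff <- numeric(length(model@genes))
  for (i in seq_along(model@genes)) {
    g <- model@genes[[i]]
    lpOn <- .logPhi(pNorm, Q, g@geneId, model@interactions, sign = 1)
    lpOff <- .logPhi(pNorm, Q, g@geneId, model@interactions, sign = -1)
    kon[i] <- .rateResponseLog(lpOn, g@betaOn, g@phiRefOn, g@konMin, g@konMax)
    koff[i] <- .rateResponseLog(lpOff, g@betaOff, g@phiRefOff,
                                g@koffMin, g@koffMax)
  }
  ids <- vapply(model@genes, function(g) g@geneId, character(1))
  list(kon = setNames(kon, ids), koff = setNames(koff, ids))
}
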