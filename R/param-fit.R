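## Parameter calibration machinery: the relative-error objective over the six
## (gene, stage) nodes, the deterministic Cartesian candidate grid with the
## published candidate sets, seeded grid search, and one-dimensional sweeps.

#' Objective function: summed relative error of stage-gene means
#'
#' `OF = sum over (gene, stage) nodes of |data - model| / |data|`, where the
#' sums run over the three genes and the two stages. Zero iff every node mean
#' matches exactly.
#'
#' @param modelMeans,dataMeans data.frames with columns `gene`, `stage`,
#'   `mean` covering the same nodes (as returned by [comparisonMeans()]).
#' @return Nonnegative objective value.
#' @examples
#' m <- data.frame(gene = "BCL6", stage = "GC", mean = 11)
#' d <- data.frame(gene = "BCL6", stage = "GC", mean = 10)
#' objectiveFunction(m, d)  # 0.1
#' @export
objectiveFunction <- function(modelMeans, dataMeans) {
  key <- function(df) paste(df$gene, df$stage, sep = "|")
  mk <- key(modelMeans); dk <- key(dataMeans)
  if (!setequal(mk, dk) || anyDuplicated(mk) || anyDuplicated(dk))
    stop("'modelMeans' and 'dataMeans' must cover the same (gene, stage) nodes")
  om <- dataMeans$mean[match(mk, dk)]
  ym <- modelMeans$mean
  if (any(om == 0))
    stop("zero reference mean: the objective is undefined for nodes with ",
         "zero data mean")
  sum(abs(om - ym) / abs(om))
}

## parameter addressing: "theta.REG.TARGET", "H.REG.TARGET", or
## "<slot>.GENE" with slot in s0, d0, s1, d1, konInit, koffInit,
## konMin, konMax, koffMin, koffMax
.setParameterValue <- function(model, name, value) {
  parts <- strsplit(name, ".", fixed = TRUE)[[1L]]
  kind <- parts[1L]
  if (kind %in% c("theta", "H")) {
    if (length(parts) != 3L)
      stop("expected '", kind, ".REGULATOR.TARGET': ", name)
    reg <- parts[2L]; tgt <- parts[3L]
    th <- model@interactions@theta
    if (!(reg %in% rownames(th)) || !(tgt %in% colnames(th)))
      stop("unknown interaction parameter: ", name)
    if (kind == "theta") model@interactions@theta[reg, tgt] <- value
    else model@interactions@H[reg, tgt] <- value
  } else {
    if (length(parts) != 2L) stop("expected '<slot>.GENE': ", name)
    gene <- parts[2L]
    ids <- vapply(model@genes, function(g) g@geneId, character(1))
    i <- match(gene, ids)
    if (is.na(i) ||
        !kind %in% c("s0", "d0", "s1", "d1", "konInit", "koffInit",
                     "konMin", "konMax", "koffMin", "koffMax"))
      stop("unknown parameter: ", name)
    slot(model@genes[[i]], kind) <- value
  }
  model
}

#' Set a named model parameter
#'
#' Addresses `"theta.REGULATOR.TARGET"`, `"H.REGULATOR.TARGET"` or
#' `"<slot>.GENE"` (slots `s0`, `d0`, `s1`, `d1`, `konInit`, `koffInit` and
#' the rate bounds). The returned model is re-calibrated.
#'
#' @param model a [NetworkModel-class].
#' @param name parameter name.
#' @param value new value.
#' @param anchor calibration mode passed to [calibrateModel()].
#' @return The modified, calibrated model.
#' @export
setParameterValue <- function(model, name, value,
                              anchor = c("initState", "none")) {
  calibrateModel(.setParameterValue(model, name, value),
                 anchor = match.arg(anchor))
}

#' Number of candidates of a parameter grid
#'
#' The exact Cartesian-product size, the product of the value-set sizes.
#'
#' @param grid a [ParameterGrid-class].
#' @return A number (can exceed integer range).
#' @examples
#' gridSize(fullTuningGrid(loadParameterVersion("I")))  # 7776000
#' @export
gridSize <- function(grid) {
  stopifnot(is(grid, "ParameterGrid"))
  prod(vapply(c(grid@thetaMultipliers, grid@HCandidates), length, integer(1)))
}

## axis layout of the deterministic enumeration: theta axes in list order,
## then H axes in list order; first axis varies slowest
.gridAxes <- function(grid) {
  axes <- c(
    lapply(names(grid@thetaMultipliers), function(nm)
      list(kind = "theta", name = nm, values = grid@thetaMultipliers[[nm]])),
    lapply(names(grid@HCandidates), function(nm)
      list(kind = "H", name = nm, values = grid@HCandidates[[nm]]))
  )
  axes
}

#' Materialize one grid candidate
#'
#' Decodes the 1-based candidate index along the deterministic lexicographic
#' enumeration (theta-multiplier axes first, then H axes; the first axis
#' varies slowest), applies the values to the base model (multipliers on
#' theta, absolute values for H) and re-calibrates.
#'
#' @param grid a [ParameterGrid-class].
#' @param index candidate index in `1:gridSize(grid)`.
#' @param anchor calibration mode passed to [calibrateModel()].
#' @return A calibrated [NetworkModel-class].
#' @export
gridCandidate <- function(grid, index, anchor = c("initState", "none")) {
  stopifnot(is(grid, "ParameterGrid"))
  n <- gridSize(grid)
  if (index < 1 || index > n) stop("candidate index out of range")
  axes <- .gridAxes(grid)
  model <- grid@base
  rem <- index - 1
  sizes <- vapply(axes, function(a) length(a$values), integer(1))
  if (length(axes)) {
    radix <- rev(cumprod(rev(c(sizes[-1L], 1))))
    for (k in seq_along(axes)) {
      pos <- floor(rem / radix[k]) + 1
      rem <- rem %% radix[k]
      a <- axes[[k]]
      if (a$kind == "theta") {
        p <- strsplit(a$name, ".", fixed = TRUE)[[1L]]
        cur <- model@interactions@theta[p[1L], p[2L]]
        model <- .setParameterValue(model, paste0("theta.", a$name),
                                    cur * a$values[pos])
      } else {
        model <- .setParameterValue(model, paste0("H.", a$name), a$values[pos])
      }
    }
  }
  calibrateModel(model, anchor = match.arg(anchor))
}

#' The published automatized tuning grid
#'
#' The full candidate grid of the automatized calibration stage:
#' theta multipliers {1, 5} on the five gene-gene edges BCL6->BCL6,
#' BCL6->BLIMP1, IRF4->BCL6, IRF4->BLIMP1, BLIMP1->BCL6; multipliers {1, 10}
#' on IRF4->IRF4, BCR->BCL6, CD40->IRF4; thresholds {0.01, 0.1, 1} on the
#' five gene-gene edges and {0.0001, 0.001, 0.1, 1, 100} on IRF4->IRF4,
#' BCR->BCL6, CD40->IRF4 — 2^5 x 2^3 x 3^5 x 5^3 = 7,776,000 candidates.
#'
#' @param base base model (typically the initial parameter set, version I).
#' @return A [ParameterGrid-class].
#' @export
fullTuningGrid <- function(base) {
  five <- c("BCL6.BCL6", "BCL6.BLIMP1", "IRF4.BCL6", "IRF4.BLIMP1",
            "BLIMP1.BCL6")
  three <- c("IRF4.IRF4", "BCR.BCL6", "CD40.IRF4")
  thetaMult <- c(setNames(rep(list(c(1, 5)), length(five)), five),
                 setNames(rep(list(c(1, 10)), length(three)), three))
  Hcand <- c(setNames(rep(list(c(0.01, 0.1, 1)), length(five)), five),
             setNames(rep(list(c(1e-4, 1e-3, 0.1, 1, 100)), length(three)),
                      three))
  parameterGrid(base, thetaMultipliers = thetaMult, HCandidates = Hcand)
}

#' Seeded grid search against reference single-cell data
#'
#' For each candidate (all of them, or a seeded random subsample of the grid)
#' one dataset is simulated — a single replicate per candidate is justified
#' by the low model-to-model variability, see [mtmVariability()] — its
#' stage-gene means are computed on the comparison scale and the objective
#' [objectiveFunction()] is evaluated against the reference means. The
#' candidate with the smallest objective wins; ties break in enumeration
#' order. All candidate simulations use the seed of `protocol`, so the
#' search is reproducible end to end.
#'
#' @param grid a [ParameterGrid-class].
#' @param referenceData reference dataset (an [SCDataset()]), both stages and
#'   all genes present.
#' @param protocol a [SimulationProtocol-class] used for every candidate.
#' @param schedules stimulus schedules.
#' @param subsample optional number of candidates to draw (without
#'   replacement) from the grid.
#' @param subsampleSeed seed of the subsample draw.
#' @param maxExhaustive guard: an exhaustive run over a grid larger than this
#'   must be requested explicitly via `subsample = gridSize(grid)`.
#' @return A [FitResult-class].
#' @export
runGridSearch <- function(grid, referenceData, protocol,
                          schedules = defaultSchedules(), subsample = NULL,
                          subsampleSeed = 1L, maxExhaustive = 10000) {
  n <- gridSize(grid)
  refMeans <- comparisonMeans(referenceData)
  if (is.null(subsample)) {
    if (n > maxExhaustive)
      stop("grid has ", n, " candidates; pass 'subsample' (a seeded random ",
           "subsample, or gridSize(grid) for the full sweep)")
    idx <- seq_len(n)
  } else {
    if (subsample >= n) {
      idx <- seq_len(n)
    } else {
      old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      set.seed(subsampleSeed)
      idx <- sort(sample.int(n, subsample))
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    }
  }
  ofs <- numeric(length(idx))
  best <- NULL; bestOf <- Inf; bestIdx <- NA_integer_
  for (k in seq_along(idx)) {
    of <- tryCatch({
      cand <- gridCandidate(grid, idx[k])
      d <- simulateDataset(cand, schedules, protocol)
      objectiveFunction(comparisonMeans(d), refMeans)
    }, error = function(e) Inf)
    ofs[k] <- of
    if (of < bestOf) {
      bestOf <- of; bestIdx <- idx[k]
      best <- gridCandidate(grid, idx[k])
    }
  }
  if (is.null(best)) stop("no grid candidate could be evaluated")
  new("FitResult", model = best, of = bestOf, index = as.integer(bestIdx),
      seed = protocol@seed,
      ranking = data.frame(index = idx, of = ofs))
}

#' One-dimensional parameter sweep
#'
#' Perturbs a single parameter of the base model over an interval (linear or
#' log spacing; log spacing of a negative interval runs over the magnitudes,
#' keeping the sign), simulates one dataset per value and evaluates the
#' objective against the reference means.
#'
#' @param spec a [SweepSpec-class].
#' @param base base [NetworkModel-class].
#' @param referenceData reference dataset.
#' @param protocol a [SimulationProtocol-class].
#' @param schedules stimulus schedules.
#' @return data.frame with columns `value` and `of`, sorted by value.
#' @export
sweepParameter <- function(spec, base, referenceData, protocol,
                           schedules = defaultSchedules()) {
  stopifnot(is(spec, "SweepSpec"))
  validObject(spec)
  if (spec@lo == spec@hi) {
    values <- spec@lo
  } else if (spec@scale == "log") {
    sgn <- sign(spec@lo)
    mags <- sort(abs(c(spec@lo, spec@hi)))
    values <- sgn * exp(seq(log(mags[1L]), log(mags[2L]),
                            length.out = spec@points))
  } else {
    values <- seq(spec@lo, spec@hi, length.out = spec@points)
  }
  values <- sort(values)
  refMeans <- comparisonMeans(referenceData)
  ofs <- vapply(values, function(v) {
    tryCatch({
      m <- setParameterValue(base, spec@parameter, v)
      d <- simulateDataset(m, schedules, protocol)
      objectiveFunction(comparisonMeans(d), refMeans)
    }, error = function(e) Inf)
  }, numeric(1))
  data.frame(value = values, of = ofs)
}
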