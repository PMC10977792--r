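## Generator of experiment-like single-cell qPCR datasets: exact per-node
## dropout counts, truncated-normal positive Et values, and the Ct -> Et
## transform.

#' Expression threshold from a qPCR cycle threshold
#'
#' `Et = 30 - Ct`, clipped to zero for unreliably low or undetected
#' expression (`Ct > 30`). Vectorized.
#'
#' @param ct cycle-threshold value(s), `>= 0`.
#' @return Et value(s) in `[0, 30]`.
#' @examples
#' etFromCt(c(20, 30, 30.5))  # 10 0 0
#' @export
etFromCt <- function(ct) {
  if (any(!is.finite(ct)) || any(ct < 0))
    stop("'ct' must be finite and >= 0")
  pmax(30 - ct, 0)
}

#' Default stage profiles of the synthetic qPCR dataset
#'
#' Encodes the structure of the single-cell RT-qPCR reference data: a GC
#' stage of 317 cells with 30/292/292 zeros for BCL6/IRF4/BLIMP1 and a PB_PC
#' stage of 104 cells with 25/79/5 zeros, with positive Et values drawn from
#' a truncated normal on (0, 30]. The positive-value location/scale defaults
#' (`mu = 8`, `sd = 2.5` for every node) are synthetic placeholders — they
#' are not derived from the experimental data and only need to exercise the
#' pipeline with plausible bounded unimodal values.
#'
#' @param mu,sd positive-value truncated-normal parameters, recycled across
#'   genes and stages.
#' @return Named list of two [StageProfile-class] objects.
#' @export
defaultStageProfiles <- function(mu = 8, sd = 2.5) {
  genes <- grnGenes()
  muv <- setNames(rep_len(mu, 3L), genes)
  sdv <- setNames(rep_len(sd, 3L), genes)
  list(
    GC = stageProfile("GC", nCells = 317,
                      nZero = c(BCL6 = 30, IRF4 = 292, BLIMP1 = 292),
                      mu = muv, sd = sdv),
    PB_PC = stageProfile("PB_PC", nCells = 104,
                         nZero = c(BCL6 = 25, IRF4 = 79, BLIMP1 = 5),
                         mu = muv, sd = sdv)
  )
}

## truncated normal on (lo, hi] via inverse-CDF sampling
.rtruncnorm <- function(n, mu, sd, lo = 0, hi = 30) {
  u <- stats::runif(n, stats::pnorm(lo, mu, sd), stats::pnorm(hi, mu, sd))
  pmin(pmax(stats::qnorm(u, mu, sd), lo + 1e-12), hi)
}

#' Generate an experiment-like single-cell qPCR dataset
#'
#' For each stage and gene, exactly `nZero` cells receive an exact zero (the
#' zero set is an independently shuffled, seeded sample of cells per gene)
#' and the remaining cells draw positive Et values from the profile's
#' truncated normal on (0, 30]. Dropout counts are deterministic, not
#' Bernoulli draws, so the generated structure matches the profile exactly
#' on every run.
#'
#' @param profiles list of [StageProfile-class] (default:
#'   [defaultStageProfiles()]).
#' @param seed RNG seed.
#' @return An [SCDataset()] on the Et scale.
#' @examples
#' d <- generateExperimentalLike(seed = 1)
#' sum(exprValues(d, "IRF4", "GC") == 0)  # 292
#' @export
generateExperimentalLike <- function(profiles = defaultStageProfiles(),
                                     seed = 1) {
  set.seed(seed)
  blocks <- lapply(profiles, function(pf) {
    stopifnot(is(pf, "StageProfile"))
    validObject(pf)
    genes <- names(pf@nZero)
    vals <- matrix(NA_real_, nrow = pf@nCells, ncol = length(genes),
                   dimnames = list(NULL, genes))
    for (g in genes) {
      nz <- pf@nZero[[g]]
      v <- numeric(pf@nCells)
      npos <- pf@nCells - nz
      if (npos > 0)
        v[setdiff(seq_len(pf@nCells), sample.int(pf@nCells, nz))] <-
          .rtruncnorm(npos, pf@mu[[g]], pf@sd[[g]])
      vals[, g] <- v
    }
    list(values = vals, stage = rep(pf@stage, pf@nCells))
  })
  values <- do.call(rbind, lapply(blocks, `[[`, "values"))
  stage <- unlist(lapply(blocks, `[[`, "stage"), use.names = FALSE)
  SCDataset(values, stage = stage,
            cellId = sprintf("cell_%03d", seq_len(nrow(values))),
            scale = "Et")
}
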