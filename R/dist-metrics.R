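## Binned Kantorovich (1-Wasserstein) distance between expression samples,
## histogram construction on the log2(x + 1) scale, and the model-to-model
## variability study over replicate simulated datasets.

## bin two samples on one shared equal-width grid spanning the pooled range
.sharedBins <- function(a, b, nBins) {
  lo <- min(a, b); hi <- max(a, b)
  if (hi == lo) return(NULL)  # zero pooled range
  edges <- seq(lo, hi, length.out = nBins + 1L)
  binOf <- function(x) pmin(pmax(findInterval(x, edges, all.inside = TRUE),
                                 1L), nBins)
  p <- tabulate(binOf(a), nbins = nBins) / length(a)
  q <- tabulate(binOf(b), nbins = nBins) / length(b)
  list(edges = edges, p = p, q = q)
}

#' Kantorovich distance between two samples
#'
#' Bins both samples on a common equal-width grid spanning their pooled
#' range, then sums the absolute differences of the cumulative bin
#' probabilities: `KD = sum_n |CDF_p(n) - CDF_q(n)|`. This is the discrete
#' 1-Wasserstein distance in bin-width units: symmetric, nonnegative, zero
#' iff the binned distributions coincide, and satisfying the triangle
#' inequality on a fixed binning.
#'
#' @param a,b non-empty numeric samples.
#' @param nBins number of equal-width bins (default 30).
#' @return The distance (a nonnegative number; 0 by convention when the
#'   pooled range is a single point).
#' @examples
#' kantorovichDistance(c(0, 0, 0), c(1, 1, 1), nBins = 2)  # 1
#' @export
kantorovichDistance <- function(a, b, nBins = 30) {
  if (!length(a) || !length(b)) stop("samples must be non-empty")
  if (nBins < 2) stop("'nBins' must be >= 2")
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("samples must be finite")
  sb <- .sharedBins(a, b, nBins)
  if (is.null(sb)) return(0)
  sum(abs(cumsum(sb$p) - cumsum(sb$q)))
}

#' Relative-frequency histogram of one node on the log2(x + 1) scale
#'
#' Extracts the (gene, stage) slice of a dataset, transforms the values as
#' `log2(x + 1)` (molecule-scale data; other scales are binned as stored)
#' and bins them into equal-width bins spanning the observed range.
#'
#' @param dataset a dataset built by [SCDataset()].
#' @param gene gene name.
#' @param stage stage label.
#' @param nBins number of bins (default 30).
#' @return A [BinnedDistribution-class].
#' @export
histogramLog2p1 <- function(dataset, gene, stage, nBins = 30) {
  v <- exprValues(dataset, gene, stage)
  if (scaleTag(dataset) == "molecules") v <- log2(v + 1)
  lo <- min(v); hi <- max(v)
  if (hi == lo) hi <- lo + 1  # single occupied bin for degenerate slices
  edges <- seq(lo, hi, length.out = nBins + 1L)
  bins <- pmin(pmax(findInterval(v, edges, all.inside = TRUE), 1L), nBins)
  new("BinnedDistribution", edges = edges,
      prob = tabulate(bins, nbins = nBins) / length(v))
}

#' Model-to-model variability of the stochastic simulator
#'
#' Simulates `nDatasets` independent datasets from one parameter set (one
#' master seed per dataset, derived from `protocol@seed`) and computes the
#' Kantorovich distance for every unordered pair of datasets, separately per
#' gene and stage (six nodes), on the log2(x + 1) scale. The resulting
#' "model-to-model" distributions quantify how much the finite-cell
#' empirical distributions vary between runs, and justify single-replicate
#' evaluation in the grid search when they are narrow.
#'
#' @param model a calibrated [NetworkModel-class].
#' @param schedules stimulus schedules.
#' @param protocol a [SimulationProtocol-class]; `nCells` cells per dataset.
#' @param nDatasets number of replicate datasets (>= 2).
#' @param nBins bins of the distance (default 30).
#' @return A [KDResult-class].
#' @export
mtmVariability <- function(model, schedules = defaultSchedules(),
                           protocol = simulationProtocol(), nDatasets = 20,
                           nBins = 30) {
  if (nDatasets < 2) stop("'nDatasets' must be >= 2")
  dseeds <- .cellSeeds(protocol@seed, nDatasets)
  datasets <- vector("list", nDatasets)
  for (d in seq_len(nDatasets)) {
    pr <- protocol
    pr@seed <- dseeds[d]
    datasets[[d]] <- simulateDataset(model, schedules, pr)
  }
  ids <- vapply(model@genes, function(g) g@geneId, character(1))
  nodes <- expand.grid(gene = ids, stage = grnStages(),
                       stringsAsFactors = FALSE)
  prs <- utils::combn(nDatasets, 2)
  rows <- vector("list", nrow(nodes))
  for (k in seq_len(nrow(nodes))) {
    g <- nodes$gene[k]; s <- nodes$stage[k]
    vals <- lapply(datasets, function(d) log2(exprValues(d, g, s) + 1))
    kd <- unname(apply(prs, 2, function(ij)
      kantorovichDistance(vals[[ij[1L]]], vals[[ij[2L]]], nBins = nBins)))
    rows[[k]] <- data.frame(gene = g, stage = s, i = unname(prs[1L, ]),
                            j = unname(prs[2L, ]), kd = kd,
                            row.names = NULL)
  }
  pairs <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(rows, function(r) data.frame(
    gene = r$gene[1L], stage = r$stage[1L],
    median = stats::median(r$kd), iqr = stats::IQR(r$kd), nPairs = nrow(r))))
  new("KDResult", pairs = pairs, summary = summ,
      nDatasets = as.integer(nDatasets), nCells = protocol@nCells)
}
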