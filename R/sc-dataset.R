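## Stage-labelled single-cell expression container and its accessors.
## Datasets are SingleCellExperiment objects: one assay "expression"
## (genes x cells), a "stage" column, a "cell_id" column and a scale tag
## ("Et", "molecules" or "log2p1") in the metadata.

#' @importFrom SingleCellExperiment SingleCellExperiment
#' @importFrom SummarizedExperiment assay colData
#' @importFrom S4Vectors metadata metadata<- DataFrame
NULL

.validScales <- c("Et", "molecules", "log2p1")

#' Build a stage-labelled single-cell expression dataset
#'
#' The single-cell container of this package: a `SingleCellExperiment` with
#' one `expression` assay (genes in rows), per-cell `stage` and `cell_id`
#' columns and a scale tag (`"Et"`: expression threshold, 30 - Ct, bounded in
#' `[0, 30]`; `"molecules"`: mRNA molecule numbers; `"log2p1"`:
#' log2(x + 1)-transformed values).
#'
#' @param values cells x genes numeric matrix (column names = gene names).
#' @param stage character vector of stage labels (`"GC"`/`"PB_PC"`), one per
#'   row of `values`.
#' @param cellId optional cell identifiers (recycled labels are allowed:
#'   the same cell observed at two stages keeps one id).
#' @param scale one of `"Et"`, `"molecules"`, `"log2p1"`.
#' @return A `SingleCellExperiment`.
#' @examples
#' d <- SCDataset(matrix(1:6, 2, dimnames = list(NULL, c("A", "B", "C"))),
#'                stage = c("GC", "PB_PC"), scale = "molecules")
#' @export
SCDataset <- function(values, stage, cellId = NULL, scale = "molecules") {
  values <- as.matrix(values)
  if (is.null(colnames(values))) stop("'values' must have gene column names")
  scale <- match.arg(scale, .validScales)
  stage <- as.character(stage)
  if (length(stage) != nrow(values))
    stop("'stage' must have one label per cell row")
  bad <- setdiff(unique(stage), grnStages())
  if (length(bad)) stop("unknown stage label(s): ", paste(bad, collapse = ", "))
  if (any(!is.finite(values)) || any(values < 0))
    stop("expression values must be finite and >= 0")
  if (scale == "Et" && any(values > 30))
    stop("Et-scale values must not exceed 30")
  if (is.null(cellId)) cellId <- sprintf("cell_%03d", seq_len(nrow(values)))
  sce <- SingleCellExperiment(
    assays = list(expression = t(values)),
    colData = DataFrame(cell_id = as.character(cellId), stage = stage)
  )
  colnames(sce) <- make.unique(paste(cellId, stage, sep = "."))
  metadata(sce)$scale <- scale
  sce
}

#' Scale tag of a dataset
#' @param x a dataset built by [SCDataset()].
#' @return `"Et"`, `"molecules"` or `"log2p1"`.
#' @export
scaleTag <- function(x) {
  sc <- metadata(x)$scale
  if (is.null(sc)) stop("dataset carries no scale tag")
  sc
}

#' Stage labels of a dataset
#' @param x a dataset built by [SCDataset()].
#' @return Character vector, one label per cell column.
#' @export
stageLabels <- function(x) as.character(colData(x)$stage)

#' Expression values of one (gene, stage) node
#'
#' @param x a dataset built by [SCDataset()].
#' @param gene gene name.
#' @param stage stage label; `NULL` returns all cells.
#' @return Numeric vector of expression values.
#' @export
exprValues <- function(x, gene, stage = NULL) {
  a <- assay(x, "expression")
  if (!gene %in% rownames(a)) stop("gene not in dataset: ", gene)
  keep <- if (is.null(stage)) rep(TRUE, ncol(a)) else stageLabels(x) == stage
  if (!any(keep)) stop("no cells with stage: ", stage)
  unname(a[gene, keep])
}

#' Per-node mean expression of a dataset
#'
#' Arithmetic mean (zeros included) per (gene, stage) node, on the dataset's
#' own scale.
#'
#' @param x a dataset built by [SCDataset()].
#' @return data.frame with columns `gene`, `stage`, `mean`.
#' @export
datasetMeans <- function(x) {
  a <- assay(x, "expression")
  st <- stageLabels(x)
  stages <- unique(st)
  out <- expand.grid(gene = rownames(a), stage = stages,
                     stringsAsFactors = FALSE)
  out$mean <- mapply(function(g, s) {
    v <- a[g, st == s]
    if (!length(v)) stop("empty (gene, stage) node: ", g, "/", s)
    mean(v)
  }, out$gene, out$stage)
  out
}

#' Means on the distribution-comparison scale
#'
#' Means used by the fitting objective: molecule-scale model output is
#' compared on the log2(x + 1) scale, while Et-scale (and already
#' transformed) data enter on their native scale, treated as directly
#' comparable.
#'
#' @param x a dataset built by [SCDataset()].
#' @return data.frame as [datasetMeans()], on the comparison scale.
#' @export
comparisonMeans <- function(x) {
  if (scaleTag(x) == "molecules") {
    a <- log2(assay(x, "expression") + 1)
    st <- stageLabels(x)
    out <- expand.grid(gene = rownames(a), stage = unique(st),
                       stringsAsFactors = FALSE)
    out$mean <- mapply(function(g, s) mean(a[g, st == s]), out$gene, out$stage)
    out
  } else {
    datasetMeans(x)
  }
}
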