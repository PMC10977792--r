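## Parameter-set fixtures (YAML), generic config loading and the CSV dialect
## of the single-cell datasets.

#' Load a network model from a parameter config file
#'
#' Reads a YAML (or JSON) parameter set with the layout of the shipped
#' fixtures: a `genes` map (per-gene kinetic constants and switching-rate
#' settings), flat `theta` and `H` edge maps keyed `"REGULATOR.TARGET"`, and
#' `gamma`. Keys use gene names; the fixed model order (BCL6, IRF4, BLIMP1)
#' is applied on load. The returned model is calibrated.
#'
#' @param path file path.
#' @param anchor calibration mode passed to [calibrateModel()].
#' @return A calibrated [NetworkModel-class].
#' @export
loadParameterConfig <- function(path, anchor = c("initState", "none")) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  for (k in c("genes", "theta", "H"))
    if (is.null(cfg[[k]]))
      stop("fixture integrity failure: config lacks required key '", k, "'")
  genes <- lapply(grnGenes(), function(id) {
    gc <- cfg$genes[[id]]
    if (is.null(gc))
      stop("fixture integrity failure: no parameters for gene ", id)
    need <- c("s0", "d0", "s1", "d1", "konInit", "koffInit")
    miss <- setdiff(need, names(gc))
    if (length(miss))
      stop("fixture integrity failure: gene ", id, " lacks ",
           paste(miss, collapse = ", "))
    geneParameters(id, s0 = gc$s0, d0 = gc$d0, s1 = gc$s1, d1 = gc$d1,
                   konInit = gc$konInit, koffInit = gc$koffInit,
                   konMin = gc$konMin %||% 0.001,
                   konMax = gc$konMax %||% 2,
                   koffMin = gc$koffMin %||% 0.01,
                   koffMax = gc$koffMax %||% 10)
  })
  ip <- grnInteractionParams(theta = unlist(cfg$theta), H = unlist(cfg$H),
                             gamma = cfg$gamma %||% 2)
  calibrateModel(networkModel(genes, ip), anchor = match.arg(anchor))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load one of the shipped parameter versions
#'
#' The three published parameter sets of the stochastic model: version I
#' (initial set), version II (selected by the automatized grid search) and
#' version III (after semi-manual tuning), shipped as YAML fixtures.
#'
#' @param tag `"I"`, `"II"` or `"III"`.
#' @param anchor calibration mode passed to [calibrateModel()].
#' @return A calibrated [NetworkModel-class].
#' @examples
#' m <- loadParameterVersion("III")
#' m@interactions@theta["IRF4", "IRF4"]  # 11
#' @export
loadParameterVersion <- function(tag, anchor = c("initState", "none")) {
  if (!is.character(tag) || length(tag) != 1L || !tag %in% c("I", "II", "III"))
    stop("unknown parameter version tag: ", paste(tag, collapse = ", "),
         " (expected \"I\", \"II\" or \"III\")")
  path <- system.file("extdata", paste0("version_", tag, ".yaml"),
                      package = "gcbnet", mustWork = TRUE)
  loadParameterConfig(path, anchor = match.arg(anchor))
}

#' Write a single-cell dataset as CSV
#'
#' One row per cell and stage, columns `cell_id`, `stage`, then the genes;
#' the scale tag is kept in a leading `# scale:` comment line.
#'
#' @param x a dataset built by [SCDataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSCDataset <- function(x, path) {
  a <- assay(x, "expression")
  df <- data.frame(cell_id = colData(x)$cell_id, stage = stageLabels(x),
                   t(a), check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# scale: ", scaleTag(x)), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a single-cell dataset from CSV
#'
#' Inverse of [writeSCDataset()]; `read` after `write` reproduces values,
#' stage labels and the scale tag. Parse problems (missing columns, unknown
#' stage labels, negative or out-of-range values) are reported with the
#' offending line number.
#'
#' @param path CSV file path.
#' @return An [SCDataset()].
#' @export
readSCDataset <- function(path) {
  if (!file.exists(path)) stop("dataset file not found: ", path)
  lines <- readLines(path)
  scale <- "molecules"
  hdrLine <- 1L
  if (length(lines) && grepl("^#", lines[1L])) {
    m <- regmatches(lines[1L], regexec("^#\\s*scale:\\s*(\\S+)", lines[1L]))[[1L]]
    if (length(m) == 2L) {
      if (!m[2L] %in% .validScales)
        stop("line 1: unknown scale tag '", m[2L], "'")
      scale <- m[2L]
    }
    hdrLine <- 2L
  }
  df <- tryCatch(
    utils::read.csv(text = lines[hdrLine:length(lines)],
                    stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop("line ", hdrLine, ": malformed CSV header (",
                             conditionMessage(e), ")"))
  need <- c("cell_id", "stage")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("line ", hdrLine, ": missing column(s) ",
         paste(miss, collapse = ", "))
  geneCols <- setdiff(names(df), need)
  if (!length(geneCols)) stop("line ", hdrLine, ": no gene columns")
  lineOf <- function(i) hdrLine + i  # data row i sits on this file line
  badStage <- which(!df$stage %in% grnStages())
  if (length(badStage))
    stop("line ", lineOf(badStage[1L]), ": unknown stage '",
         df$stage[badStage[1L]], "'")
  vals <- as.matrix(df[, geneCols, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(!vapply(df[geneCols], is.numeric, logical(1)))[1L]
    stop("line ", hdrLine, ": non-numeric expression column '",
         geneCols[bad], "'")
  }
  badNeg <- which(apply(vals < 0 | !is.finite(vals), 1L, any))
  if (length(badNeg))
    stop("line ", lineOf(badNeg[1L]), ": negative or non-finite expression ",
         "value")
  if (scale == "Et") {
    badEt <- which(apply(vals > 30, 1L, any))
    if (length(badEt))
      stop("line ", lineOf(badEt[1L]), ": Et-scale value exceeds 30")
  }
  SCDataset(vals, stage = df$stage, cellId = df$cell_id, scale = scale)
}
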