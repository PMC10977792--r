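## show() methods for the S4 containers

setMethod("show", "GeneParameters", function(object) {
  cat("GeneParameters:", object@geneId, "\n")
  cat(sprintf("  s0 = %g mRNA/h, d0 = %g /h, s1 = %g /mRNA/h, d1 = %g /h\n",
              object@s0, object@d0, object@s1, object@d1))
  cat(sprintf("  kon: init %g in [%g, %g + %g); koff: init %g in [%g, %g + %g)\n",
              object@konInit, object@konMin, object@konMin, object@konMax,
              object@koffInit, object@koffMin, object@koffMin, object@koffMax))
  if (is.na(object@betaOn)) {
    cat("  uncalibrated (betaOn/betaOff not set)\n")
  } else {
    cat(sprintf("  betaOn = %.4g, betaOff = %.4g (phiRef %.4g / %.4g)\n",
                object@betaOn, object@betaOff, object@phiRefOn,
                object@phiRefOff))
  }
})

setMethod("show", "InteractionParams", function(object) {
  cat("InteractionParams:", nrow(object@theta), "regulators x",
      ncol(object@theta), "targets, gamma =", object@gamma, "\n")
  cat("theta:\n"); print(object@theta)
})

setMethod("show", "NetworkModel", function(object) {
  ids <- vapply(object@genes, function(g) g@geneId, character(1))
  cat("NetworkModel:", paste(ids, collapse = ", "),
      if (isCalibrated(object)) "(calibrated)" else "(uncalibrated)", "\n")
})

setMethod("show", "StimulusSchedule", function(object) {
  cat(sprintf(
    "StimulusSchedule %s: ramp [%g, %g] h, plateau to %g h, off at %g h, amplitude %g\n",
    object@stimulusId, object@rampUpStart, object@rampUpEnd,
    object@plateauEnd, object@rampDownEnd, object@amplitude))
})

setMethod("show", "SimulationProtocol", function(object) {
  cat(sprintf(
    "SimulationProtocol: burn-in %g h, post-stimulus %g h, dt %g h, sample every %g h, %d cells, seed %d\n",
    object@burnIn, object@postStimulus, object@dt, object@sampleEvery,
    object@nCells, object@seed))
})

setMethod("show", "SteadyStateReport", function(object) {
  cat("SteadyStateReport:",
      if (object@bistable) "bistable" else "monostable",
      if (!object@converged) "(relaxation did not converge)", "\n")
  m <- rbind(`pre-stimulus M` = object@preM, `post-stimulus M` = object@postM)
  print(signif(m, 4))
  cat(sprintf("  residuals: pre %.3g, post %.3g; stable: pre %s, post %s\n",
              object@preResidual, object@postResidual,
              object@preStable, object@postStable))
})

setMethod("show", "ParameterGrid", function(object) {
  cat("ParameterGrid:", length(object@thetaMultipliers), "theta axes,",
      length(object@HCandidates), "H axes,", format(gridSize(object)),
      "candidates\n")
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult: best OF = %.4g at grid index %d (%d evaluated, seed %d)\n",
              object@of, object@index, nrow(object@ranking), object@seed))
})

setMethod("show", "BinnedDistribution", function(object) {
  cat(sprintf("BinnedDistribution: %d bins on [%g, %g]\n",
              length(object@prob), min(object@edges), max(object@edges)))
})

setMethod("show", "KDResult", function(object) {
  cat(sprintf("KDResult: %d datasets x %d cells, %d pairs per node\n",
              object@nDatasets, object@nCells, object@summary$nPairs[1L]))
  print(object@summary)
})

setMethod("show", "StageProfile", function(object) {
  cat(sprintf("StageProfile %s: %d cells; zeros: %s\n", object@stage,
              object@nCells,
              paste(names(object@nZero), object@nZero, sep = "=",
                    collapse = ", ")))
})
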