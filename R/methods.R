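#' @rdname accessors
#' @aliases rateConstant,ExponentialFit-method
setMethod("rateConstant", "ExponentialFit", function(x) x@k)

#' @rdname accessors
setMethod("rateConstant", "RateEstimate", function(x) x@k)

#' @rdname accessors
setMethod("rateConstant", "PermeabilityEstimate", function(x) x@k)

#' @rdname accessors
setMethod("waterPermeability", "PermeabilityEstimate", function(x) x@Pf)

#' @rdname accessors
setMethod("activationEnergy", "ArrheniusEstimate", function(x) x@Ea)

#' @rdname accessors
setMethod("rSquared", "ArrheniusEstimate", function(x) x@rSquared)

#' @rdname accessors
setMethod("rSquared", "RateEstimate", function(x) x@rSquared)

#' @rdname accessors
setMethod("rSquared", "StandardCurve", function(x) x@rSquared)

#' @rdname accessors
setMethod("groundTruth", "ShrinkageTrace", function(x) x@groundTruth)

#' @rdname accessors
setMethod("groundTruth", "DecayTrace", function(x) x@groundTruth)

#' @rdname accessors
setMethod("traceTimes", "ShrinkageTrace", function(x) x@times)

#' @rdname accessors
setMethod("traceTimes", "DecayTrace", function(x) x@times)

#' @rdname accessors
setMethod("traceValues", "ShrinkageTrace", function(x) x@fluorescence)

#' @rdname accessors
setMethod("traceValues", "DecayTrace", function(x) x@values)

#' @rdname accessors
setMethod("conditionLabels", "ShrinkageTrace", function(x) x@condition)

#' @rdname accessors
setMethod("conditionLabels", "DecayTrace", function(x) x@condition)

#' @rdname accessors
setMethod("conditionLabels", "PermeabilityEstimate",
          function(x) x@condition)

#' @rdname asTidy
setMethod("asTidy", "PermeabilityEstimate", function(x, ...) {
  out <- data.frame(Pf = x@Pf, k = x@k, dEq = x@geometry@dEq,
                    osmOut = x@osmOut, temperature = x@temperature)
  for (nm in names(x@condition)) out[[nm]] <- x@condition[[nm]]
  out
})

#' @rdname asTidy
setMethod("asTidy", "MembraneExpression", function(x, ...) x@perLine)

#' @rdname asTidy
setMethod("asTidy", "RateEstimate", function(x, ...)
  data.frame(k = x@k, rSquared = x@rSquared, nPoints = x@nPoints,
             mode = x@mode, nBelowFloor = x@nBelowFloor))

setMethod("show", "ShrinkageTrace", function(object) {
  cat("ShrinkageTrace:", length(object@times), "samples,",
      sprintf("t = [%.4g, %.4g] s,", object@times[1],
              object@times[length(object@times)]),
      sprintf("T = %.2f K\n", object@temperature))
  if (length(object@condition))
    cat("  condition:",
        paste(names(object@condition), unlist(object@condition),
              sep = "=", collapse = ", "), "\n")
  if (length(object@groundTruth))
    cat("  synthetic (ground truth attached)\n")
})

setMethod("show", "DecayTrace", function(object) {
  cat(sprintf("DecayTrace (%s mode): %d samples, C0 nominal %.4g uM\n",
              object@mode, length(object@times), object@C0Nominal))
  if (object@nClipped > 0L)
    cat("  ", object@nClipped, "sample(s) clipped at the floor\n")
})

setMethod("show", "ExponentialFit", function(object) {
  cat(sprintf(
    "ExponentialFit: k = %.6g 1/s, F0 = %.4g, Finf = %.4g (n = %d%s)\n",
    object@k, object@F0, object@Finf, object@nPoints,
    if (object@converged) ", converged" else ", NOT converged"))
})

setMethod("show", "PermeabilityEstimate", function(object) {
  cat(sprintf(
    "PermeabilityEstimate: Pf = %.4g cm/s (k = %.4g 1/s, dEq = %.3g um, osm_out = %.3g osmol/L)\n",
    object@Pf, object@k, object@geometry@dEq, object@osmOut))
})

setMethod("show", "ArrheniusEstimate", function(object) {
  cat(sprintf(
    "ArrheniusEstimate: Ea = %.4g kcal/mol (slope %.6g K, n = %d, r2 = %s)\n",
    object@Ea, object@slope, object@nTemperatures,
    ifelse(is.na(object@rSquared), "NA",
           sprintf("%.4f", object@rSquared))))
})

setMethod("show", "RateEstimate", function(object) {
  cat(sprintf(
    "RateEstimate (%s mode): k = %.6g 1/s (n = %d, r2 = %.4f, %d below floor)\n",
    object@mode, object@k, object@nPoints, object@rSquared,
    object@nBelowFloor))
})

setMethod("show", "MembraneExpression", function(object) {
  cat(sprintf(
    "MembraneExpression: cohort %.3f +/- %s over %d cells (%d lines)\n",
    object@cohortMean,
    ifelse(is.na(object@cohortSd), "NA", sprintf("%.3f", object@cohortSd)),
    object@nCells, nrow(object@perLine)))
})

setMethod("show", "StandardCurve", function(object) {
  cat(sprintf(
    "StandardCurve (%s): reading = %.4g x conc + %.4g (r2 = %.4f, n = %d, range [%.3g, %.3g])\n",
    object@assay, object@slope, object@intercept, object@rSquared,
    object@nStandards, object@range[1], object@range[2]))
})

setMethod("show", "CatalaseResult", function(object) {
  cat(sprintf(
    "CatalaseResult: %.4g U/mg (%.4g umol H2O2 in %.3g min, %.3g mg protein)\n",
    object@UPerMg, object@consumedUmol, object@reactionTime,
    object@proteinMg))
})

setMethod("show", "GshResult", function(object) {
  cat(sprintf("GshResult: %.4g %s%s\n", object@perMgProtein,
              object@unitLabel,
              if (object@extrapolated) " [extrapolated]" else ""))
})

setMethod("show", "TestResult", function(object) {
  cat(sprintf("%s (%s vs %s): statistic = %.4g, p = %.4g %s\n",
              object@method, object@groups[1],
              object@groups[min(2, length(object@groups))],
              object@statistic, object@pValue, object@stars))
})
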