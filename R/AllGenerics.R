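#' Accessor generics
#'
#' Small family of read-only accessors for the pipeline's S4 containers.
#' `rateConstant()` returns the exponential or first-order rate constant k in
#' s^-1; `waterPermeability()` the Pf coefficient in cm s^-1;
#' `activationEnergy()` the Arrhenius Ea in kcal mol^-1; `rSquared()` the
#' coefficient of determination of the underlying regression;
#' `groundTruth()` the generative parameters attached by the synthetic-data
#' module (an empty list for real data); `traceTimes()` / `traceValues()`
#' the raw coordinates of a trace; `conditionLabels()` the named list of
#' experimental labels.
#'
#' @param x an object of one of the pipeline classes.
#' @return see Description; scalar numeric unless stated otherwise.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("rateConstant", function(x) standardGeneric("rateConstant"))

#' @rdname accessors
#' @export
setGeneric("waterPermeability",
           function(x) standardGeneric("waterPermeability"))

#' @rdname accessors
#' @export
setGeneric("activationEnergy",
           function(x) standardGeneric("activationEnergy"))

#' @rdname accessors
#' @export
setGeneric("rSquared", function(x) standardGeneric("rSquared"))

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname accessors
#' @export
setGeneric("traceTimes", function(x) standardGeneric("traceTimes"))

#' @rdname accessors
#' @export
setGeneric("traceValues", function(x) standardGeneric("traceValues"))

#' @rdname accessors
#' @export
setGeneric("conditionLabels",
           function(x) standardGeneric("conditionLabels"))

#' Inverse prediction from a standard curve
#'
#' Maps a readout back to a concentration through the fitted line,
#' `conc = (reading - intercept)/slope`.  Readings whose predicted
#' concentration falls outside the standard range extended by 10% of its span
#' are flagged as extrapolated (attribute `extrapolated`, plus a warning).
#'
#' @param object a [StandardCurve-class].
#' @param reading numeric vector of readings.
#' @param ... unused.
#' @return numeric vector of concentrations with logical attribute
#'   `extrapolated`.
#' @export
setGeneric("inversePredict",
           function(object, reading, ...) standardGeneric("inversePredict"))

#' Tidy data.frame views of pipeline objects
#'
#' @param x a pipeline object.
#' @param ... unused.
#' @return a base `data.frame`, one row per atomic result.
#' @export
setGeneric("asTidy", function(x, ...) standardGeneric("asTidy"))
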