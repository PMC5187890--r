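#' Fit a linear standard curve
#'
#' Ordinary least squares of `reading` on `concentration` over the standard
#' wells.  Replicate concentrations are allowed; at least three distinct
#' concentrations are required and a slope indistinguishable from zero makes
#' the curve unusable for inverse prediction.
#'
#' @param standards data.frame with columns `concentration` and `reading`
#'   (rows with `role` other than `"standard"` are ignored when a `role`
#'   column is present).
#' @param assay assay identifier stored on the curve.
#' @param slopeTol minimal usable `|slope|`.
#' @return a [StandardCurve-class].
#' @examples
#' fitStandardCurve(data.frame(concentration = c(0, 10, 20),
#'                             reading = c(0, 1, 2)))
#' @export
fitStandardCurve <- function(standards, assay = "generic",
                             slopeTol = 1e-10) {
  if ("role" %in% names(standards))
    standards <- standards[standards$role == "standard", , drop = FALSE]
  conc <- standards$concentration
  reading <- standards$reading
  if (length(unique(conc)) < 3L)
    stop("need >= 3 distinct standard concentrations")
  fit <- stats::lm(reading ~ conc)
  slope <- stats::coef(fit)[[2]]
  if (abs(slope) < slopeTol)
    stop("unusable curve: |slope| below tolerance")
  r2 <- rSquaredOf(fit)
  new("StandardCurve", slope = slope, intercept = stats::coef(fit)[[1]],
      rSquared = r2, range = range(conc), assay = assay,
      nStandards = length(conc))
}

#' @rdname inversePredict
#' @export
setMethod("inversePredict", "StandardCurve", function(object, reading, ...) {
  conc <- (reading - object@intercept) / object@slope
  span <- diff(object@range)
  lo <- object@range[1] - 0.1 * span
  hi <- object@range[2] + 0.1 * span
  extrap <- conc < lo | conc > hi
  if (any(extrap))
    warning(sum(extrap),
            " reading(s) outside 1.1x the standard range (extrapolated)")
  attr(conc, "extrapolated") <- extrap
  conc
})

#' Catalase activity by the endpoint molybdate assay
#'
#' The remaining H2O2 after the stopped reaction is interpolated from the
#' standard curve; consumption over the reaction window gives the activity.
#' One unit (U) degrades 1 µmol H2O2 per minute, and the result is
#' normalised per mg of lysate protein:
#' `consumed_umol = (C_initial - C_remaining) * assayVolume_mL` (mM x mL =
#' µmol), `U = consumed_umol / reactionTime`, `U/mg = U / protein_mg`.
#'
#' @param curve a [StandardCurve-class] mapping H2O2 (mM) to readings.
#' @param readingT5 reading of the stopped reaction, a.u.
#' @param CInitial starting H2O2, mM.
#' @param assayVolumeML effective reaction volume, mL.
#' @param reactionTimeMin reaction time, min.
#' @param proteinMg mg protein in the assayed supernatant (> 0).
#' @return a [CatalaseResult-class].
#' @examples
#' curve <- fitStandardCurve(data.frame(concentration = seq(0, 75, 15),
#'                                      reading = 1 - 0.01 * seq(0, 75, 15)))
#' catalaseActivity(curve, readingT5 = 1 - 0.01 * 32.5, proteinMg = 1)
#' @export
catalaseActivity <- function(curve, readingT5, CInitial = 65,
                             assayVolumeML = 0.1, reactionTimeMin = 5,
                             proteinMg) {
  if (proteinMg <= 0) stop("proteinMg must be > 0")
  remaining <- as.numeric(inversePredict(curve, readingT5))
  if (remaining > CInitial * (1 + 1e-9))
    stop("negative consumption: interpolated remaining H2O2 (",
         format(remaining), " mM) exceeds the initial ", CInitial, " mM")
  consumed <- max(CInitial - remaining, 0) * assayVolumeML
  U <- consumed / reactionTimeMin
  new("CatalaseResult", UPerMg = U / proteinMg, consumedUmol = consumed,
      concRemaining = remaining, reactionTime = reactionTimeMin,
      proteinMg = proteinMg)
}

#' Total glutathione level from the recycling assay
#'
#' Inverse prediction from the GSH standard curve, scaled by the sample
#' dilution and normalised per mg protein.  The concentration unit label is
#' carried verbatim from the configuration (no unit conversion is applied).
#'
#' @param curve a [StandardCurve-class].
#' @param reading sample reading, a.u.
#' @param dilutionFactor applied sample dilution.
#' @param proteinMg mg protein.
#' @param unitLabel unit string attached to the result.
#' @return a [GshResult-class]; extrapolated readings are flagged.
#' @export
gshLevel <- function(curve, reading, dilutionFactor = 1, proteinMg = 1,
                     unitLabel = "uM GSH per mg protein") {
  if (proteinMg <= 0) stop("proteinMg must be > 0")
  conc <- inversePredict(curve, reading)
  raw <- as.numeric(conc) * dilutionFactor
  # zero readings on near-zero-intercept curves can land at -eps
  if (raw < 0 && abs(raw) < 1e-8 * max(diff(curve@range), 1)) raw <- 0
  new("GshResult", perMgProtein = raw / proteinMg, rawConcentration = raw,
      dilutionFactor = dilutionFactor, proteinMg = proteinMg,
      unitLabel = unitLabel,
      extrapolated = any(attr(conc, "extrapolated")))
}

#' Fold-change series of a DCF fluorescence time course
#'
#' `fold(t) = F(t)/F(0)` where `F(0)` is the pre-treatment baseline (the
#' first sample).  Readings are background-uncorrected by default; an
#' optional blank is subtracted before the fold is taken.
#'
#' @param times min, starting at the baseline measurement.
#' @param fluorescence a.u.
#' @param blank optional matched-length blank readings subtracted first.
#' @return a [RosTimeCourse-class].
#' @examples
#' rosFoldChange(seq(0, 60, 10), c(100, 120, 150, 180, 210, 235, 250))
#' @export
rosFoldChange <- function(times, fluorescence, blank = NULL) {
  if (!is.null(blank)) fluorescence <- fluorescence - blank
  if (length(times) != length(fluorescence))
    stop("times and fluorescence must have equal length")
  if (fluorescence[1] <= 0) stop("baseline fluorescence must be > 0")
  new("RosTimeCourse", times = times, fluorescence = fluorescence,
      fold = fluorescence / fluorescence[1])
}

#' Per-time comparison of two groups of ROS time courses
#'
#' Runs an unpaired t-test on the fold changes of the two groups at every
#' shared time point (the per-time inputs of the comparison layer).
#'
#' @param groupA,groupB lists of [RosTimeCourse-class] objects sampled on
#'   the same time base.
#' @param labels group names.
#' @param equalVariance passed to [unpairedTTest()].
#' @return data.frame with columns `time`, `meanFoldA`, `meanFoldB`,
#'   `pValue`, `stars` (baseline row has NA p-value: folds are identically
#'   1 there).
#' @export
compareRosGroups <- function(groupA, groupB, labels = c("A", "B"),
                             equalVariance = TRUE) {
  times <- groupA[[1]]@times
  foldMat <- function(g) do.call(rbind, lapply(g, function(x) {
    stopifnot(identical(x@times, times))
    x@fold
  }))
  fa <- foldMat(groupA)
  fb <- foldMat(groupB)
  out <- do.call(rbind, lapply(seq_along(times), function(i) {
    a <- fa[, i]; b <- fb[, i]
    if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b)) {
      p <- NA_real_; st <- "ns"
    } else {
      tt <- unpairedTTest(a, b, equalVariance = equalVariance,
                          labels = labels)
      p <- tt@pValue; st <- tt@stars
    }
    data.frame(time = times[i], meanFoldA = mean(a), meanFoldB = mean(b),
               pValue = p, stars = st)
  }))
  rownames(out) <- NULL
  out
}
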