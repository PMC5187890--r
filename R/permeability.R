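#' Equivalent-sphere geometry from measured cell dimensions
#'
#' The cell is assumed spherical with diameter the average of its maximum
#' and minimum measured dimensions; volume, area and the volume-to-area
#' ratio `V0/A = dEq/6` are converted to cgs.
#'
#' @param dMax,dMin measured dimensions, micrometres (`dMax >= dMin > 0`).
#' @return a [CellGeometry-class].
#' @examples
#' computeGeometry(6, 4)  # dEq = 5 um, V0/A = 8.333e-5 cm
#' @export
computeGeometry <- function(dMax, dMin = dMax) {
  if (dMin <= 0 || dMax < dMin)
    stop("need dMax >= dMin > 0 (micrometres)")
  dEq <- (dMax + dMin) / 2
  dcm <- dEq * 1e-4
  new("CellGeometry", dMax = dMax, dMin = dMin, dEq = dEq,
      V0 = pi * dcm^3 / 6, A = pi * dcm^2, V0OverA = dcm / 6)
}

#' Fit a single exponential to a stopped-flow shrinkage trace
#'
#' Least-squares fit of `F(t) = Finf + (F0 - Finf) exp(-k t)` by
#' Levenberg-Marquardt, with starting values from a log-linearisation of
#' `F - Finf0` (plateau guessed from the trace tail) and bounded restarts
#' over a ladder of initial rates if the first attempt fails.
#'
#' @param trace a [ShrinkageTrace-class].
#' @param fitWindow optional `c(tStart, tEnd)` in seconds restricting the
#'   fitted points; default uses every post-dead-time sample.
#' @return an [ExponentialFit-class].
#' @examples
#' tr <- simulateShrinkageTrace(simCellSpec(Pf = 4.94e-3),
#'                              instrumentSpec(noiseSd = 0))
#' fitSingleExponential(tr)
#' @export
fitSingleExponential <- function(trace, fitWindow = NULL) {
  stopifnot(is(trace, "ShrinkageTrace"))
  t <- trace@times
  f <- trace@fluorescence
  if (!is.null(fitWindow)) {
    keep <- t >= fitWindow[1] & t <= fitWindow[2]
    t <- t[keep]; f <- f[keep]
  }
  if (length(t) < 5L)
    stop("need >= 5 points after dead-time and window trimming")
  if (stats::sd(f) == 0)
    stop("degenerate fit: signal is constant")
  t0 <- t[1]
  ts <- t - t0  # shift so amplitude is estimated at the first kept sample

  ## starting values from the tail plateau and a log-linear slope
  nTail <- max(5L, ceiling(length(f) * 0.1))
  finf0 <- mean(utils::tail(f, nTail))
  a0 <- f[1] - finf0
  if (abs(a0) < .Machine$double.eps) a0 <- f[1] - mean(f)
  resid0 <- (f - finf0) / a0
  use <- which(resid0 > 0.05)
  k0 <- if (length(use) >= 2L) {
    sl <- stats::coef(stats::lm(log(resid0[use]) ~ ts[use]))[2]
    max(abs(sl), 1e-6)
  } else 1 / max(ts[length(ts)] / 3, 1e-6)

  fitOne <- function(kStart) {
    tryCatch(
      minpack.lm::nlsLM(
        f ~ Finf + A * exp(-k * ts),
        start = list(Finf = finf0, A = a0, k = kStart),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  }
  fit <- NULL
  for (mult in c(1, 0.1, 10, 0.01, 100)) {
    fit <- fitOne(k0 * mult)
    if (!is.null(fit) && stats::coef(fit)[["k"]] > 0) break
    fit <- NULL
  }
  if (is.null(fit))
    stop("single-exponential fit did not converge (k0 = ",
         format(k0), ", n = ", length(ts), ")")

  cf <- stats::coef(fit)
  ## map amplitude back to absolute t = 0
  a_t0 <- cf[["A"]] * exp(cf[["k"]] * t0)
  new("ExponentialFit", k = cf[["k"]], F0 = cf[["Finf"]] + a_t0,
      Finf = cf[["Finf"]],
      residualSse = sum(stats::resid(fit)^2),
      nPoints = length(ts), converged = TRUE)
}

#' Convert a fitted rate constant to an osmotic water permeability
#'
#' `Pf = k (V0/A) / (Vw osm_out)` with the external osmolarity converted
#' from osmol L^-1 to mol cm^-3 (x 1e-3), giving Pf in cm s^-1.
#'
#' @param fit an [ExponentialFit-class].
#' @param geometry a [CellGeometry-class].
#' @param osmOut final external osmolarity after the shock, osmol L^-1.
#' @param constants a [PhysicalConstants-class].
#' @param temperature K.
#' @param condition named list of labels carried into the estimate.
#' @return a [PermeabilityEstimate-class].
#' @examples
#' fit <- new("ExponentialFit", k = 1, F0 = 1, Finf = 0.8,
#'            residualSse = 0, nPoints = 100L, converged = TRUE)
#' computePf(fit, computeGeometry(5), osmOut = 1.75)  # 2.638e-3 cm/s
#' @export
computePf <- function(fit, geometry, osmOut,
                      constants = physicalConstants(),
                      temperature = 296.15, condition = list()) {
  stopifnot(is(fit, "ExponentialFit"))
  if (missing(geometry) || !is(geometry, "CellGeometry"))
    stop("a CellGeometry is required")
  if (osmOut <= 0) stop("osmOut must be > 0")
  Pf <- fit@k * geometry@V0OverA / (constants@Vw * osmOut * 1e-3)
  new("PermeabilityEstimate", Pf = Pf, k = fit@k, geometry = geometry,
      osmOut = osmOut, temperature = temperature, constants = constants,
      condition = condition)
}

#' Arrhenius activation energy from a table of Pf versus temperature
#'
#' Ordinary least squares of `ln Pf` on `1/T`; the activation energy is the
#' negated slope multiplied by the gas constant.  Temperatures are expected
#' in Kelvin; Celsius inputs must be declared explicitly with
#' `unit = "C"`, and Kelvin-labelled values below 200 raise an error since
#' they are almost certainly Celsius passed by mistake.
#'
#' @param data data.frame with columns `temperatureK` (or `temperatureC`
#'   with `unit = "C"`) and `Pf` (cm s^-1, all positive).
#' @param constants a [PhysicalConstants-class].
#' @param unit `"K"` (default) or `"C"`.
#' @return an [ArrheniusEstimate-class]; `rSquared` is NA with fewer than 3
#'   temperatures.
#' @examples
#' arr <- generateArrheniusSeries(6.52, 4.94e-3, 296.15,
#'                                c(282.15, 289.15, 296.15, 307.15))
#' fitArrhenius(arr)
#' @export
fitArrhenius <- function(data, constants = physicalConstants(),
                         unit = c("K", "C")) {
  unit <- match.arg(unit)
  tcol <- intersect(c("temperatureK", "temperatureC", "temperature"),
                    names(data))[1]
  if (is.na(tcol)) stop("no temperature column found")
  temp <- data[[tcol]]
  if (unit == "C") temp <- temp + 273.15
  if (any(temp < 200))
    stop("temperatures below 200 K; pass Celsius values with unit = 'C'")
  Pf <- data$Pf
  if (any(Pf <= 0)) stop("all Pf values must be positive")
  if (length(unique(temp)) < 2L)
    stop("need >= 2 distinct temperatures")

  fit <- stats::lm(log(Pf) ~ I(1 / temp))
  slope <- stats::coef(fit)[[2]]
  r2 <- if (length(temp) >= 3L) rSquaredOf(fit) else NA_real_
  new("ArrheniusEstimate", Ea = -slope * constants@RKcal, slope = slope,
      intercept = stats::coef(fit)[[1]], rSquared = r2,
      nTemperatures = length(temp))
}

#' Aggregate per-trace permeability estimates over condition groups
#'
#' The analysis order is fit-per-trace, then average Pf across the runs of
#' each condition (not average-the-traces-then-fit).  The SD uses the n-1
#' denominator and is reported as NA for singleton groups rather than 0.
#'
#' @param estimates a list of [PermeabilityEstimate-class] objects or a
#'   data.frame with a `Pf` column plus grouping columns.
#' @param groupKeys character vector of condition labels to group by;
#'   missing labels are filled with `"NA"`.
#' @return data.frame with one row per group: the grouping columns, `meanPf`,
#'   `sdPf` and `n`.  Empty groups are dropped with a warning.
#' @export
aggregateReplicates <- function(estimates,
                                groupKeys = c("strain", "pH", "glucose",
                                              "inhibitor")) {
  df <- if (is.data.frame(estimates)) estimates else {
    do.call(rbind, lapply(estimates, function(e) {
      stopifnot(is(e, "PermeabilityEstimate"))
      row <- data.frame(Pf = e@Pf)
      for (kk in groupKeys)
        row[[kk]] <- as.character(e@condition[[kk]] %||% NA)
      row
    }))
  }
  keys <- intersect(groupKeys, names(df))
  if (length(keys) == 0L) {
    df$.all <- "all"
    keys <- ".all"
  }
  for (kk in keys) df[[kk]][is.na(df[[kk]])] <- "NA"
  groups <- split(df, df[keys], drop = TRUE)
  empty <- vapply(groups, nrow, 0L) == 0L
  if (any(empty)) {
    warning("dropping empty groups: ",
            paste(names(groups)[empty], collapse = ", "))
    groups <- groups[!empty]
  }
  out <- do.call(rbind, lapply(groups, function(g) {
    row <- g[1, keys, drop = FALSE]
    row$meanPf <- mean(g$Pf)
    row$sdPf <- if (nrow(g) > 1L) stats::sd(g$Pf) else NA_real_
    row$n <- nrow(g)
    row
  }))
  rownames(out) <- NULL
  out[setdiff(names(out), ".all")]
}
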