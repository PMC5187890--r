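#' First-order rate constant from an electrode decay trace
#'
#' Reproduces the plot-slope workflow: in oxygen-release mode the stored O2
#' values are first converted back to remaining H2O2 (x 2 stoichiometry),
#' points at or below the log floor are excluded (and counted), and the rate
#' constant is the negated slope of the ordinary least-squares regression of
#' `ln C` on time.
#'
#' @param trace a [DecayTrace-class].
#' @param floor exclusion floor on the H2O2 scale, µM; default 2% of the
#'   trace's nominal initial concentration.
#' @return a [RateEstimate-class].  A nonnegative slope (no consumption) is
#'   reported with a warning, not an error.
#' @examples
#' tr <- generateDecayTrace(50, 2e-3, duration = 500, sampleRate = 0.1)
#' fitFirstOrder(tr)
#' @export
fitFirstOrder <- function(trace, floor = NULL) {
  stopifnot(is(trace, "DecayTrace"))
  if (is.null(floor)) floor <- 0.02 * trace@C0Nominal
  conc <- if (trace@mode == "o2") trace@values * 2 else trace@values
  keep <- conc > floor
  if (sum(keep) < 4L)
    stop("need >= 4 points above the floor (", format(floor), " uM)")
  t <- trace@times[keep]
  lc <- log(conc[keep])
  fit <- stats::lm(lc ~ t)
  slope <- stats::coef(fit)[[2]]
  if (slope >= 0)
    warning("nonnegative semi-log slope: no measurable consumption")
  new("RateEstimate", k = -slope, interceptLogC = stats::coef(fit)[[1]],
      rSquared = rSquaredOf(fit), nPoints = as.integer(sum(keep)),
      mode = trace@mode, nBelowFloor = as.integer(sum(!keep)))
}

#' Subtract a cell-free blank trace from an electrode trace
#'
#' Optional correction for autodegradation of H2O2 in the medium: the decay
#' of a matched cell-free blank is removed on the log scale (rate-constant
#' subtraction), leaving the cell-attributable consumption.
#'
#' @param trace,blank [DecayTrace-class] objects in the same mode.
#' @param floor see [fitFirstOrder()].
#' @return a [RateEstimate-class] for the blank-corrected rate
#'   `k_cells = k_total - k_blank` (r-squared and point counts from the cell
#'   trace).
#' @export
blankCorrectRate <- function(trace, blank, floor = NULL) {
  stopifnot(trace@mode == blank@mode)
  total <- fitFirstOrder(trace, floor)
  bg <- fitFirstOrder(blank, floor)
  new("RateEstimate", k = total@k - bg@k,
      interceptLogC = total@interceptLogC, rSquared = total@rSquared,
      nPoints = total@nPoints, mode = total@mode,
      nBelowFloor = total@nBelowFloor)
}

#' Fold change of consumption rates between two groups
#'
#' `fold = mean(k_B) / mean(k_A)` with group-label bookkeeping (groups are
#' never silently reordered).  With at least two estimates per group an
#' unpaired t-test on the rate constants is attached.
#'
#' @param groupA,groupB lists of [RateEstimate-class] objects (or numeric
#'   vectors of rate constants).
#' @param labels length-2 character vector naming the groups.
#' @param equalVariance passed to [unpairedTTest()].
#' @return list with `fold`, `meanA`, `meanB`, `labels` and `test` (a
#'   [TestResult-class], or NULL when either group has fewer than 2 values).
#' @examples
#' compareRates(c(1.68e-3), c(2.39e-3),
#'              labels = c("control", "AQP5"))$fold  # 1.42
#' @export
compareRates <- function(groupA, groupB, labels = c("A", "B"),
                         equalVariance = TRUE) {
  kOf <- function(g) vapply(g, function(x)
    if (is(x, "RateEstimate")) x@k else as.numeric(x), numeric(1))
  kA <- kOf(as.list(groupA))
  kB <- kOf(as.list(groupB))
  if (length(kA) < 1L || length(kB) < 1L)
    stop("need >= 1 estimate per group")
  if (mean(kA) == 0) stop("zero mean rate in the denominator group")
  test <- if (length(kA) >= 2L && length(kB) >= 2L)
    unpairedTTest(kA, kB, equalVariance = equalVariance, labels = labels)
  else NULL
  list(fold = mean(kB) / mean(kA), meanA = mean(kA), meanB = mean(kB),
       labels = labels, test = test)
}
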