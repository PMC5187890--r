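#' Assemble tidy summary tables and figures from pipeline outputs
#'
#' Writes CSV summaries and standard diagnostic figures for whichever
#' analysis outputs are supplied; empty sections are simply omitted.  Output
#' is deterministic given identical inputs (no timestamps are written).
#'
#' @param outputs named list with any of:
#'   \describe{
#'     \item{permeability}{data.frame from [aggregateReplicates()].}
#'     \item{traces}{list of `list(trace = ShrinkageTrace,
#'       fit = ExponentialFit)`; plotted as signal + fitted curve.}
#'     \item{arrhenius}{`list(data = data.frame(temperatureK, Pf),
#'       estimate = ArrheniusEstimate)`; plotted as ln Pf vs 1/T.}
#'     \item{decay}{list of `list(trace = DecayTrace, fit = RateEstimate)`;
#'       plotted on a semi-log concentration axis.}
#'     \item{membrane}{a [MembraneExpression-class].}
#'     \item{survival}{data.frame from [survivalSummary()].}
#'     \item{tests}{named list of [TestResult-class]; the names label the
#'       comparisons, and figure star labels are drawn from these results.}
#'   }
#' @param dir output directory (created if needed).
#' @param figures write PNG figures as well as CSVs.
#' @return invisibly, the character vector of files written.
#' @export
buildReport <- function(outputs, dir, figures = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    written <<- c(written, path)
  }
  fig <- function(plot, name, width = 5, height = 4) {
    if (!figures) return()
    path <- file.path(dir, name)
    ggplot2::ggsave(path, plot, width = width, height = height, dpi = 120)
    written <<- c(written, path)
  }

  if (!is.null(outputs$permeability))
    emit(outputs$permeability, "permeability_summary.csv")

  if (length(outputs$traces)) {
    df <- do.call(rbind, lapply(seq_along(outputs$traces), function(i) {
      x <- outputs$traces[[i]]
      data.frame(trace = i, time = x$trace@times,
                 signal = x$trace@fluorescence,
                 fitted = x$fit@Finf + (x$fit@F0 - x$fit@Finf) *
                   exp(-x$fit@k * x$trace@times))
    }))
    emit(df, "trace_fits.csv")
    fig(ggplot2::ggplot(df, ggplot2::aes(x = time)) +
          ggplot2::geom_point(ggplot2::aes(y = signal), size = 0.2,
                              alpha = 0.3) +
          ggplot2::geom_line(ggplot2::aes(y = fitted), colour = "red") +
          ggplot2::facet_wrap(~trace) +
          ggplot2::labs(x = "time (s)", y = "fluorescence (a.u.)"),
        "trace_fits.png")
  }

  if (!is.null(outputs$arrhenius)) {
    a <- outputs$arrhenius
    df <- data.frame(invT = 1 / a$data$temperatureK, lnPf = log(a$data$Pf))
    emit(cbind(a$data, data.frame(
      Ea = a$estimate@Ea, slope = a$estimate@slope)), "arrhenius.csv")
    fig(ggplot2::ggplot(df, ggplot2::aes(invT, lnPf)) +
          ggplot2::geom_point() +
          ggplot2::geom_abline(slope = a$estimate@slope,
                               intercept = a$estimate@intercept,
                               colour = "red") +
          ggplot2::labs(x = "1/T (1/K)", y = "ln Pf"),
        "arrhenius.png")
  }

  if (length(outputs$decay)) {
    df <- do.call(rbind, lapply(seq_along(outputs$decay), function(i) {
      x <- outputs$decay[[i]]
      conc <- if (x$trace@mode == "o2") x$trace@values * 2
              else x$trace@values
      data.frame(trace = i, time = x$trace@times, h2o2 = conc,
                 k = x$fit@k)
    }))
    emit(df, "decay_fits.csv")
    fig(ggplot2::ggplot(df[df$h2o2 > 0, ],
                        ggplot2::aes(time, h2o2, group = trace)) +
          ggplot2::geom_line(alpha = 0.6) +
          ggplot2::scale_y_log10() +
          ggplot2::labs(x = "time (s)", y = "H2O2 (uM, log scale)"),
        "decay_fits.png")
  }

  if (!is.null(outputs$membrane)) {
    m <- outputs$membrane
    emit(m@perCell, "membrane_per_cell.csv")
    emit(data.frame(cohortMean = m@cohortMean, cohortSd = m@cohortSd,
                    nCells = m@nCells), "membrane_cohort.csv")
  }

  if (!is.null(outputs$survival)) {
    emit(outputs$survival, "survival_summary.csv")
    fig(ggplot2::ggplot(outputs$survival,
                        ggplot2::aes(time, meanPercent, colour = strain)) +
          ggplot2::geom_line() + ggplot2::geom_point() +
          ggplot2::labs(x = "time (min)", y = "survival (% of t0)"),
        "survival.png")
  }

  if (length(outputs$tests)) {
    df <- do.call(rbind, lapply(names(outputs$tests), function(nm) {
      tr <- outputs$tests[[nm]]
      data.frame(comparison = nm, method = tr@method,
                 statistic = tr@statistic, pValue = tr@pValue,
                 stars = tr@stars)
    }))
    emit(df, "tests.csv")
  }

  invisible(written)
}
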