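#' Generate a synthetic assay plate table
#'
#' Emulates a plate-reader export for a linear colorimetric or fluorometric
#' assay: standards at known concentrations and unknown samples, all read
#' through `reading = slope * concentration + intercept` plus Gaussian
#' noise.  The tidy layout (well, role, concentration, reading) is the
#' package's plate interchange format.
#'
#' @param assay one of `"catalase"`, `"gsh"`, `"bradford"`, `"dcf"`.
#' @param standards vector of standard concentrations (>= 3 values;
#'   replicate concentrations are allowed).
#' @param slope readout change per concentration unit (nonzero).
#' @param intercept readout at zero concentration.
#' @param unknownTrue true concentration(s) of the unknown sample(s).
#' @param noiseSd additive Gaussian noise SD on the readings.
#' @param seed integer seed.
#' @return data.frame with columns `well`, `role` (`standard`/`unknown`),
#'   `concentration` (NA for unknowns) and `reading`; attribute
#'   `groundTruth` carries `unknownTrue`, `slope` and `intercept`.
#' @examples
#' generateAssayPlate("catalase", standards = seq(0, 75, by = 15),
#'                    slope = -0.01, intercept = 1, unknownTrue = 32.5)
#' @export
generateAssayPlate <- function(assay = c("catalase", "gsh", "bradford",
                                         "dcf"),
                               standards, slope, intercept = 0,
                               unknownTrue, noiseSd = 0, seed = NULL) {
  assay <- match.arg(assay)
  if (length(standards) < 3L) stop("need >= 3 standards")
  if (slope == 0) stop("slope must be nonzero")
  conc <- c(standards, unknownTrue)
  role <- c(rep("standard", length(standards)),
            rep("unknown", length(unknownTrue)))
  reading <- slope * conc + intercept
  if (noiseSd > 0)
    reading <- reading + withSeed(seed, function()
      stats::rnorm(length(reading), sd = noiseSd))
  out <- data.frame(well = sprintf("W%02d", seq_along(conc)),
                    role = role,
                    concentration = ifelse(role == "standard", conc, NA),
                    reading = reading)
  attr(out, "groundTruth") <- list(assay = assay, unknownTrue = unknownTrue,
                                   slope = slope, intercept = intercept,
                                   noiseSd = noiseSd)
  out
}

#' Generate a colony-count table for an acute-stress survival time course
#'
#' Counts at each time follow `Poisson(n0 * fraction(t))` (or the exact
#' product with dispersion off).  A time-0 untreated reference (fraction 1)
#' is always present, matching the plating protocol in which survival is
#' expressed as a percentage of the time-0 colony number.
#'
#' @param n0 expected colony count of the untreated reference.
#' @param survivalCurve data.frame with columns `time` (min) and `fraction`
#'   (true surviving fraction in `[0, 1]`).
#' @param dispersion `"poisson"` or `"none"`.
#' @param seed integer seed.
#' @param replicates number of biological replicates.
#' @param strain label stamped on all rows.
#' @return data.frame with columns `strain`, `replicate`, `time`, `count`;
#'   attribute `groundTruth` carries the true curve and `n0`.
#' @examples
#' curve <- data.frame(time = c(5, 15, 30), fraction = c(0.8, 0.5, 0.6))
#' generateSurvivalCounts(250, curve, dispersion = "none")
#' @export
generateSurvivalCounts <- function(n0, survivalCurve,
                                   dispersion = c("poisson", "none"),
                                   seed = NULL, replicates = 1,
                                   strain = "strain1") {
  dispersion <- match.arg(dispersion)
  if (n0 <= 0) stop("n0 must be > 0")
  if (any(survivalCurve$fraction < 0 | survivalCurve$fraction > 1))
    stop("fractions must lie in [0, 1]")
  if (!0 %in% survivalCurve$time)
    survivalCurve <- rbind(data.frame(time = 0, fraction = 1),
                           survivalCurve)
  survivalCurve <- survivalCurve[order(survivalCurve$time), ]
  grid <- expand.grid(replicate = seq_len(replicates),
                      time = survivalCurve$time)
  mu <- n0 * survivalCurve$fraction[match(grid$time, survivalCurve$time)]
  counts <- if (dispersion == "poisson") {
    withSeed(seed, function() stats::rpois(nrow(grid), mu))
  } else mu
  out <- data.frame(strain = strain, replicate = grid$replicate,
                    time = grid$time, count = counts)
  attr(out, "groundTruth") <- list(n0 = n0, curve = survivalCurve,
                                   dispersion = dispersion, seed = seed)
  out
}
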