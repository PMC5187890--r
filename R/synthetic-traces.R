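#' Construct a simulated-cell specification
#'
#' @param Pf true osmotic water permeability, cm s^-1.
#' @param diameter equivalent sphere diameter, micrometres.
#' @param nonosmoticFraction non-osmotic volume fraction in `[0, 1)`.
#' @param osmIn0 initial internal osmolarity, osmol L^-1.  The default 1.4 is
#'   the isotonic sorbitol loading buffer.
#' @param osmOut external osmolarity after mixing, osmol L^-1.  The default
#'   1.75 is the equal-volume mix of 1.4 M and 2.1 M sorbitol buffers.
#' @return a [SimCellSpec-class].
#' @examples
#' simCellSpec(Pf = 4.94e-3)
#' @export
simCellSpec <- function(Pf, diameter = 5, nonosmoticFraction = 0,
                        osmIn0 = 1.4, osmOut = 1.75) {
  new("SimCellSpec", Pf = Pf, diameter = diameter,
      nonosmoticFraction = nonosmoticFraction,
      osmIn0 = osmIn0, osmOut = osmOut)
}

#' Construct a stopped-flow instrument specification
#'
#' Defaults describe a typical stopped-flow acquisition for yeast shrinkage:
#' 2 ms dead time, a 2 s window (about six relaxation half-times at the
#' aquaporin-mediated rate), 1 kHz sampling and additive Gaussian noise.
#'
#' @param deadTime s.
#' @param duration s.
#' @param sampleRate Hz.
#' @param noiseSd a.u.
#' @param fluorOffset a.u.
#' @param fluorGain a.u. per unit relative volume.
#' @param seed integer seed for the noise draws.
#' @return an [InstrumentSpec-class].
#' @export
instrumentSpec <- function(deadTime = 0.002, duration = 2,
                           sampleRate = 1000, noiseSd = 0.005,
                           fluorOffset = 0, fluorGain = 1, seed = 1L) {
  new("InstrumentSpec", deadTime = deadTime, duration = duration,
      sampleRate = sampleRate, noiseSd = noiseSd,
      fluorOffset = fluorOffset, fluorGain = fluorGain,
      seed = as.integer(seed))
}

#' Simulate the osmotic volume relaxation of a spherical cell
#'
#' Integrates the standard osmometer model
#' `dV/dt = -Pf A Vw (osm_out - osm_in(V))` with
#' `osm_in(V) = osm_in0 (V0 - Vb)/(V - Vb)` and non-osmotic volume
#' `Vb = nonosmoticFraction * V0`, i.e. the internal osmolyte amount is
#' conserved while the osmotically active volume shrinks.  In the
#' small-perturbation limit the relaxation is a single exponential with rate
#' `k = Pf (A/V0) Vw osm_out` (osm_out in mol cm^-3), which is the linear
#' relationship inverted by the estimation chain.
#'
#' @param cell a [SimCellSpec-class].
#' @param times strictly increasing sampling times, s, with `times[1] >= 0`.
#' @param constants a [PhysicalConstants-class].
#' @return numeric vector of relative volumes `V(t)/V0` in
#'   `(nonosmoticFraction, 1]`, monotone non-increasing for a hyperosmotic
#'   shock, converging to
#'   `nonosmoticFraction + (1 - nonosmoticFraction) osmIn0/osmOut`.
#' @examples
#' cell <- simCellSpec(Pf = 4.94e-3)
#' v <- simulateVolumeRelaxation(cell, seq(0, 2, by = 0.01))
#' tail(v, 1)  # near osmIn0/osmOut = 0.8
#' @export
simulateVolumeRelaxation <- function(cell, times,
                                     constants = physicalConstants()) {
  stopifnot(is(cell, "SimCellSpec"))
  if (length(times) < 1L || any(!is.finite(times)))
    stop("times must be finite")
  if (times[1] < 0) stop("times must start at or after 0")
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("times must be strictly increasing")
  if (cell@osmOut <= 0) stop("osmOut must be > 0")

  if (cell@Pf == 0) return(rep(1, length(times)))

  vb <- cell@nonosmoticFraction
  AoverV0 <- 6 / (cell@diameter * 1e-4)          # cm^-1
  rate <- cell@Pf * AoverV0 * constants@Vw * 1e-3 # per (osmol/L) per s
  deriv <- function(t, y, parms) {
    v <- y[1]
    osmIn <- cell@osmIn0 * (1 - vb) / (v - vb)
    list(-rate * (cell@osmOut - osmIn))
  }
  tt <- if (times[1] > 0) c(0, times) else times
  out <- deSolve::ode(y = c(v = 1), times = tt, func = deriv, parms = NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
  v <- out[, "v"]
  if (times[1] > 0) v <- v[-1]
  unname(pmin(v, 1))
}

#' Transduce a relative-volume series into a fluorescence trace
#'
#' Fluorescence is affine in relative volume,
#' `F(t) = fluorOffset + fluorGain * V(t)/V0`, plus i.i.d. Gaussian noise;
#' self-quenching of the entrapped fluorophore makes the signal track the
#' shrinking volume.  Samples earlier than the instrument dead time are
#' dropped, and the generative parameters are attached as ground truth.
#'
#' @param vRel relative-volume series in `(0, 1]`.
#' @param times sampling times, s, matching `vRel`.
#' @param instrument an [InstrumentSpec-class]; its `seed` drives the noise.
#' @param cell optional [SimCellSpec-class] recorded in the ground truth.
#' @param temperature K.
#' @param condition named list of labels.
#' @return a [ShrinkageTrace-class].
#' @export
volumeToFluorescence <- function(vRel, times, instrument,
                                 cell = NULL, temperature = 296.15,
                                 condition = list()) {
  stopifnot(is(instrument, "InstrumentSpec"))
  if (length(vRel) != length(times))
    stop("vRel and times must have equal length")
  if (any(vRel <= 0 | vRel > 1 + 1e-9))
    stop("vRel must lie in (0, 1]")
  if (instrument@fluorGain == 0)
    stop("degenerate signal: fluorGain must be nonzero")

  keep <- times >= instrument@deadTime
  times <- times[keep]
  f <- instrument@fluorOffset + instrument@fluorGain * vRel[keep]
  if (instrument@noiseSd > 0)
    f <- f + withSeed(instrument@seed, function()
      stats::rnorm(length(f), sd = instrument@noiseSd))

  gt <- list(noiseSd = instrument@noiseSd, seed = instrument@seed)
  if (!is.null(cell))
    gt <- c(list(PfTrue = cell@Pf, diameter = cell@diameter,
                 nonosmoticFraction = cell@nonosmoticFraction,
                 osmIn0 = cell@osmIn0, osmOut = cell@osmOut), gt)
  new("ShrinkageTrace", times = times, fluorescence = f,
      instrument = instrument, temperature = temperature,
      condition = condition, groundTruth = gt)
}

#' Simulate a complete stopped-flow shrinkage trace
#'
#' Convenience wrapper chaining [simulateVolumeRelaxation()] and
#' [volumeToFluorescence()] on the instrument's time base.
#'
#' @inheritParams volumeToFluorescence
#' @inheritParams simulateVolumeRelaxation
#' @return a [ShrinkageTrace-class].
#' @examples
#' tr <- simulateShrinkageTrace(simCellSpec(Pf = 4.94e-3),
#'                              instrumentSpec(seed = 7))
#' tr
#' @export
simulateShrinkageTrace <- function(cell, instrument = instrumentSpec(),
                                   temperature = 296.15,
                                   condition = list(),
                                   constants = physicalConstants()) {
  times <- seq(0, instrument@duration, by = 1 / instrument@sampleRate)
  v <- simulateVolumeRelaxation(cell, times, constants)
  volumeToFluorescence(v, times, instrument, cell = cell,
                       temperature = temperature, condition = condition)
}

#' Generate a synthetic Arrhenius series of Pf versus temperature
#'
#' `ln Pf(T) = ln PfRef - (EaTrue/R)(1/T - 1/TRef)` with optional Gaussian
#' noise on the log scale.
#'
#' @param EaTrue activation energy, kcal mol^-1 (> 0).
#' @param PfRef permeability at the reference temperature, cm s^-1.
#' @param TRef reference temperature, K.
#' @param temperatures vector of absolute temperatures, K.
#' @param noiseSdLog SD of the log-scale noise (0 = noiseless).
#' @param seed integer seed for the noise.
#' @param constants a [PhysicalConstants-class].
#' @return data.frame with columns `temperatureK` and `Pf`; attributes
#'   `groundTruth` (EaTrue, PfRef, TRef) and `insufficientPoints` (TRUE when
#'   fewer than 2 temperatures were requested, for downstream flagging).
#' @examples
#' generateArrheniusSeries(6.52, 4.94e-3, 296.15,
#'                         c(282.15, 289.15, 296.15, 307.15))
#' @export
generateArrheniusSeries <- function(EaTrue, PfRef, TRef, temperatures,
                                    noiseSdLog = 0, seed = NULL,
                                    constants = physicalConstants()) {
  if (EaTrue < 0) stop("EaTrue must be >= 0")
  if (any(temperatures <= 0)) stop("temperatures must be positive (K)")
  lnPf <- log(PfRef) - (EaTrue / constants@RKcal) *
    (1 / temperatures - 1 / TRef)
  if (noiseSdLog > 0)
    lnPf <- lnPf + withSeed(seed, function()
      stats::rnorm(length(lnPf), sd = noiseSdLog))
  out <- data.frame(temperatureK = temperatures, Pf = exp(lnPf))
  attr(out, "groundTruth") <- list(EaTrue = EaTrue, PfRef = PfRef,
                                   TRef = TRef, noiseSdLog = noiseSdLog)
  attr(out, "insufficientPoints") <- length(temperatures) < 2L
  out
}

#' Generate a first-order hydrogen peroxide decay trace
#'
#' `C(t) = C0 exp(-kTrue t)` plus additive Gaussian noise.  In `"o2"` mode
#' the stored series is `O2(t) = C(t)/2`: the oxygen burst produced when
#' exogenous catalase dismutates the remaining peroxide
#' (2 H2O2 -> 2 H2O + O2).  Negative draws are clipped to `floor` and
#' counted in the trace's `nClipped` slot.
#'
#' @param C0 initial H2O2 concentration, µM.
#' @param kTrue first-order rate constant, s^-1 (>= 0).
#' @param duration s.
#' @param sampleRate Hz.
#' @param noiseSd µM.
#' @param mode `"h2o2"` (peroxide electrode) or `"o2"` (oxygen release).
#' @param seed integer seed.
#' @param floor clipping floor, µM.
#' @param condition named list of labels.
#' @return a [DecayTrace-class] carrying `kTrue`, `C0` and `mode` as ground
#'   truth.
#' @examples
#' generateDecayTrace(50, 2e-3, duration = 500, sampleRate = 0.01)
#' @export
generateDecayTrace <- function(C0, kTrue, duration = 600, sampleRate = 1,
                               noiseSd = 0, mode = c("h2o2", "o2"),
                               seed = NULL, floor = 1e-3,
                               condition = list()) {
  mode <- match.arg(mode)
  if (C0 <= 0) stop("C0 must be > 0")
  if (kTrue < 0) stop("kTrue must be >= 0")
  times <- seq(0, duration, by = 1 / sampleRate)
  conc <- C0 * exp(-kTrue * times)
  values <- if (mode == "o2") conc / 2 else conc
  if (noiseSd > 0)
    values <- values + withSeed(seed, function()
      stats::rnorm(length(values), sd = noiseSd))
  clipped <- values < floor
  values[clipped] <- floor
  new("DecayTrace", times = times, values = values, mode = mode,
      C0Nominal = C0, condition = condition,
      groundTruth = list(kTrue = kTrue, C0 = C0, mode = mode,
                         noiseSd = noiseSd, seed = seed),
      nClipped = as.integer(sum(clipped)))
}
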