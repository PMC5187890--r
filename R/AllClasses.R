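#' @import methods
NULL

## Central S4 containers for the stopped-flow / electrode / imaging pipeline.
## All internal computation is in cgs units and Kelvin; osmolarities are held
## in osmol/L and converted to mol/cm^3 (x 1e-3) only inside the permeability
## formula.

#' Physical constants used throughout the pipeline
#'
#' Holds the molar volume of water and the gas constant in the units the
#' permeability and Arrhenius formulas expect.  Immutable value object.
#'
#' @slot Vw molar volume of water, cm^3 mol^-1.
#' @slot RKcal gas constant, kcal mol^-1 K^-1.
#'
#' @seealso [physicalConstants()]
#' @export
setClass("PhysicalConstants",
  representation(Vw = "numeric", RKcal = "numeric"),
  prototype(Vw = 18.05, RKcal = 1.9872e-3),
  validity = function(object) {
    if (length(object@Vw) != 1L || !is.finite(object@Vw) || object@Vw <= 0)
      return("Vw must be a single positive number (cm^3/mol)")
    if (length(object@RKcal) != 1L || !is.finite(object@RKcal) ||
        object@RKcal <= 0)
      return("RKcal must be a single positive number (kcal/(mol K))")
    TRUE
  })

#' Specification of a simulated osmometer cell
#'
#' Ground-truth parameters of the forward osmotic-shrinkage model: the true
#' water permeability, the equivalent-sphere diameter, the non-osmotic volume
#' fraction (solids and bound water unavailable to osmotic exchange) and the
#' internal/external osmolarities of the shock.
#'
#' @slot Pf true osmotic water permeability, cm s^-1.
#' @slot diameter equivalent sphere diameter, micrometres.
#' @slot nonosmoticFraction volume fraction in `[0, 1)` not available to
#'   osmosis.  The default 0 makes the linearised single-exponential model an
#'   exact nested case.
#' @slot osmIn0 initial internal osmolarity, osmol L^-1.
#' @slot osmOut external osmolarity after mixing, osmol L^-1.
#'
#' @seealso [simCellSpec()], [simulateVolumeRelaxation()]
#' @export
setClass("SimCellSpec",
  representation(Pf = "numeric", diameter = "numeric",
                 nonosmoticFraction = "numeric",
                 osmIn0 = "numeric", osmOut = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@Pf < 0) msg <- c(msg, "Pf must be >= 0")
    if (object@diameter <= 0) msg <- c(msg, "diameter must be > 0")
    if (object@nonosmoticFraction < 0 || object@nonosmoticFraction >= 1)
      msg <- c(msg, "nonosmoticFraction must be in [0, 1)")
    if (object@osmIn0 <= 0) msg <- c(msg, "osmIn0 must be > 0")
    if (object@osmOut <= 0) msg <- c(msg, "osmOut must be > 0")
    if (is.null(msg)) TRUE else msg
  })

#' Stopped-flow instrument settings
#'
#' @slot deadTime instrument dead time, s; samples earlier than this are
#'   discarded from generated traces.
#' @slot duration acquisition window, s.
#' @slot sampleRate sampling rate, Hz.
#' @slot noiseSd additive Gaussian noise SD, arbitrary units.
#' @slot fluorOffset fluorescence offset, a.u.
#' @slot fluorGain fluorescence change per unit relative volume, a.u.
#' @slot seed integer seed driving all random draws for this instrument.
#'
#' @seealso [instrumentSpec()]
#' @export
setClass("InstrumentSpec",
  representation(deadTime = "numeric", duration = "numeric",
                 sampleRate = "numeric", noiseSd = "numeric",
                 fluorOffset = "numeric", fluorGain = "numeric",
                 seed = "integer"),
  validity = function(object) {
    msg <- NULL
    if (object@deadTime < 0) msg <- c(msg, "deadTime must be >= 0")
    if (object@duration <= object@deadTime)
      msg <- c(msg, "duration must exceed deadTime")
    if (object@sampleRate <= 0) msg <- c(msg, "sampleRate must be > 0")
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
    if (is.null(msg)) TRUE else msg
  })

#' A stopped-flow shrinkage fluorescence trace
#'
#' Time-stamped fluorescence of carboxyfluorescein-loaded cells after a
#' hyperosmotic shock, together with the instrument settings, temperature and
#' condition labels.  Synthetic traces carry their generative ground truth.
#'
#' @slot times sampling times, s (strictly increasing, all >= dead time).
#' @slot fluorescence signal, a.u.
#' @slot instrument an [InstrumentSpec-class] object.
#' @slot temperature K.
#' @slot condition named list of labels (strain, pH, glucose, inhibitor, ...).
#' @slot groundTruth named list of generative parameters (empty for real
#'   data).
#'
#' @export
setClass("ShrinkageTrace",
  representation(times = "numeric", fluorescence = "numeric",
                 instrument = "InstrumentSpec", temperature = "numeric",
                 condition = "list", groundTruth = "list"),
  validity = function(object) {
    msg <- NULL
    if (length(object@times) != length(object@fluorescence))
      msg <- c(msg, "times and fluorescence must have equal length")
    if (length(object@times) > 1L && any(diff(object@times) <= 0))
      msg <- c(msg, "times must be strictly increasing")
    if (is.null(msg)) TRUE else msg
  })

#' Equivalent-sphere cell geometry
#'
#' Cells are treated as spheres with diameter equal to the average of the
#' maximum and minimum dimensions measured under the microscope.  Volume,
#' area and the volume-to-area ratio are stored in cgs units.
#'
#' @slot dMax,dMin measured maximum and minimum cell dimensions, micrometres.
#' @slot dEq equivalent diameter `(dMax + dMin)/2`, micrometres.
#' @slot V0 equilibrium volume, cm^3.
#' @slot A surface area, cm^2.
#' @slot V0OverA volume-to-area ratio `dEq/6`, cm.
#'
#' @seealso [computeGeometry()]
#' @export
setClass("CellGeometry",
  representation(dMax = "numeric", dMin = "numeric", dEq = "numeric",
                 V0 = "numeric", A = "numeric", V0OverA = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@dMin <= 0 || object@dMax < object@dMin)
      msg <- c(msg, "need dMax >= dMin > 0")
    dcm <- object@dEq * 1e-4
    if (abs(object@V0OverA - dcm / 6) > 1e-12 * max(dcm, 1e-12))
      msg <- c(msg, "V0OverA inconsistent with dEq (must equal dEq/6 in cm)")
    if (is.null(msg)) TRUE else msg
  })

#' Single-exponential fit of a shrinkage trace
#'
#' Result of fitting `F(t) = Finf + (F0 - Finf) exp(-k t)` to a stopped-flow
#' signal by nonlinear least squares.
#'
#' @slot k rate constant, s^-1.
#' @slot F0 fitted signal at t = 0, a.u.
#' @slot Finf fitted plateau, a.u.
#' @slot residualSse residual sum of squares, a.u.^2.
#' @slot nPoints number of points used.
#' @slot converged logical convergence flag.
#'
#' @seealso [fitSingleExponential()]
#' @export
setClass("ExponentialFit",
  representation(k = "numeric", F0 = "numeric", Finf = "numeric",
                 residualSse = "numeric", nPoints = "integer",
                 converged = "logical"),
  validity = function(object) {
    if (object@nPoints < 5L) return("nPoints must be >= 5")
    TRUE
  })

#' Osmotic water permeability estimate for one trace
#'
#' Couples a fitted rate constant with the geometry and shock osmolarity
#' through `Pf = k (V0/A) / (Vw osm_out)` (osm_out in mol cm^-3).  Validity
#' enforces internal consistency of the stored Pf with its own k, geometry
#' and osmolarity to machine precision.
#'
#' @slot Pf cm s^-1.
#' @slot k s^-1.
#' @slot geometry a [CellGeometry-class].
#' @slot osmOut external osmolarity, osmol L^-1.
#' @slot temperature K.
#' @slot constants the [PhysicalConstants-class] used.
#' @slot condition named list of labels.
#'
#' @seealso [computePf()]
#' @export
setClass("PermeabilityEstimate",
  representation(Pf = "numeric", k = "numeric", geometry = "CellGeometry",
                 osmOut = "numeric", temperature = "numeric",
                 constants = "PhysicalConstants", condition = "list"),
  validity = function(object) {
    if (object@osmOut <= 0) return("osmOut must be > 0")
    expect <- object@k * object@geometry@V0OverA /
      (object@constants@Vw * object@osmOut * 1e-3)
    if (abs(object@Pf - expect) > 1e-12 * max(abs(expect), 1e-15))
      return("Pf inconsistent with k, geometry and osmOut")
    TRUE
  })

#' Arrhenius activation-energy estimate
#'
#' Ordinary least squares of ln Pf on 1/T; the activation energy is the
#' negated slope times the gas constant.
#'
#' @slot Ea kcal mol^-1.
#' @slot slope K (slope of ln Pf vs 1/T).
#' @slot intercept dimensionless (ln Pf extrapolated to 1/T = 0).
#' @slot rSquared coefficient of determination (NA when only 2 temperatures).
#' @slot nTemperatures number of temperature points.
#'
#' @seealso [fitArrhenius()]
#' @export
setClass("ArrheniusEstimate",
  representation(Ea = "numeric", slope = "numeric", intercept = "numeric",
                 rSquared = "numeric", nTemperatures = "integer"),
  validity = function(object) {
    if (object@nTemperatures < 2L) return("need >= 2 temperatures")
    if (object@nTemperatures < 3L && !is.na(object@rSquared))
      return("rSquared must be NA with fewer than 3 temperatures")
    TRUE
  })

#' An electrode trace of hydrogen peroxide consumption
#'
#' Concentration versus time recorded either with a H2O2-specific electrode
#' (`mode = "h2o2"`) or as the O2 released when exogenous catalase dismutates
#' the remaining peroxide (`mode = "o2"`; the stored series is then half the
#' remaining H2O2 by the 2 H2O2 -> 2 H2O + O2 stoichiometry).
#'
#' @slot times s, strictly increasing.
#' @slot values µM (H2O2 in h2o2 mode, O2 in o2 mode); floor-clipped >= 0.
#' @slot mode `"h2o2"` or `"o2"`.
#' @slot C0Nominal nominal initial H2O2, µM.
#' @slot condition named list of labels (strain, inhibitor, ...).
#' @slot groundTruth named list of generative parameters.
#' @slot nClipped number of samples clipped at the generator floor.
#'
#' @export
setClass("DecayTrace",
  representation(times = "numeric", values = "numeric", mode = "character",
                 C0Nominal = "numeric", condition = "list",
                 groundTruth = "list", nClipped = "integer"),
  validity = function(object) {
    msg <- NULL
    if (length(object@times) != length(object@values))
      msg <- c(msg, "times and values must have equal length")
    if (length(object@times) > 1L && any(diff(object@times) <= 0))
      msg <- c(msg, "times must be strictly increasing")
    if (!object@mode %in% c("h2o2", "o2"))
      msg <- c(msg, "mode must be 'h2o2' or 'o2'")
    if (any(object@values < 0))
      msg <- c(msg, "values must be >= 0 after floor clipping")
    if (is.null(msg)) TRUE else msg
  })

#' First-order rate-constant estimate from an electrode trace
#'
#' @slot k s^-1 (negated slope of the semi-logarithmic regression).
#' @slot interceptLogC intercept of the regression, ln µM.
#' @slot rSquared coefficient of determination.
#' @slot nPoints points above the log floor actually used.
#' @slot mode readout mode of the fitted trace.
#' @slot nBelowFloor points excluded at or below the floor.
#'
#' @seealso [fitFirstOrder()]
#' @export
setClass("RateEstimate",
  representation(k = "numeric", interceptLogC = "numeric",
                 rSquared = "numeric", nPoints = "integer",
                 mode = "character", nBelowFloor = "integer"),
  validity = function(object) {
    if (!is.na(object@rSquared) &&
        (object@rSquared < 0 || object@rSquared > 1))
      return("rSquared must be in [0, 1]")
    TRUE
  })

#' A fluorescence intensity profile along a line crossing the membrane
#'
#' @slot positions distance along the line path, pixels.
#' @slot intensities sampled intensities, a.u.
#' @slot background matched-length intensities from a cell-free region
#'   (length 0 when not yet attached).
#' @slot cellId,lineId identifiers.
#'
#' @seealso [extractProfile()]
#' @export
setClass("LineProfile",
  representation(positions = "numeric", intensities = "numeric",
                 background = "numeric", cellId = "character",
                 lineId = "character"),
  validity = function(object) {
    msg <- NULL
    if (length(object@positions) != length(object@intensities))
      msg <- c(msg, "positions and intensities must have equal length")
    if (length(object@background) &&
        length(object@background) != length(object@intensities))
      msg <- c(msg, "background must match the profile length")
    if (any(object@intensities < 0) || any(object@background < 0))
      msg <- c(msg, "intensities must be >= 0")
    if (is.null(msg)) TRUE else msg
  })

#' Relative membrane expression of a cohort of cells
#'
#' Per-line values are averaged within each cell (three lines per cell in the
#' reference workflow) and the cohort mean and SD are taken across cells, not
#' across pooled lines.
#'
#' @slot perLine data.frame with columns cellId, lineId, value.
#' @slot perCell data.frame with columns cellId, value, nLines.
#' @slot cohortMean,cohortSd cohort statistics across cells.
#' @slot nCells number of cells.
#' @slot nClipped number of per-line values clipped into `[0, 1]`.
#'
#' @seealso [aggregateCells()]
#' @export
setClass("MembraneExpression",
  representation(perLine = "data.frame", perCell = "data.frame",
                 cohortMean = "numeric", cohortSd = "numeric",
                 nCells = "integer", nClipped = "integer"),
  validity = function(object) {
    if (any(object@perLine$value < 0 | object@perLine$value > 1))
      return("per-line values must lie in [0, 1] after clipping")
    TRUE
  })

#' A linear standard curve for a colorimetric assay
#'
#' @slot slope reading per concentration unit.
#' @slot intercept reading at zero concentration.
#' @slot rSquared coefficient of determination.
#' @slot range concentration range spanned by the standards (length 2).
#' @slot assay assay identifier ("catalase", "gsh", "bradford", "dcf", ...).
#' @slot nStandards number of standard points fitted.
#'
#' @seealso [fitStandardCurve()], [inversePredict()]
#' @export
setClass("StandardCurve",
  representation(slope = "numeric", intercept = "numeric",
                 rSquared = "numeric", range = "numeric",
                 assay = "character", nStandards = "integer"),
  validity = function(object) {
    if (object@nStandards < 3L) return("need >= 3 standards")
    if (length(object@range) != 2L) return("range must have length 2")
    TRUE
  })

#' Catalase activity result (Goth endpoint assay)
#'
#' One unit degrades 1 µmol H2O2 per minute at 25 degrees C.
#'
#' @slot UPerMg U mg^-1 protein.
#' @slot consumedUmol µmol H2O2 consumed during the reaction.
#' @slot concRemaining interpolated remaining H2O2, mM.
#' @slot reactionTime min.
#' @slot proteinMg mg protein in the assayed lysate.
#'
#' @seealso [catalaseActivity()]
#' @export
setClass("CatalaseResult",
  representation(UPerMg = "numeric", consumedUmol = "numeric",
                 concRemaining = "numeric", reactionTime = "numeric",
                 proteinMg = "numeric"),
  validity = function(object) {
    if (object@UPerMg < 0 || object@consumedUmol < 0)
      return("catalase activity must be nonnegative")
    TRUE
  })

#' Total glutathione result (Tietze recycling assay)
#'
#' @slot perMgProtein concentration per mg protein; the unit label is carried
#'   verbatim from the configuration rather than converted.
#' @slot rawConcentration interpolated concentration before normalisation.
#' @slot dilutionFactor applied dilution factor.
#' @slot proteinMg mg protein.
#' @slot unitLabel unit string carried through to reports.
#' @slot extrapolated TRUE when the reading fell outside the standard range.
#'
#' @seealso [gshLevel()]
#' @export
setClass("GshResult",
  representation(perMgProtein = "numeric", rawConcentration = "numeric",
                 dilutionFactor = "numeric", proteinMg = "numeric",
                 unitLabel = "character", extrapolated = "logical"),
  validity = function(object) {
    if (object@perMgProtein < 0) return("GSH level must be nonnegative")
    TRUE
  })

#' A DCF fluorescence time course with its fold-change series
#'
#' @slot times min.
#' @slot fluorescence a.u.
#' @slot fold `F(t)/F(0)`; fold at time 0 is exactly 1.
#'
#' @seealso [rosFoldChange()]
#' @export
setClass("RosTimeCourse",
  representation(times = "numeric", fluorescence = "numeric",
                 fold = "numeric"),
  validity = function(object) {
    if (length(object@times) != length(object@fluorescence) ||
        length(object@times) != length(object@fold))
      return("times, fluorescence and fold must have equal length")
    if (length(object@fold) && abs(object@fold[1] - 1) > 1e-12)
      return("fold at baseline must equal 1")
    TRUE
  })

#' A hypothesis-test result with its significance star label
#'
#' Stars follow the conventional mapping: `*` p < 0.05, `**` p < 0.01,
#' `***` p < 0.001, `ns` otherwise.
#'
#' @slot statistic test statistic.
#' @slot df degrees of freedom (length 1 for t, length 2 for F).
#' @slot pValue two-sided p-value in `[0, 1]`.
#' @slot method test name.
#' @slot groups labels of the compared groups.
#' @slot stars one of `ns`, `*`, `**`, `***`.
#'
#' @seealso [unpairedTTest()], [oneWayAnova()], [starLabel()]
#' @export
setClass("TestResult",
  representation(statistic = "numeric", df = "numeric", pValue = "numeric",
                 method = "character", groups = "character",
                 stars = "character"),
  validity = function(object) {
    if (object@pValue < 0 || object@pValue > 1)
      return("pValue must be in [0, 1]")
    if (!object@stars %in% c("ns", "*", "**", "***"))
      return("stars must be one of ns, *, **, ***")
    TRUE
  })
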