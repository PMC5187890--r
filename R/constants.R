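#' Create the physical-constants object
#'
#' @param Vw molar volume of water, cm^3 mol^-1.
#' @param RKcal gas constant, kcal mol^-1 K^-1.
#' @return a [PhysicalConstants-class] object.
#' @examples
#' physicalConstants()
#' @export
physicalConstants <- function(Vw = 18.05, RKcal = 1.9872e-3) {
  new("PhysicalConstants", Vw = Vw, RKcal = RKcal)
}

#' Reference measurements for rat AQP5 expressed in aqy-null yeast
#'
#' Published summary measurements (mean and SD) from the stopped-flow,
#' electrode, imaging and colorimetric characterisation of aqy-null yeast
#' transformed with rat AQP5 or with the empty vector (control).  These values
#' parameterise the synthetic-data generators and anchor the package's
#' derived-quantity checks (fold ratios, percent reductions).
#'
#' Columns: `quantity` (one of `Pf`, `Ea`, `k_o2_electrode`,
#' `k_h2o2_electrode`, `catalase`, `gsh`, `membrane_expression`), `strain`
#' (`control` or `AQP5`), `pH`, `condition` (`basal`, `glucose`,
#' `glucose_HgCl2`, `glucose_5min`, `glucose_15min`), `value`, `sd`, `units`.
#'
#' @return a `data.frame` of reference values.
#' @examples
#' refs <- aqp5ReferenceValues()
#' subset(refs, quantity == "Pf" & condition == "basal")
#' @export
aqp5ReferenceValues <- function() {
  path <- system.file("extdata", "aqp5_reference_values.csv",
                      package = "aquaflux", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Look up a single reference measurement
#'
#' Convenience filter over [aqp5ReferenceValues()]; errors unless exactly one
#' row matches.
#'
#' @param refs the reference table.
#' @param quantity,strain,condition,pH filter values; electrode and lysate
#'   quantities carry `pH = NA`.
#' @return the matching `value` (scalar).
#' @examples
#' refValue(aqp5ReferenceValues(), "Pf", "AQP5")
#' @export
refValue <- function(refs, quantity, strain, condition = "basal",
                     pH = 7.4) {
  hit <- refs[refs$quantity == quantity & refs$strain == strain &
                refs$condition == condition &
                (is.na(refs$pH) | refs$pH == pH), , drop = FALSE]
  if (nrow(hit) != 1L)
    stop("reference lookup not unique for ", quantity, "/", strain, "/",
         condition)
  hit$value
}

## evaluate a thunk under a temporary RNG state seeded with `seed`;
## the caller's .Random.seed is restored afterwards.  NULL seed = use the
## current RNG stream.
withSeed <- function(seed, fun) {
  if (is.null(seed)) return(fun())
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  fun()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## coefficient of determination without summary.lm's perfect-fit warning
rSquaredOf <- function(fit) {
  y <- stats::fitted(fit) + stats::resid(fit)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) return(NA_real_)
  max(0, min(1, 1 - sum(stats::resid(fit)^2) / sst))
}
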