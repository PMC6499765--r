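#' @import methods
NULL

#' One-compartment radiosensitizer pharmacokinetic parameters
#'
#' Disposition parameters of the orally dosed radiosensitizer. Dosing is
#' modelled as an instantaneous bolus into the central compartment (no
#' absorption phase), so a dose \eqn{D} (mg/kg) produces an initial
#' concentration \eqn{D F / V} that decays mono-exponentially with rate `ke`.
#'
#' @slot ke elimination rate constant (1/day).
#' @slot vOverF apparent distribution volume over bioavailability, normalised
#'   per kg body weight (mL/kg), so that a dose in mg/kg yields a plasma
#'   concentration in ug/mL.
#'
#' @seealso [pkParameters()], [concentrationAt()], [fitPK()]
#' @export
setClass("PKParameters",
  representation(ke = "numeric", vOverF = "numeric"))

setValidity("PKParameters", function(object) {
  msg <- character()
  if (length(object@ke) != 1L || !is.finite(object@ke) || object@ke <= 0)
    msg <- c(msg, "'ke' must be a single positive number")
  if (length(object@vOverF) != 1L || !is.finite(object@vOverF) ||
      object@vOverF <= 0)
    msg <- c(msg, "'vOverF' must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Tumor model parameters
#'
#' Structural parameters of the six-compartment tumor growth-and-kill model.
#' All rates are per day, radiation doses in Gy, concentrations in ug/mL.
#' The quadratic LQ coefficient is never free: `beta = alpha/alphaBetaRatio`
#' with the ratio fixed at 10 Gy by default (identifiability). All values are
#' stored in per-Gy / per-day units; per-kGy table values are converted at the
#' I/O boundary (see [readModelParameters()]).
#'
#' @slot kg exponential growth rate of proliferating cells (1/day).
#' @slot kk kill/natural-death rate feeding the damage-transit cascade (1/day).
#' @slot v0 initial proliferating-compartment scale (mm^3).
#' @slot alpha linear LQ coefficient (1/Gy).
#' @slot alphaBetaRatio alpha/beta ratio (Gy); beta = alpha/alphaBetaRatio.
#' @slot a radiosensitizer potency on the instantaneous-kill effect (mL/ug).
#' @slot gamma long-term growth-inhibition coefficient (1/Gy).
#' @slot b radiosensitizer potency on the long-term effect (mL/ug).
#' @slot lqQuadratic logical; include the quadratic LQ term (default `TRUE`).
#' @slot tsePotency `"b"` (default) or `"a"`: which potency multiplies the
#'   accumulated dose in the static-exposure expressions.
#'
#' @seealso [modelParameters()], [lethalFraction()], [tseDose()]
#' @export
setClass("ModelParameters",
  representation(kg = "numeric", kk = "numeric", v0 = "numeric",
                 alpha = "numeric", alphaBetaRatio = "numeric",
                 a = "numeric", gamma = "numeric", b = "numeric",
                 lqQuadratic = "logical", tsePotency = "character"))

setValidity("ModelParameters", function(object) {
  msg <- character()
  one <- function(x) length(x) == 1L && is.finite(x)
  for (nm in c("kg", "kk", "v0", "alpha", "alphaBetaRatio", "a", "gamma", "b"))
    if (!one(slot(object, nm)))
      msg <- c(msg, sprintf("'%s' must be a single finite number", nm))
  if (length(msg)) return(msg)
  if (object@kg < 0) msg <- c(msg, "'kg' must be non-negative")
  if (object@kk < 0) msg <- c(msg, "'kk' must be non-negative")
  if (object@v0 < 0) msg <- c(msg, "'v0' must be non-negative")
  if (object@alpha < 0 || object@gamma < 0 || object@a < 0 || object@b < 0)
    msg <- c(msg, "'alpha', 'gamma', 'a', 'b' must be non-negative")
  if (object@alphaBetaRatio <= 0)
    msg <- c(msg, "'alphaBetaRatio' must be positive")
  if (length(object@lqQuadratic) != 1L || is.na(object@lqQuadratic))
    msg <- c(msg, "'lqQuadratic' must be TRUE or FALSE")
  if (length(object@tsePotency) != 1L ||
      !object@tsePotency %in% c("a", "b"))
    msg <- c(msg, "'tsePotency' must be \"a\" or \"b\"")
  if (length(msg)) msg else TRUE
})

#' Population (mixed-effects) parameters
#'
#' Population medians plus between-subject variability (BSV) and residual
#' error of the combined (proportional + additive) model. Random effects are
#' log-normal on `v0`, `gamma` and `alpha`; `omega` holds their standard
#' deviations on the log scale.
#'
#' @slot fixed a [ModelParameters-class] object of population medians.
#' @slot omega named numeric of log-scale BSV standard deviations for
#'   `v0`, `gamma`, `alpha`.
#' @slot sigmaProp proportional residual SD (fraction of predicted volume).
#' @slot sigmaAdd additive residual SD (mm^3).
#'
#' @seealso [populationParameters()], [fitPopulation()], [generateStudy()]
#' @export
setClass("PopulationParameters",
  representation(fixed = "ModelParameters", omega = "numeric",
                 sigmaProp = "numeric", sigmaAdd = "numeric"))

setValidity("PopulationParameters", function(object) {
  msg <- character()
  if (!identical(sort(names(object@omega)), sort(c("v0", "gamma", "alpha"))))
    msg <- c(msg, "'omega' must be named with v0, gamma, alpha")
  else if (any(!is.finite(object@omega)) || any(object@omega < 0))
    msg <- c(msg, "'omega' entries must be finite and non-negative")
  if (length(object@sigmaProp) != 1L || object@sigmaProp < 0)
    msg <- c(msg, "'sigmaProp' must be a single non-negative number")
  if (length(object@sigmaAdd) != 1L || object@sigmaAdd < 0)
    msg <- c(msg, "'sigmaAdd' must be a single non-negative number")
  if (length(msg)) msg else TRUE
})

#' Treatment schedule of timed radiation fractions and sensitizer doses
#'
#' Each event carries a time (days since first treatment day), a radiation
#' fraction (Gy) and a concurrent oral sensitizer dose (mg/kg). The sensitizer
#' bolus is placed `sensitizerLeadTime` days before the irradiation time
#' (default 30 min), matching the protocol in which irradiation follows the
#' radiosensitizer application.
#'
#' @slot events `data.frame` with columns `time` (days, strictly increasing),
#'   `radiationGy` and `sensitizerMgPerKg`.
#' @slot sensitizerLeadTime days between sensitizer bolus and irradiation.
#'
#' @seealso [treatmentSchedule()], [monFriSchedule()], [simulateTumor()]
#' @export
setClass("TreatmentSchedule",
  representation(events = "data.frame", sensitizerLeadTime = "numeric"))

setValidity("TreatmentSchedule", function(object) {
  ev <- object@events
  msg <- character()
  need <- c("time", "radiationGy", "sensitizerMgPerKg")
  if (!all(need %in% names(ev)))
    return(sprintf("'events' needs columns %s", paste(need, collapse = ", ")))
  if (nrow(ev) > 0) {
    if (any(!is.finite(ev$time)) || is.unsorted(ev$time, strictly = TRUE))
      msg <- c(msg, "event times must be finite and strictly increasing")
    if (any(ev$radiationGy < 0) || any(ev$sensitizerMgPerKg < 0))
      msg <- c(msg, "doses must be non-negative")
  }
  if (length(object@sensitizerLeadTime) != 1L || object@sensitizerLeadTime < 0)
    msg <- c(msg, "'sensitizerLeadTime' must be a single non-negative number")
  if (length(msg)) msg else TRUE
})

#' Tumor model state
#'
#' The six model compartments plus accumulated effective dose: proliferating
#' volume `v1`; damage-transit volumes `v2`, `v3`, `v4`; lethally irradiated
#' division-capable volume `u1`; lethally irradiated post-division volume
#' `u2`; and the accumulated effective radiation dose `irTot` (Gy) that drives
#' permanent growth inhibition.
#'
#' @slot v1,v2,v3,v4,u1,u2 compartment volumes (mm^3), all non-negative.
#' @slot irTot accumulated effective dose (Gy), non-negative.
#'
#' @seealso [initialState()], [propagateState()], [applyIrradiation()],
#'   [totalVolume()]
#' @export
setClass("TumorState",
  representation(v1 = "numeric", v2 = "numeric", v3 = "numeric",
                 v4 = "numeric", u1 = "numeric", u2 = "numeric",
                 irTot = "numeric"))

setValidity("TumorState", function(object) {
  vals <- c(object@v1, object@v2, object@v3, object@v4,
            object@u1, object@u2, object@irTot)
  if (length(vals) != 7L || any(!is.finite(vals)))
    return("all slots must be single finite numbers")
  if (any(vals < -1e-9))
    return("compartment volumes and irTot must be non-negative")
  TRUE
})

#' Simulated tumor trajectory
#'
#' Result of [simulateTumor()]: compartment states at the requested
#' observation times (left limits at event times) plus pre-/post-event states
#' at every irradiation event.
#'
#' @slot times observation times (days).
#' @slot states matrix (one row per time) with columns `v1..v4`, `u1`, `u2`,
#'   `irTot`.
#' @slot events `data.frame` with one row per irradiation event: `time`,
#'   `radiationGy`, `concentration`, `totalPre`, `totalPost`, `irTotPost`.
#' @slot params the [ModelParameters-class] used.
#'
#' @seealso [simulateTumor()], [totalVolume()], [isEradicated()]
#' @export
setClass("TumorTrajectory",
  representation(times = "numeric", states = "matrix", events = "data.frame",
                 params = "ModelParameters"))

#' Tumor Static Exposure curve
#'
#' The locus of (concentration, total radiation dose) pairs at which the net
#' tumor growth rate equals `targetRate` (0 for classic TSE: stasis).
#' Exposures above the curve shrink the tumor faster than the target.
#'
#' @slot concentrations sensitizer plasma concentration grid (ug/mL).
#' @slot doses total accumulated radiation dose at the target rate (Gy).
#' @slot targetRate net growth rate defining the isocline (1/day).
#' @slot params the [ModelParameters-class] used.
#'
#' @seealso [tseCurve()], [tseDose()], [tseConcentration()]
#' @export
setClass("TSECurve",
  representation(concentrations = "numeric", doses = "numeric",
                 targetRate = "numeric", params = "ModelParameters"))

setValidity("TSECurve", function(object) {
  if (length(object@concentrations) != length(object@doses))
    return("'concentrations' and 'doses' must have equal length")
  TRUE
})

#' In-silico xenograft study design
#'
#' Emulates the reference protocol: four arms (vehicle; 2 Gy; 2 Gy + 25 mg/kg;
#' 2 Gy + 100 mg/kg) of ten mice each, treated Mon-Fri for six weeks, with
#' caliper measurements twice a week (Mondays and Thursdays) during treatment
#' and for twelve weeks of follow-up. Day 0 is the Monday of week 1.
#'
#' @slot arms `data.frame` with columns `label`, `radiationGy`,
#'   `sensitizerMgPerKg` (per-fraction values).
#' @slot nPerArm animals per arm.
#' @slot nWeeksTreatment weeks of Mon-Fri dosing.
#' @slot nWeeksFollowup weeks of post-treatment follow-up measurements.
#' @slot measurementDays days-of-week measured (0 = Monday).
#' @slot enrollmentRange optional length-2 numeric (mm^3): draw each animal's
#'   initial total volume uniformly on this window and back-scale `v0`
#'   accordingly; empty (default) draws `v0` from the population law.
#' @slot censoringCap volume (mm^3) above which the animal is sacrificed and
#'   later records dropped.
#' @slot detectionLimit volume (mm^3) below which observations are flagged
#'   below-limit.
#' @slot dropoutHazard per-day random dropout hazard (default 0, off).
#' @slot seed integer RNG seed.
#'
#' @seealso [studyDesign()], [generateStudy()]
#' @export
setClass("StudyDesign",
  representation(arms = "data.frame", nPerArm = "numeric",
                 nWeeksTreatment = "numeric", nWeeksFollowup = "numeric",
                 measurementDays = "numeric", enrollmentRange = "numeric",
                 censoringCap = "numeric", detectionLimit = "numeric",
                 dropoutHazard = "numeric", seed = "numeric"))

setValidity("StudyDesign", function(object) {
  msg <- character()
  need <- c("label", "radiationGy", "sensitizerMgPerKg")
  if (!all(need %in% names(object@arms)) || nrow(object@arms) < 1)
    msg <- c(msg, "'arms' needs >= 1 row with label, radiationGy, sensitizerMgPerKg")
  if (object@nPerArm < 1) msg <- c(msg, "'nPerArm' must be >= 1")
  if (object@nWeeksFollowup < 0) msg <- c(msg, "'nWeeksFollowup' must be >= 0")
  if (!length(object@enrollmentRange) %in% c(0L, 2L))
    msg <- c(msg, "'enrollmentRange' must be empty or length 2")
  if (object@dropoutHazard < 0) msg <- c(msg, "'dropoutHazard' must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Fitted population model
#'
#' Result of [fitPopulation()]: maximum (Laplace-approximated) marginal
#' likelihood estimates, optional asymptotic standard errors, empirical Bayes
#' estimates (EBEs) and convergence diagnostics.
#'
#' @slot estimates fitted [PopulationParameters-class].
#' @slot se named numeric of asymptotic standard errors on the natural scale
#'   (length 0 when not computed).
#' @slot rse named numeric of relative standard errors (percent).
#' @slot ebes `data.frame` of per-animal random-effect modes (`etaV0`,
#'   `etaGamma`, `etaAlpha`), derived individual parameters and objective
#'   contributions.
#' @slot neg2ll final -2 log marginal likelihood.
#' @slot trace numeric vector of accepted objective values.
#' @slot convergence optimizer convergence code (0 = success).
#' @slot message optimizer message.
#' @slot fixedNames parameters held fixed during the fit.
#'
#' @seealso [fitPopulation()], [ebeShrinkage()], [parameterTable()]
#' @export
setClass("PopulationFit",
  representation(estimates = "PopulationParameters", se = "numeric",
                 rse = "numeric", ebes = "data.frame", neg2ll = "numeric",
                 trace = "numeric", convergence = "numeric",
                 message = "character", fixedNames = "character"))
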