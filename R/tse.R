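# Tumor Static Exposure analytics.
#
# The short-term (instantaneous kill) effect only displaces volume
# transiently, so the long-run fate of the tumor is decided by the permanent
# growth inhibition: k_net = kg * exp(-gamma * IR_Tot) - kk with
# IR_Tot = (1 + potency * C) * D for a total physical dose D delivered at
# concurrent concentration C. The potency is `b` by default; `tsePotency`
# in ModelParameters allows probing `a` instead.

tsePotencyValue <- function(params) {
  if (params@tsePotency == "b") params@b else params@a
}

#' Net tumor growth rate after accumulated exposure
#'
#' \deqn{k_{net} = k_g \exp(-\gamma (1 + bC) D) - k_k}
#' Its sign separates regrowth from regression; its zero set is the TSE
#' curve.
#'
#' @param totalDose total physical radiation dose (Gy, >= 0); vectorised.
#' @param C concurrent sensitizer concentration (ug/mL, >= 0); vectorised.
#' @param params a [ModelParameters-class] object.
#' @return net growth rate (1/day).
#' @examples
#' netGrowthRate(0, 0, modelParameters())    # 0.14
#' netGrowthRate(60, 0, modelParameters())   # 0.0547: regrowth, slower
#' @export
netGrowthRate <- function(totalDose, C = 0, params) {
  stopifnot(is(params, "ModelParameters"))
  if (any(totalDose < 0) || any(C < 0)) stop("negative dose or concentration")
  pot <- tsePotencyValue(params)
  params@kg * exp(-params@gamma * (1 + pot * C) * totalDose) - params@kk
}

checkTargetRate <- function(params, targetRate) {
  if (length(targetRate) != 1L || !is.finite(targetRate))
    stop("'targetRate' must be a single finite number")
  if (targetRate <= -params@kk || targetRate > params@kg - params@kk)
    stop(sprintf(
      "no finite stasis dose: 'targetRate' must lie in (%.4g, %.4g]",
      -params@kk, params@kg - params@kk))
}

#' Total radiation dose achieving a target net growth rate
#'
#' Solves `k_net = targetRate` for the total dose at concentration `C`:
#' \deqn{D = \frac{\log(k_g / (k_k + r))}{\gamma (1 + bC)}}
#' `targetRate = 0` (default) gives the classic TSE dose; negative targets
#' give shrinkage isoclines (TSE_dV). Valid targets lie in
#' `(-kk, kg - kk]`; outside, no finite dose exists and an error is raised.
#'
#' @param C sensitizer plasma concentration (ug/mL, >= 0); vectorised.
#' @param params a [ModelParameters-class] object with `gamma > 0`.
#' @param targetRate target net growth rate (1/day).
#' @return total dose (Gy).
#' @examples
#' tseDose(0, modelParameters())   # 107.7 Gy radiation alone
#' tseDose(2, modelParameters())   # 82.8 Gy with 2 ug/mL sensitizer
#' @export
tseDose <- function(C, params, targetRate = 0) {
  stopifnot(is(params, "ModelParameters"))
  if (any(C < 0)) stop("negative concentration")
  if (params@gamma <= 0)
    stop("'gamma' must be positive for a finite stasis dose")
  checkTargetRate(params, targetRate)
  pot <- tsePotencyValue(params)
  log(params@kg / (params@kk + targetRate)) / (params@gamma * (1 + pot * C))
}

#' Sensitizer concentration achieving a target net rate at a given dose
#'
#' Exact functional inverse of [tseDose()]:
#' \deqn{C = \frac{\log(k_g / (k_k + r))}{\gamma b D} - \frac{1}{b}}
#' When the dose alone already achieves the target the raw value is negative;
#' it is clipped to 0 and flagged in the `"radiationSufficient"` attribute.
#'
#' @param D total radiation dose (Gy, > 0); vectorised.
#' @inheritParams tseDose
#' @return concentration (ug/mL) with logical attribute
#'   `"radiationSufficient"`.
#' @examples
#' tseConcentration(82.84287, modelParameters())   # ~2 ug/mL
#' tseConcentration(200, modelParameters())        # 0, radiation sufficient
#' @export
tseConcentration <- function(D, params, targetRate = 0) {
  stopifnot(is(params, "ModelParameters"))
  if (any(D <= 0)) stop("dose must be positive")
  if (params@gamma <= 0) stop("'gamma' must be positive")
  pot <- tsePotencyValue(params)
  if (pot <= 0) stop("TSE potency is zero: no concentration can compensate")
  checkTargetRate(params, targetRate)
  raw <- log(params@kg / (params@kk + targetRate)) / (params@gamma * pot * D) -
    1 / pot
  out <- pmax(0, raw)
  attr(out, "radiationSufficient") <- raw < 0
  out
}

#' Build a TSE curve over a concentration grid
#'
#' @param params a [ModelParameters-class] object.
#' @param concentrations concentration grid (ug/mL).
#' @param targetRate target net growth rate (1/day); 0 for classic TSE.
#' @return a [TSECurve-class] object.
#' @examples
#' tseCurve(modelParameters())
#' @export
tseCurve <- function(params, concentrations = seq(0, 10, length.out = 201),
                     targetRate = 0) {
  new("TSECurve", concentrations = concentrations,
      doses = tseDose(concentrations, params, targetRate),
      targetRate = targetRate, params = params)
}

setMethod("show", "TSECurve", function(object) {
  cat(sprintf(
    "TSE curve (target rate %.4g /day): C %.3g-%.3g ug/mL, D %.4g-%.4g Gy\n",
    object@targetRate, min(object@concentrations),
    max(object@concentrations), min(object@doses), max(object@doses)))
})

#' @describeIn tseCurve curve as a `data.frame`
#'   (`concentration_ug_per_ml`, `tse_dose_gy`, `target_rate_per_day`).
#' @param x a `TSECurve` object.
#' @param ... ignored.
#' @export
as.data.frame.TSECurve <- function(x, ...) {
  data.frame(concentration_ug_per_ml = x@concentrations,
             tse_dose_gy = x@doses,
             target_rate_per_day = x@targetRate)
}

#' Write a TSE curve to CSV
#' @param curve a [TSECurve-class] object.
#' @param path CSV file path.
#' @export
writeTSECurve <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' Net-growth-rate heat map over exposure grids
#'
#' Element `[i, j]` is the net growth rate at total dose `dGrid[i]` and
#' concentration `cGrid[j]`. The zero contour coincides pointwise with the
#' TSE curve. Default grids cover 0-10 ug/mL by 0-200 Gy at 201 x 201 points.
#'
#' @param params a [ModelParameters-class] object.
#' @param cGrid concentration grid (ug/mL, >= 0), non-empty.
#' @param dGrid total-dose grid (Gy, >= 0), non-empty.
#' @return matrix of rates (1/day) with `dimnames` of doses x concentrations
#'   and attributes `"concentrations"` and `"doses"`.
#' @examples
#' h <- tseHeatmap(modelParameters(), cGrid = c(0, 2), dGrid = c(0, 110))
#' h["0", "0"]   # 0.14
#' @export
tseHeatmap <- function(params, cGrid = seq(0, 10, length.out = 201),
                       dGrid = seq(0, 200, length.out = 201)) {
  if (length(cGrid) == 0L || length(dGrid) == 0L) stop("empty exposure grid")
  m <- outer(dGrid, cGrid, function(d, c) netGrowthRate(d, c, params))
  dimnames(m) <- list(format(dGrid, trim = TRUE, digits = 7),
                      format(cGrid, trim = TRUE, digits = 7))
  attr(m, "doses") <- dGrid
  attr(m, "concentrations") <- cGrid
  m
}

#' Write a heat map as a long CSV
#'
#' Columns: `concentration_ug_per_ml, total_dose_gy, k_net_per_day`.
#'
#' @param heatmap output of [tseHeatmap()].
#' @param path CSV file path.
#' @export
writeHeatmap <- function(heatmap, path) {
  d <- attr(heatmap, "doses")
  cc <- attr(heatmap, "concentrations")
  long <- data.frame(
    concentration_ug_per_ml = rep(cc, each = length(d)),
    total_dose_gy = rep(d, length(cc)),
    k_net_per_day = as.vector(heatmap))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Net growth rate over time for each treatment arm
#'
#' The net rate is a step function of time, dropping at each irradiation as
#' effective dose accumulates; a vehicle arm stays constant at `kg - kk`.
#' Rates are non-increasing in time for every arm.
#'
#' @param params a [ModelParameters-class] object.
#' @param schedules named list of [TreatmentSchedule-class], one per arm.
#' @param pk a [PKParameters-class] object, or `NULL`.
#' @return `data.frame` with columns `arm`, `time` (days), `knet` (1/day):
#'   the value holding from `time` until the next row of the same arm.
#' @export
netRateTimeline <- function(params, schedules, pk = NULL) {
  stopifnot(is(params, "ModelParameters"), is.list(schedules))
  if (is.null(names(schedules)))
    names(schedules) <- paste0("arm", seq_along(schedules))
  pot <- params@b
  out <- lapply(names(schedules), function(arm) {
    sched <- schedules[[arm]]
    ev <- sched@events
    conc <- eventConcentrations(sched, pk)
    irTot <- cumsum((1 + pot * conc) * ev$radiationGy)
    data.frame(arm = arm,
               time = c(0, ev$time),
               knet = params@kg *
                 growthInhibition(c(0, irTot), params) - params@kk)
  })
  do.call(rbind, out)
}

#' Population TSE fan
#'
#' One TSE curve per individual parameter set (e.g., empirical Bayes
#' estimates), a summary curve from the component-wise median parameters, and
#' a pointwise quantile envelope of the individual curves.
#'
#' @param paramsList list of [ModelParameters-class] objects (>= 1).
#' @param concentrations concentration grid (ug/mL).
#' @param targetRate target net growth rate (1/day).
#' @param probs quantiles of the envelope.
#' @return list with `curves` (individuals x grid matrix of doses),
#'   `medianCurve` (a [TSECurve-class] from median parameters), and
#'   `envelope` (`data.frame` of pointwise quantiles).
#' @export
populationTSE <- function(paramsList,
                          concentrations = seq(0, 10, length.out = 101),
                          targetRate = 0,
                          probs = c(0.025, 0.5, 0.975)) {
  stopifnot(length(paramsList) >= 1L)
  curves <- t(vapply(paramsList,
                     function(p) tseDose(concentrations, p, targetRate),
                     numeric(length(concentrations))))
  med <- paramsList[[1L]]
  for (nm in c("kg", "kk", "v0", "alpha", "a", "gamma", "b"))
    slot(med, nm) <- stats::median(vapply(paramsList, slot, numeric(1), nm))
  qs <- apply(curves, 2L, stats::quantile, probs = probs)
  envelope <- data.frame(concentration_ug_per_ml = concentrations,
                         t(qs), check.names = FALSE)
  list(curves = curves,
       medianCurve = tseCurve(med, concentrations, targetRate),
       envelope = envelope)
}

#' Allometric scaling of the system rates
#'
#' Scales `kg` and `kk` jointly by `s`, leaving all exposure parameters
#' unchanged. The TSE curve depends on the rates only through the quotient
#' `kg/kk`, so it is invariant under this scaling, while the untreated net
#' growth rate scales by `s` (a larger animal grows more slowly, but needs
#' the same exposure for stasis).
#'
#' @param params a [ModelParameters-class] object.
#' @param s positive scale factor.
#' @return the scaled [ModelParameters-class].
#' @export
allometricScale <- function(params, s) {
  stopifnot(is(params, "ModelParameters"))
  if (length(s) != 1L || !is.finite(s) || s <= 0)
    stop("'s' must be a single positive number")
  updateParameters(params, kg = s * params@kg, kk = s * params@kk)
}

#' Sensitivity of the TSE curve to its parameters
#'
#' Rescales each parameter by `1 + perturbation` and `1 - perturbation` in
#' turn and reports the signed relative change of the stasis dose over the
#' concentration grid. For `gamma` the change is uniform in `C`
#' (`D` is proportional to `1/gamma`); for `b` it grows with `C`; the rate
#' parameters act through `log(kg/kk)` and dominate.
#'
#' @param params a [ModelParameters-class] object.
#' @param perturbation fractional perturbation in (0, 1).
#' @param concentrations concentration grid (ug/mL).
#' @param parameters which parameters to perturb.
#' @return `data.frame` with columns `parameter`, `scale`, `concentration`,
#'   `tse_dose_gy`, `rel_change`.
#' @examples
#' s <- tseSensitivity(modelParameters(), 0.1, concentrations = 0)
#' subset(s, parameter == "kg" & scale > 1)$rel_change   # +22.1%
#' @export
tseSensitivity <- function(params, perturbation = 0.1,
                           concentrations = c(0, 2, 8),
                           parameters = c("kg", "kk", "gamma", "b")) {
  if (length(perturbation) != 1L || perturbation <= 0 || perturbation >= 1)
    stop("'perturbation' must be in (0, 1)")
  base <- tseDose(concentrations, params)
  rows <- list()
  for (nm in parameters) {
    for (fac in c(1 + perturbation, 1 - perturbation)) {
      p2 <- params
      slot(p2, nm) <- fac * slot(params, nm)
      d2 <- tseDose(concentrations, p2)
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = nm, scale = fac, concentration = concentrations,
        tse_dose_gy = d2, rel_change = d2 / base - 1)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
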