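#' Construct PK parameters
#'
#' Defaults are calibrated to the reported radiosensitizer kinetics: a 3 h
#' half-life (`ke = log(2)/0.125` per day) and peak plasma concentrations of
#' 2 and 8 ug/mL after 25 and 100 mg/kg oral doses (`vOverF` = 12500 mL/kg).
#'
#' @param ke elimination rate constant (1/day).
#' @param vOverF apparent distribution volume over bioavailability per kg body
#'   weight (mL/kg).
#' @return a [PKParameters-class] object.
#' @examples
#' pk <- pkParameters()
#' halfLife(pk) * 24      # hours
#' @export
pkParameters <- function(ke = log(2) / 0.125, vOverF = 12500) {
  new("PKParameters", ke = ke, vOverF = vOverF)
}

#' Elimination half-life (days)
#' @param pk a [PKParameters-class] object.
#' @export
halfLife <- function(pk) {
  stopifnot(is(pk, "PKParameters"))
  log(2) / pk@ke
}

setMethod("show", "PKParameters", function(object) {
  cat(sprintf(
    "One-compartment PK: ke = %.4g /day (half-life %.3g h), V/F = %.4g mL/kg\n",
    object@ke, 24 * halfLife(object), object@vOverF))
})

#' Plasma concentration under a multi-dose schedule
#'
#' Closed-form superposition of mono-exponential decays: each bolus of
#' `amount` mg/kg contributes `1000 * amount / vOverF * exp(-ke (t - tdose))`
#' ug/mL for `t >= tdose`. Returns 0 before the first dose.
#'
#' @param pk a [PKParameters-class] object.
#' @param doses `data.frame` with columns `time` (days, >= 0) and `amount`
#'   (mg/kg, >= 0).
#' @param t times (days, >= 0) at which to evaluate; vectorised.
#' @return concentrations (ug/mL), same length as `t`.
#' @examples
#' pk <- pkParameters()
#' concentrationAt(pk, data.frame(time = 0, amount = 25), c(0, 0.125))
#' @export
concentrationAt <- function(pk, doses, t) {
  stopifnot(is(pk, "PKParameters"))
  doses <- as.data.frame(doses)
  if (!all(c("time", "amount") %in% names(doses)))
    stop("'doses' needs columns 'time' and 'amount'")
  if (any(t < 0)) stop("negative evaluation times")
  if (nrow(doses) == 0L) return(rep(0, length(t)))
  if (any(doses$time < 0) || any(doses$amount < 0))
    stop("negative dose times or amounts")
  doses <- doses[order(doses$time), , drop = FALSE]
  peak <- 1000 * doses$amount / pk@vOverF        # ug/mL at dose time
  vapply(t, function(ti) {
    on <- doses$time <= ti
    sum(peak[on] * exp(-pk@ke * (ti - doses$time[on])))
  }, numeric(1))
}

#' Fit one-compartment PK parameters to sparse samples
#'
#' Log-linear regression of log-concentration on time after a single dose:
#' `ke` is minus the slope and `vOverF` is back-extrapolated from the
#' intercept. Times may be supplied in days (default) or hours.
#'
#' @param samples `data.frame` with columns `time` and `conc` (ug/mL, > 0).
#' @param dose administered dose (mg/kg).
#' @param timeUnit `"days"` or `"hours"`.
#' @return a [PKParameters-class] object; residuals of the log-linear fit are
#'   attached as attribute `"residuals"`.
#' @examples
#' pk <- pkParameters()
#' s <- data.frame(time = c(1, 2, 6) / 24,
#'                 conc = concentrationAt(pk, data.frame(time = 0, amount = 25),
#'                                        c(1, 2, 6) / 24))
#' fitPK(s, dose = 25)
#' @export
fitPK <- function(samples, dose, timeUnit = c("days", "hours")) {
  timeUnit <- match.arg(timeUnit)
  samples <- as.data.frame(samples)
  if (!all(c("time", "conc") %in% names(samples)))
    stop("'samples' needs columns 'time' and 'conc'")
  if (any(samples$conc <= 0))
    stop("non-positive concentrations cannot be log-transformed")
  tt <- samples$time
  if (timeUnit == "hours") tt <- tt / 24
  if (length(unique(tt)) < 2L)
    stop("underdetermined: need samples at >= 2 distinct times")
  fit <- stats::lm(log(samples$conc) ~ tt)
  ke <- -unname(stats::coef(fit)[2L])
  if (!is.finite(ke) || ke <= 0)
    stop("fitted elimination rate is not positive; data do not decay")
  c0 <- exp(unname(stats::coef(fit)[1L]))
  out <- pkParameters(ke = ke, vOverF = 1000 * dose / c0)
  attr(out, "residuals") <- unname(stats::residuals(fit))
  out
}

#' Read / write sparse PK sample CSVs
#'
#' Schema: `animal_id, dose_mg_per_kg, time_h, conc_ug_per_ml`.
#'
#' @param path CSV file path.
#' @return `readPKSamples` returns the `data.frame`.
#' @export
readPKSamples <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "dose_mg_per_kg", "time_h", "conc_ug_per_ml")
  if (!all(need %in% names(x)))
    stop("PK sample file must have columns ", paste(need, collapse = ", "))
  x
}

#' @rdname readPKSamples
#' @param samples `data.frame` in the same schema.
#' @export
writePKSamples <- function(samples, path) {
  utils::write.csv(samples, path, row.names = FALSE)
  invisible(path)
}
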