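#' Construct a treatment schedule
#'
#' @param time event times (days since first treatment day), strictly
#'   increasing.
#' @param radiationGy radiation fraction sizes (Gy), recycled.
#' @param sensitizerMgPerKg sensitizer oral doses (mg/kg), recycled.
#' @param sensitizerLeadTime days between sensitizer bolus and irradiation
#'   (default 30 min = 0.5/24 day).
#' @return a [TreatmentSchedule-class] object.
#' @examples
#' treatmentSchedule(0:4, radiationGy = 2, sensitizerMgPerKg = 25)
#' @export
treatmentSchedule <- function(time = numeric(), radiationGy = numeric(),
                              sensitizerMgPerKg = 0,
                              sensitizerLeadTime = 0.5 / 24) {
  n <- length(time)
  ev <- data.frame(time = as.numeric(time),
                   radiationGy = rep_len(as.numeric(radiationGy), n),
                   sensitizerMgPerKg = rep_len(as.numeric(sensitizerMgPerKg), n))
  new("TreatmentSchedule", events = ev, sensitizerLeadTime = sensitizerLeadTime)
}

#' Monday-to-Friday fractionation protocol
#'
#' Builds the reference schedule: one fraction per weekday for `nWeeks` weeks,
#' with day 0 the Monday of week 1. The default (2 Gy, 6 weeks) delivers
#' 30 fractions / 60 Gy physical dose.
#'
#' @param radiationGy per-fraction dose (Gy).
#' @param sensitizerMgPerKg per-day sensitizer dose (mg/kg).
#' @param nWeeks number of treatment weeks.
#' @param sensitizerLeadTime days between sensitizer bolus and irradiation.
#' @return a [TreatmentSchedule-class] object.
#' @examples
#' sched <- monFriSchedule(2, 25)
#' nrow(sched@events)   # 30 fractions
#' @export
monFriSchedule <- function(radiationGy = 2, sensitizerMgPerKg = 0,
                           nWeeks = 6, sensitizerLeadTime = 0.5 / 24) {
  days <- as.vector(outer(0:4, 7 * (seq_len(nWeeks) - 1), "+"))
  treatmentSchedule(sort(days), radiationGy, sensitizerMgPerKg,
                    sensitizerLeadTime)
}

setMethod("show", "TreatmentSchedule", function(object) {
  ev <- object@events
  cat(sprintf("Treatment schedule: %d events", nrow(ev)))
  if (nrow(ev)) {
    cat(sprintf(", days %.3g-%.3g, total %.3g Gy",
                min(ev$time), max(ev$time), sum(ev$radiationGy)))
    if (any(ev$sensitizerMgPerKg > 0))
      cat(sprintf(", sensitizer %.3g mg/kg/dose (lead %.3g h)",
                  max(ev$sensitizerMgPerKg), 24 * object@sensitizerLeadTime))
  }
  cat("\n")
})

#' Sensitizer bolus times implied by a schedule
#'
#' Each event with a positive sensitizer dose contributes a bolus placed
#' `sensitizerLeadTime` days before the irradiation time (clipped at 0 for
#' events at time 0 or earlier than the lead).
#'
#' @param schedule a [TreatmentSchedule-class] object.
#' @return `data.frame` with columns `time`, `amount` suitable for
#'   [concentrationAt()].
#' @export
sensitizerDoses <- function(schedule) {
  stopifnot(is(schedule, "TreatmentSchedule"))
  ev <- schedule@events
  keep <- ev$sensitizerMgPerKg > 0
  data.frame(time = pmax(0, ev$time[keep] - schedule@sensitizerLeadTime),
             amount = ev$sensitizerMgPerKg[keep])
}

#' Sensitizer concentration at each irradiation event
#'
#' Evaluates the full superposition of all sensitizer boluses (including
#' carry-over from earlier days) at the irradiation times. With the
#' no-absorption PK model and negligible carry-over this equals the peak
#' concentration times `exp(-ke * leadTime)`.
#'
#' @param schedule a [TreatmentSchedule-class] object.
#' @param pk a [PKParameters-class] object, or `NULL` for zero concentration.
#' @return concentrations (ug/mL), one per event.
#' @export
eventConcentrations <- function(schedule, pk) {
  stopifnot(is(schedule, "TreatmentSchedule"))
  ev <- schedule@events
  if (is.null(pk) || nrow(ev) == 0L || all(ev$sensitizerMgPerKg == 0))
    return(rep(0, nrow(ev)))
  concentrationAt(pk, sensitizerDoses(schedule), ev$time)
}

#' Read / write dosing CSVs
#'
#' Schema (shared across modules):
#' `animal_id, time_days, radiation_gy, sensitizer_mg_per_kg`, zero-filled
#' where a component is absent.
#'
#' @param path CSV file path.
#' @return `readDosing` returns the `data.frame`.
#' @export
readDosing <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "time_days", "radiation_gy", "sensitizer_mg_per_kg")
  if (!all(need %in% names(x)))
    stop("dosing file must have columns ", paste(need, collapse = ", "))
  x
}

#' @rdname readDosing
#' @param dosing `data.frame` in the same schema.
#' @export
writeDosing <- function(dosing, path) {
  utils::write.csv(dosing, path, row.names = FALSE)
  invisible(path)
}

#' Per-animal schedules from a dosing table
#'
#' @param dosing `data.frame` in the [readDosing()] schema.
#' @param sensitizerLeadTime lead time applied to every schedule (days).
#' @return named list of [TreatmentSchedule-class], one per `animal_id`.
#' @export
schedulesFromDosing <- function(dosing, sensitizerLeadTime = 0.5 / 24) {
  lapply(split(dosing, dosing$animal_id), function(d) {
    d <- d[order(d$time_days), , drop = FALSE]
    # rows that deliver nothing (vehicle placeholders) carry no event
    d <- d[d$radiation_gy > 0 | d$sensitizer_mg_per_kg > 0, , drop = FALSE]
    treatmentSchedule(d$time_days, d$radiation_gy, d$sensitizer_mg_per_kg,
                      sensitizerLeadTime)
  })
}
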