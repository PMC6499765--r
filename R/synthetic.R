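# In-silico replicas of the xenograft study and the sparse-sampling PK
# substudy, with ground truth written alongside so every estimator is
# testable without external data.

#' Construct a study design
#'
#' Defaults emulate the reference protocol: four arms (vehicle; 2 Gy;
#' 2 Gy + 25 mg/kg; 2 Gy + 100 mg/kg) of 10 mice, Mon-Fri dosing for 6 weeks,
#' caliper measurements on Mondays and Thursdays during treatment plus 12
#' follow-up weeks, sacrifice above 2000 mm^3, detection limit 4 mm^3.
#'
#' @param arms `data.frame` with columns `label`, `radiationGy`,
#'   `sensitizerMgPerKg` (per-fraction / per-day values).
#' @param nPerArm animals per arm.
#' @param nWeeksTreatment treatment weeks (Mon-Fri pattern).
#' @param nWeeksFollowup follow-up weeks of measurement after arrest.
#' @param measurementDays measured days-of-week (0 = Monday, 3 = Thursday).
#' @param enrollmentRange optional `c(lo, hi)` mm^3: draw initial total
#'   volume uniformly and back-scale `v0`; empty draws `v0` from the
#'   population law.
#' @param censoringCap sacrifice volume (mm^3).
#' @param detectionLimit below-limit flagging threshold (mm^3).
#' @param dropoutHazard per-day random dropout hazard (0 = off).
#' @param seed integer RNG seed.
#' @return a [StudyDesign-class] object.
#' @examples
#' studyDesign(nPerArm = 3, seed = 7)
#' @export
studyDesign <- function(arms = data.frame(
                          label = c("vehicle", "radiation",
                                    "combo25", "combo100"),
                          radiationGy = c(0, 2, 2, 2),
                          sensitizerMgPerKg = c(0, 0, 25, 100),
                          stringsAsFactors = FALSE),
                        nPerArm = 10, nWeeksTreatment = 6,
                        nWeeksFollowup = 12, measurementDays = c(0, 3),
                        enrollmentRange = numeric(),
                        censoringCap = 2000, detectionLimit = 4,
                        dropoutHazard = 0, seed = 1) {
  new("StudyDesign", arms = arms, nPerArm = nPerArm,
      nWeeksTreatment = nWeeksTreatment, nWeeksFollowup = nWeeksFollowup,
      measurementDays = measurementDays, enrollmentRange = enrollmentRange,
      censoringCap = censoringCap, detectionLimit = detectionLimit,
      dropoutHazard = dropoutHazard, seed = seed)
}

setMethod("show", "StudyDesign", function(object) {
  cat(sprintf(
    "Study design: %d arms x %d animals, %g treatment + %g follow-up weeks, seed %g\n",
    nrow(object@arms), object@nPerArm, object@nWeeksTreatment,
    object@nWeeksFollowup, object@seed))
  print(object@arms)
})

#' Measurement times of a design (days)
#'
#' Twice-weekly caliper days over treatment plus follow-up, with day 0 the
#' Monday of week 1.
#'
#' @param design a [StudyDesign-class] object.
#' @return sorted numeric vector of days.
#' @export
measurementTimes <- function(design) {
  stopifnot(is(design, "StudyDesign"))
  weeks <- seq_len(design@nWeeksTreatment + design@nWeeksFollowup) - 1
  sort(as.vector(outer(design@measurementDays, 7 * weeks, "+")))
}

#' Treatment schedule of one arm of a design
#' @param design a [StudyDesign-class] object.
#' @param arm arm label or row index.
#' @param sensitizerLeadTime days between sensitizer bolus and irradiation.
#' @return a [TreatmentSchedule-class] object (empty for a vehicle arm).
#' @export
armSchedule <- function(design, arm, sensitizerLeadTime = 0.5 / 24) {
  stopifnot(is(design, "StudyDesign"))
  row <- if (is.character(arm)) which(design@arms$label == arm) else arm
  if (length(row) != 1L || is.na(row) || row < 1 || row > nrow(design@arms))
    stop("unknown arm: ", arm)
  rad <- design@arms$radiationGy[row]
  sens <- design@arms$sensitizerMgPerKg[row]
  if (rad == 0 && sens == 0)
    return(treatmentSchedule(sensitizerLeadTime = sensitizerLeadTime))
  monFriSchedule(rad, sens, design@nWeeksTreatment, sensitizerLeadTime)
}

#' Generate a complete synthetic xenograft study
#'
#' Per animal: draw log-normal random effects on `v0`, `gamma`, `alpha`;
#' build the arm schedule; simulate the tumor trajectory; sample at the
#' design's measurement times; add combined proportional + additive residual
#' noise (truncated at 0); flag values below the detection limit; and apply
#' the sacrifice cap (the first measurement at or above the cap is kept and
#' flagged, later records are dropped). Ground-truth individual parameters
#' are returned alongside. Fully reproducible from the design seed.
#'
#' @param pop a [PopulationParameters-class] object (truth).
#' @param design a [StudyDesign-class] object.
#' @param pk a [PKParameters-class] object.
#' @param sensitizerLeadTime days between sensitizer bolus and irradiation.
#' @return list with `observations` (`animal_id, arm, time_days, volume_mm3,
#'   pred_mm3, below_limit, sacrificed`), `dosing` ([readDosing()] schema)
#'   and `groundTruth` (`animal_id, arm, eta_v0, eta_gamma, eta_alpha, v0,
#'   gamma, alpha`).
#' @examples
#' sim <- generateStudy(populationParameters(),
#'                      studyDesign(nPerArm = 2, seed = 11))
#' head(sim$observations)
#' @export
generateStudy <- function(pop, design, pk = pkParameters(),
                          sensitizerLeadTime = 0.5 / 24) {
  stopifnot(is(pop, "PopulationParameters"), is(design, "StudyDesign"))
  times <- measurementTimes(design)
  obsL <- list()
  doseL <- list()
  truthL <- list()
  withr::with_seed(design@seed, {
    for (aRow in seq_len(nrow(design@arms))) {
      armLab <- design@arms$label[aRow]
      sched <- armSchedule(design, aRow, sensitizerLeadTime)
      for (j in seq_len(design@nPerArm)) {
        id <- sprintf("%s_%02d", armLab, j)
        eta <- stats::rnorm(3) * pop@omega[c("v0", "gamma", "alpha")]
        ind <- individualParameters(pop, eta)
        if (length(design@enrollmentRange) == 2L) {
          # draw the enrolled total volume; back-scale v0 through the
          # geometric initial distribution
          tot <- stats::runif(1, design@enrollmentRange[1L],
                              design@enrollmentRange[2L])
          r <- ind@kk / ind@kg
          v0 <- tot / sum(r^(0:3))
          eta[1L] <- log(v0 / pop@fixed@v0)
          ind <- updateParameters(ind, v0 = v0)
        }
        traj <- simulateTumor(ind, sched, times, pk)
        pred <- totalVolume(traj)
        noise <- stats::rnorm(length(pred), 0, 1)
        y <- pmax(0, pred + noise * residualSD(pred, pop))
        keepN <- length(y)
        cross <- which(y >= design@censoringCap)
        if (length(cross)) keepN <- min(keepN, cross[1L])
        if (design@dropoutHazard > 0) {
          tDrop <- stats::rexp(1, design@dropoutHazard)
          keepN <- min(keepN, sum(times < tDrop))
        }
        keep <- seq_len(keepN)
        obsL[[id]] <- data.frame(
          animal_id = id, arm = armLab, time_days = times[keep],
          volume_mm3 = y[keep], pred_mm3 = pred[keep],
          below_limit = y[keep] < design@detectionLimit,
          sacrificed = y[keep] >= design@censoringCap)
        ev <- sched@events
        doseL[[id]] <- if (nrow(ev)) {
          data.frame(animal_id = id, time_days = ev$time,
                     radiation_gy = ev$radiationGy,
                     sensitizer_mg_per_kg = ev$sensitizerMgPerKg)
        } else {
          data.frame(animal_id = id, time_days = 0,
                     radiation_gy = 0, sensitizer_mg_per_kg = 0)
        }
        truthL[[id]] <- data.frame(
          animal_id = id, arm = armLab,
          eta_v0 = unname(eta[1L]), eta_gamma = unname(eta[2L]),
          eta_alpha = unname(eta[3L]),
          v0 = ind@v0, gamma = ind@gamma, alpha = ind@alpha)
      }
    }
  })
  out <- list(observations = do.call(rbind, obsL),
              dosing = do.call(rbind, doseL),
              groundTruth = do.call(rbind, truthL))
  rownames(out$observations) <- rownames(out$dosing) <-
    rownames(out$groundTruth) <- NULL
  out
}

#' Generate a sparse-sampling PK substudy
#'
#' Emulates the satellite PK experiment: a few animals per dose level, plasma
#' samples at fixed times after a single oral dose, log-normal multiplicative
#' noise.
#'
#' @param pk a [PKParameters-class] object (truth).
#' @param doses dose levels (mg/kg).
#' @param nPerDose animals per dose level.
#' @param timesH sampling times (hours after dosing).
#' @param noiseCv coefficient of variation of the log-normal noise.
#' @param seed integer RNG seed.
#' @return `data.frame` in the [readPKSamples()] schema.
#' @examples
#' generatePKStudy(pkParameters(), noiseCv = 0, seed = 1)
#' @export
generatePKStudy <- function(pk = pkParameters(), doses = c(25, 100),
                            nPerDose = 4, timesH = c(1, 2, 6),
                            noiseCv = 0.1, seed = 1) {
  stopifnot(is(pk, "PKParameters"), nPerDose >= 1)
  sdlog <- if (noiseCv > 0) sqrt(log(1 + noiseCv^2)) else 0
  rows <- list()
  withr::with_seed(seed, {
    for (d in doses) {
      for (j in seq_len(nPerDose)) {
        conc <- concentrationAt(pk, data.frame(time = 0, amount = d),
                                timesH / 24)
        if (sdlog > 0)
          conc <- conc * exp(stats::rnorm(length(conc), 0, sdlog))
        rows[[length(rows) + 1L]] <- data.frame(
          animal_id = sprintf("pk%g_%02d", d, j),
          dose_mg_per_kg = d, time_h = timesH, conc_ug_per_ml = conc)
      }
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
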