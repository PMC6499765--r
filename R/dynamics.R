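#' Total tumor volume
#'
#' Sum of all six compartments, `v1 + v2 + v3 + v4 + u1 + u2`.
#'
#' @param x a [TumorState-class] or [TumorTrajectory-class] object.
#' @return for a state, a single volume (mm^3); for a trajectory, one volume
#'   per observation time.
#' @export
setGeneric("totalVolume", function(x) standardGeneric("totalVolume"))

#' @rdname totalVolume
#' @export
setMethod("totalVolume", "TumorState", function(x) {
  x@v1 + x@v2 + x@v3 + x@v4 + x@u1 + x@u2
})

#' @rdname totalVolume
#' @export
setMethod("totalVolume", "TumorTrajectory", function(x) {
  unname(rowSums(x@states[, c("v1", "v2", "v3", "v4", "u1", "u2"),
                          drop = FALSE]))
})

setMethod("show", "TumorState", function(object) {
  cat(sprintf(
    "Tumor state: total %.4g mm^3 (v1 %.4g, v2 %.4g, v3 %.4g, v4 %.4g, u1 %.4g, u2 %.4g), irTot %.4g Gy\n",
    totalVolume(object), object@v1, object@v2, object@v3, object@v4,
    object@u1, object@u2, object@irTot))
})

tumorState <- function(v1 = 0, v2 = 0, v3 = 0, v4 = 0, u1 = 0, u2 = 0,
                       irTot = 0) {
  new("TumorState", v1 = v1, v2 = v2, v3 = v3, v4 = v4, u1 = u1, u2 = u2,
      irTot = irTot)
}

stateToVec <- function(state) {
  c(state@v1, state@v2, state@v3, state@v4, state@u1, state@u2)
}

vecToState <- function(x, irTot) {
  tumorState(v1 = x[[1L]], v2 = x[[2L]], v3 = x[[3L]], v4 = x[[4L]],
             u1 = x[[5L]], u2 = x[[6L]], irTot = irTot)
}

#' Pre-treatment initial state
#'
#' Distributes the initial volume geometrically across the four V
#' compartments, `v_i = v0 (kk/kg)^(i-1)`, with `u1 = u2 = 0` and no
#' accumulated dose. This distribution is an eigenvector of the untreated
#' transit cascade, so an untreated tumor grows strictly exponentially at
#' rate `kg - kk` from time 0.
#'
#' @param params a [ModelParameters-class] object.
#' @return a [TumorState-class] object.
#' @examples
#' totalVolume(initialState(modelParameters()))   # 63.37 mm^3
#' @export
initialState <- function(params) {
  stopifnot(is(params, "ModelParameters"))
  if (params@kg <= 0) stop("'kg' must be positive to form the initial state")
  if (params@kk >= params@kg)
    warning("kk >= kg: untreated tumor shrinks", call. = FALSE)
  r <- params@kk / params@kg
  v <- params@v0 * r^(0:3)
  tumorState(v1 = v[1L], v2 = v[2L], v3 = v[3L], v4 = v[4L])
}

#' Apply one irradiation event
#'
#' Instantaneous jump at an irradiation: the lethally irradiated fraction
#' `F(D, C)` of `v1` moves to `u1` (total volume is exactly conserved at the
#' instant) and the accumulated effective dose increases by `(1 + bC) D`.
#' All other compartments are unchanged.
#'
#' @param state a [TumorState-class] object.
#' @param D radiation dose (Gy).
#' @param C concurrent sensitizer concentration (ug/mL).
#' @param params a [ModelParameters-class] object.
#' @return the post-event [TumorState-class].
#' @export
applyIrradiation <- function(state, D, C = 0, params) {
  stopifnot(is(state, "TumorState"))
  f <- lethalFraction(D, C, params)
  moved <- f * state@v1
  tumorState(v1 = state@v1 - moved, v2 = state@v2, v3 = state@v3,
             v4 = state@v4, u1 = state@u1 + moved, u2 = state@u2,
             irTot = state@irTot + effectiveDoseIncrement(D, C, params))
}

systemMatrix <- function(params, irTot) {
  kg <- params@kg
  kk <- params@kk
  inhib <- growthInhibition(irTot, params)
  A <- matrix(0, 6, 6)
  A[1, 1] <- kg * inhib - kk
  A[2, c(1, 5, 6)] <- kk
  A[2, 2] <- -kk
  A[3, 2] <- kk
  A[3, 3] <- -kk
  A[4, 3] <- kk
  A[4, 4] <- -kk
  A[5, 5] <- -(kg + kk)
  A[6, 5] <- 2 * kg
  A[6, 6] <- -kk
  A
}

#' Propagate the state between events
#'
#' Advances the continuous dynamics for `dt` days with no intervening
#' irradiation. Between events the system is linear and time-invariant (the
#' inhibition factor depends only on `irTot`, which changes at events), so
#' the propagation is exact: `x(t + dt) = expm(A dt) x(t)` computed with
#' [Matrix::expm()]. `irTot` is unchanged.
#'
#' @param state a [TumorState-class] object.
#' @param dt time step (days, >= 0).
#' @param params a [ModelParameters-class] object.
#' @return the propagated [TumorState-class].
#' @export
propagateState <- function(state, dt, params) {
  stopifnot(is(state, "TumorState"), is(params, "ModelParameters"))
  if (length(dt) != 1L || !is.finite(dt) || dt < 0)
    stop("'dt' must be a single non-negative number")
  if (dt == 0) return(state)
  A <- systemMatrix(params, state@irTot)
  x <- as.numeric(Matrix::expm(A * dt) %*% stateToVec(state))
  vecToState(x, state@irTot)
}

#' Simulate a tumor trajectory under a treatment schedule
#'
#' Alternates exact linear propagation with irradiation jumps in event order.
#' The sensitizer concentration at each irradiation is evaluated from the PK
#' model with the bolus placed `sensitizerLeadTime` earlier (including any
#' carry-over from previous doses). Observation times may precede time 0
#' (pre-treatment growth is exactly exponential from the geometric initial
#' state). An observation exactly at an event time records the pre-event
#' (left) limit; the post-event (right) limits are in the `events` slot.
#'
#' @param params a [ModelParameters-class] object.
#' @param schedule a [TreatmentSchedule-class] object.
#' @param obsTimes observation times (days), any order (sorted internally).
#' @param pk a [PKParameters-class] object, or `NULL` to ignore the
#'   sensitizer.
#' @param concentrations optional explicit sensitizer concentrations at the
#'   events (ug/mL, recycled), overriding the PK evaluation; useful for
#'   exposure-pair (TSE) demonstrations at a fixed concentration.
#' @return a [TumorTrajectory-class] object.
#' @examples
#' traj <- simulateTumor(modelParameters(), monFriSchedule(2), seq(0, 60, 3))
#' tail(totalVolume(traj), 1)
#' @export
simulateTumor <- function(params, schedule = treatmentSchedule(),
                          obsTimes, pk = NULL, concentrations = NULL) {
  stopifnot(is(params, "ModelParameters"), is(schedule, "TreatmentSchedule"))
  if (length(obsTimes) == 0L) stop("no observation times")
  ord <- order(obsTimes)
  obsTimes <- obsTimes[ord]
  ev <- schedule@events
  conc <- if (is.null(concentrations)) eventConcentrations(schedule, pk)
          else rep_len(concentrations, nrow(ev))

  state0 <- initialState(params)
  x0 <- stateToVec(state0)
  nms <- c("v1", "v2", "v3", "v4", "u1", "u2", "irTot")

  neg <- obsTimes < 0
  states <- matrix(NA_real_, length(obsTimes), 7,
                   dimnames = list(NULL, nms))
  if (any(neg)) {
    # geometric initial distribution is an eigenvector: exact back-step
    growth <- exp((params@kg - params@kk) * obsTimes[neg])
    states[neg, 1:6] <- outer(growth, x0)
    states[neg, 7] <- 0
  }
  pos <- which(!neg)
  horizon <- if (length(pos)) max(obsTimes[pos]) else 0
  keep <- ev$time <= horizon
  evm <- cbind(ev$time[keep], ev$radiationGy[keep], conc[keep])
  res <- .simulateEngine(x0, evm, obsTimes[pos],
                         params@kg, params@kk, params@alpha, betaOf(params),
                         params@a, params@gamma, params@b)
  if (length(pos)) states[pos, ] <- res$obs

  events <- data.frame(time = evm[, 1L], radiationGy = evm[, 2L],
                       concentration = evm[, 3L],
                       totalPre = rowSums(res$eventPre[, 1:6, drop = FALSE]),
                       totalPost = rowSums(res$eventPost[, 1:6, drop = FALSE]),
                       irTotPost = res$eventPost[, 7L])
  # undo the sort so rows match the caller's obsTimes order
  inv <- order(ord)
  new("TumorTrajectory", times = obsTimes[inv],
      states = states[inv, , drop = FALSE], events = events, params = params)
}

setMethod("show", "TumorTrajectory", function(object) {
  tot <- totalVolume(object)
  cat(sprintf(
    "Tumor trajectory: %d observations over days %.3g-%.3g, %d events\n",
    length(object@times), min(object@times), max(object@times),
    nrow(object@events)))
  cat(sprintf("  total volume %.4g -> %.4g mm^3, final irTot %.4g Gy\n",
              tot[1L], tot[length(tot)],
              object@states[nrow(object@states), "irTot"]))
})

#' @describeIn simulateTumor trajectory as a long `data.frame`
#'   (`time_days`, compartments, `ir_tot_gy`, `total_mm3`).
#' @param x a `TumorTrajectory` object.
#' @param ... ignored.
#' @export
as.data.frame.TumorTrajectory <- function(x, ...) {
  data.frame(time_days = x@times,
             v1 = x@states[, "v1"], v2 = x@states[, "v2"],
             v3 = x@states[, "v3"], v4 = x@states[, "v4"],
             u1 = x@states[, "u1"], u2 = x@states[, "u2"],
             ir_tot_gy = x@states[, "irTot"],
             total_mm3 = totalVolume(x))
}

#' Eradication flag for a trajectory
#'
#' Eradication is asymptotic in an ODE model; for reporting, a tumor counts
#' as eradicated when its final simulated total volume is below `threshold`.
#'
#' @param traj a [TumorTrajectory-class] object.
#' @param threshold volume threshold (mm^3), default 1e-3.
#' @return logical.
#' @export
isEradicated <- function(traj, threshold = 1e-3) {
  stopifnot(is(traj, "TumorTrajectory"))
  tot <- totalVolume(traj)
  tot[which.max(traj@times)] < threshold
}

#' Write a trajectory to CSV
#'
#' Columns: `time_days, v1..v4, u1, u2, ir_tot_gy, total_mm3`.
#'
#' @param traj a [TumorTrajectory-class] object.
#' @param path CSV file path.
#' @export
writeTrajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' Caliper tumor volume
#'
#' Standard xenograft caliper formula `V = L W^2 / 2`. If a width exceeds its
#' length the two are swapped with a warning.
#'
#' @param length tumor length (mm, >= 0); vectorised.
#' @param width tumor width (mm, >= 0); vectorised.
#' @return volume (mm^3).
#' @examples
#' caliperVolume(12, 8)   # 384
#' @export
caliperVolume <- function(length, width) {
  if (any(length < 0) || any(width < 0)) stop("negative caliper measurements")
  swap <- width > length
  if (any(swap)) {
    warning("width > length for some measurements; swapping", call. = FALSE)
    tmp <- length[swap]
    length[swap] <- width[swap]
    width[swap] <- tmp
  }
  length * width^2 / 2
}
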