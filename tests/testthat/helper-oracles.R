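# Independent oracles and small builders used across the suite.

refParams <- function(...) modelParameters(...)

# Pure-R right-hand side of the continuous system (independent of the
# compiled engine): state x = (v1, v2, v3, v4, u1, u2), inhibition frozen at
# the current accumulated dose.
tumorRHS <- function(t, x, parms) {
  kg <- parms$kg; kk <- parms$kk
  inhib <- exp(-parms$gamma * parms$irTot)
  list(c(
    (kg * inhib - kk) * x[1],
    kk * (x[1] + x[5] + x[6]) - kk * x[2],
    kk * (x[2] - x[3]),
    kk * (x[3] - x[4]),
    -(kg + kk) * x[5],
    2 * kg * x[5] - kk * x[6]))
}

# Adaptive numerical integration of one between-event segment (deSolve).
odeSegment <- function(x, dt, params, irTot, rtol = 1e-10, atol = 1e-12) {
  parms <- list(kg = params@kg, kk = params@kk, gamma = params@gamma,
                irTot = irTot)
  out <- deSolve::lsoda(x, c(0, dt), tumorRHS, parms,
                        rtol = rtol, atol = atol)
  unname(out[nrow(out), -1])
}

# Full-trajectory oracle: deSolve segments + explicit jump algebra, written
# against the model equations only (no engine, no propagateState).
odeSimulate <- function(params, schedule, obsTimes, concAtEvents = NULL) {
  ev <- schedule@events
  if (is.null(concAtEvents)) concAtEvents <- rep(0, nrow(ev))
  beta <- betaOf(params)
  st <- initialState(params)
  x <- c(st@v1, st@v2, st@v3, st@v4, st@u1, st@u2)
  irTot <- 0
  t <- 0
  ei <- 1L
  totals <- numeric(length(obsTimes))
  for (oi in seq_along(obsTimes)) {
    to <- obsTimes[oi]
    while (ei <= nrow(ev) && ev$time[ei] < to) {
      if (ev$time[ei] > t) x <- odeSegment(x, ev$time[ei] - t, params, irTot)
      t <- ev$time[ei]
      D <- ev$radiationGy[ei]; C <- concAtEvents[ei]
      f <- 1 - exp(-(1 + params@a * C) * (params@alpha * D + beta * D^2))
      x[5] <- x[5] + f * x[1]
      x[1] <- x[1] * (1 - f)
      irTot <- irTot + (1 + params@b * C) * D
      ei <- ei + 1L
    }
    if (to > t) x <- odeSegment(x, to - t, params, irTot)
    t <- to
    totals[oi] <- sum(x)
  }
  totals
}

# exponential-growth slope of a log-volume series
logSlope <- function(times, volumes) {
  unname(stats::coef(stats::lm(log(volumes) ~ times))[2L])
}

smallDesign <- function(arms = c("vehicle", "radiation"), nPerArm = 3,
                        seed = 5, nWeeksTreatment = 3, nWeeksFollowup = 3) {
  all <- data.frame(label = c("vehicle", "radiation", "combo25", "combo100"),
                    radiationGy = c(0, 2, 2, 2),
                    sensitizerMgPerKg = c(0, 0, 25, 100),
                    stringsAsFactors = FALSE)
  studyDesign(arms = all[all$label %in% arms, ], nPerArm = nPerArm,
              nWeeksTreatment = nWeeksTreatment,
              nWeeksFollowup = nWeeksFollowup, seed = seed)
}
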