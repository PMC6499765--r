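test_that("initial state follows the geometric distribution", {
  st <- initialState(refParams())
  expect_equal(c(st@v1, st@v2, st@v3, st@v4),
               c(27, 17.55, 11.4075, 7.414875))
  expect_equal(totalVolume(st), 63.37238, tolerance = 1e-6)
  expect_equal(c(st@u1, st@u2, st@irTot), c(0, 0, 0))
  stK0 <- initialState(refParams(kk = 0))
  expect_equal(c(stK0@v1, stK0@v2, stK0@v3, stK0@v4), c(27, 0, 0, 0))
  expect_equal(totalVolume(initialState(refParams(v0 = 0))), 0)
  expect_warning(p <- refParams(kg = 0.2, kk = 0.3), "does not grow")
  expect_warning(initialState(p), "shrinks")
})

test_that("irradiation jumps conserve volume and accumulate effective dose", {
  p <- refParams()
  st <- initialState(refParams(v0 = 100, kk = 0))   # v1 = 100, rest 0
  post <- applyIrradiation(st, D = 2, C = 0, params = p)
  expect_equal(post@v1, 82.13549, tolerance = 1e-5)
  expect_equal(post@u1, 17.86451, tolerance = 1e-5)
  expect_equal(post@irTot, 2)
  expect_equal(totalVolume(post), totalVolume(st))
  # D = 0 leaves the state untouched
  same <- applyIrradiation(st, 0, 5, p)
  expect_equal(totalVolume(same), totalVolume(st))
  expect_equal(same@v1, st@v1)
  # conservation across random states and exposures
  set.seed(4)
  for (i in 1:10) {
    sti <- propagateState(initialState(refParams(v0 = runif(1, 5, 200))),
                          runif(1, 0, 10), p)
    D <- runif(1, 0, 10); C <- runif(1, 0, 10)
    expect_equal(totalVolume(applyIrradiation(sti, D, C, p)),
                 totalVolume(sti), tolerance = 1e-12)
  }
})

test_that("untreated propagation is exactly exponential from the eigen initial state", {
  p <- refParams()
  st <- initialState(p)
  v0tot <- totalVolume(st)
  for (t in c(0.5, 5, 17.3, 42, 60)) {
    expect_equal(totalVolume(propagateState(st, t, p)),
                 v0tot * exp(0.14 * t), tolerance = 1e-9)
  }
  # 5 days of growth from the reference initial volume
  expect_equal(totalVolume(propagateState(st, 5, p)), 127.6163,
               tolerance = 1e-6)
  traj <- simulateTumor(p, treatmentSchedule(), seq(0, 60, by = 2.5))
  expect_equal(totalVolume(traj), v0tot * exp(0.14 * seq(0, 60, by = 2.5)),
               tolerance = 1e-9)
})

test_that("degenerate propagation cases behave as identities", {
  p <- refParams()
  st <- propagateState(initialState(p), 3, p)
  same <- propagateState(st, 0, p)
  expect_equal(totalVolume(same), totalVolume(st))
  expect_error(propagateState(st, -1, p), "non-negative")
  # frozen system: kg = kk = 0 keeps a pure-u1 state constant
  suppressWarnings(pz <- refParams(kg = 0, kk = 0))
  stU <- applyIrradiation(
    new("TumorState", v1 = 0, v2 = 0, v3 = 0, v4 = 0, u1 = 1, u2 = 0,
        irTot = 0), 0, 0, pz)
  moved <- propagateState(stU, 7, pz)
  expect_equal(c(moved@u1, moved@u2, totalVolume(moved)), c(1, 0, 1))
})

test_that("closed-form propagation agrees with an adaptive ODE integrator", {
  skip_if_not_installed("deSolve")
  set.seed(20)
  for (i in 1:5) {
    p <- refParams(kg = runif(1, 0.2, 0.8), kk = runif(1, 0.05, 0.18),
                   v0 = runif(1, 10, 100), gamma = runif(1, 0.001, 0.02))
    st <- initialState(p)
    st <- applyIrradiation(st, runif(1, 0, 6), runif(1, 0, 8), p)
    dt <- runif(1, 0.5, 4)
    prop <- propagateState(st, dt, p)
    ode <- odeSegment(c(st@v1, st@v2, st@v3, st@v4, st@u1, st@u2), dt, p,
                      st@irTot)
    expect_equal(c(prop@v1, prop@v2, prop@v3, prop@v4, prop@u1, prop@u2),
                 ode, tolerance = 1e-6)
  }
})

test_that("full trajectories match the segment-wise ODE oracle", {
  skip_if_not_installed("deSolve")
  p <- refParams()
  pk <- pkParameters()
  sched <- monFriSchedule(2, 25, nWeeks = 2)
  tt <- seq(0, 28, by = 1.75)
  conc <- eventConcentrations(sched, pk)
  expect_equal(totalVolume(simulateTumor(p, sched, tt, pk)),
               odeSimulate(p, sched, tt, conc), tolerance = 1e-6)
})

test_that("untreated simulation reproduces the five-day doubling time", {
  p <- refParams()
  traj <- simulateTumor(p, treatmentSchedule(), seq(0, 35, by = 3.5))
  dt <- log(2) / logSlope(traj@times, totalVolume(traj))
  expect_equal(dt, 4.951051, tolerance = 1e-6)
})

test_that("fractionated radiotherapy slows regrowth to the predicted net rate", {
  p <- refParams()
  sched <- monFriSchedule(2)     # 30 x 2 Gy
  tt <- seq(0, 130, by = 1)
  traj <- simulateTumor(p, sched, tt)
  tail <- tt >= 100   # transit transients have decayed by then
  rate <- logSlope(tt[tail], totalVolume(traj)[tail])
  expect_equal(rate, 0.40 * exp(-0.24) - 0.26, tolerance = 1e-5)
  expect_lt(rate, 0.14)          # slower than control regrowth
  # strong long-term inhibition flips the sign: monotone decline after arrest
  pHot <- refParams(gamma = 0.02)
  trajHot <- simulateTumor(pHot, sched, tt)
  totHot <- totalVolume(trajHot)
  expect_true(all(diff(totHot[tt >= 50]) < 0))
})

test_that("response is monotone in fraction size and sensitizer dose", {
  p <- refParams()
  pk <- pkParameters()
  atDay80 <- sapply(c(0, 25, 100), function(s)
    sapply(c(0, 1, 2, 4), function(d) {
      sched <- if (d == 0 && s == 0) treatmentSchedule()
               else monFriSchedule(d, s)
      tail(totalVolume(simulateTumor(p, sched, c(0, 80), pk)), 1)
    }))
  expect_true(all(apply(atDay80, 2, diff) <= 0))   # more Gy, less volume
  expect_true(all(apply(atDay80, 1, diff) <= 1e-6)) # more drug, less volume
})

test_that("with gamma 0 a single fraction only transiently depresses growth", {
  p <- refParams(gamma = 0)
  sched <- treatmentSchedule(time = 0, radiationGy = 2)
  tt <- seq(0, 80, by = 1)
  tot <- totalVolume(simulateTumor(p, sched, tt))
  expect_equal(logSlope(tt[tt >= 50], tot[tt >= 50]), 0.14,
               tolerance = 1e-4)
})

test_that("caliper volume formula handles its edge cases", {
  expect_equal(caliperVolume(10, 10), 500)
  expect_equal(caliperVolume(0, 0), 0)
  expect_equal(caliperVolume(12, 8), 384)
  expect_warning(v <- caliperVolume(8, 12), "swap")
  expect_equal(v, 384)
  expect_error(caliperVolume(-1, 1), "negative")
})

test_that("trajectory events record continuous totals and observation order is preserved", {
  p <- refParams()
  traj <- simulateTumor(p, monFriSchedule(2), seq(0, 60, 5))
  expect_equal(traj@events$totalPre, traj@events$totalPost,
               tolerance = 1e-12)
  # unsorted observation times come back in the caller's order
  tt <- c(30, 0, 60, 10)
  tr2 <- simulateTumor(p, monFriSchedule(2), tt)
  expect_equal(tr2@times, tt)
  # observation before treatment start: exact exponential back-step
  tr3 <- simulateTumor(p, monFriSchedule(2), c(-5, 0))
  expect_equal(totalVolume(tr3)[1], 63.37238 * exp(-0.14 * 5),
               tolerance = 1e-6)
  expect_error(
    simulateTumor(p, treatmentSchedule(c(1, 1), 2), c(0, 10)),
    "strictly increasing")
})
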