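test_that("combined residual error follows its closed form", {
  pop <- populationParameters()
  expect_equal(residualSD(0, pop), 6.9)
  expect_equal(residualSD(100, pop), sqrt(24^2 + 6.9^2))
  expect_equal(residualSD(100, pop), 24.97218, tolerance = 1e-6)
  pop0 <- populationParameters(sigmaProp = 0, sigmaAdd = 5)
  expect_equal(residualSD(c(0, 50, 1000), pop0), rep(5, 3))
  expect_error(residualSD(-1, pop), "negative")
})

test_that("individual -2LL behaves like a Gaussian likelihood", {
  p <- refParams()
  pop <- populationParameters()
  sched <- monFriSchedule(2)
  tt <- seq(0, 40, by = 5)
  pred <- totalVolume(simulateTumor(p, sched, tt))
  sd <- residualSD(pred, pop)
  dat <- data.frame(time_days = tt, volume_mm3 = pred)
  # zero residuals: only the normalisation term remains
  expect_equal(individualNeg2LL(p, dat, sched, pop),
               sum(log(2 * pi * sd^2)), tolerance = 1e-10)
  # displacing one observation by +1 SD raises -2LL by exactly 1
  dat1 <- dat
  dat1$volume_mm3[3] <- dat1$volume_mm3[3] + sd[3]
  expect_equal(individualNeg2LL(p, dat1, sched, pop) -
               individualNeg2LL(p, dat, sched, pop), 1, tolerance = 1e-10)
  # invariant to observation order
  shuf <- dat1[sample(nrow(dat1)), ]
  expect_equal(individualNeg2LL(p, shuf, sched, pop),
               individualNeg2LL(p, dat1, sched, pop))
})

test_that("noise-free single-animal data reduce to least squares and recover the rates", {
  truth <- populationParameters()
  sched <- monFriSchedule(2)
  tt <- seq(0, 80, by = 3.5)
  pred <- totalVolume(simulateTumor(truth@fixed, sched, tt))
  obs <- data.frame(animal_id = "m1", arm = "radiation", time_days = tt,
                    volume_mm3 = pred)
  dosing <- data.frame(animal_id = "m1", time_days = sched@events$time,
                       radiation_gy = sched@events$radiationGy,
                       sensitizer_mg_per_kg = 0)
  # additive-only residual with omegas pinned at zero: a pure NLS limit
  # (local problem: start within +-12% of the generating rates)
  init <- populationParameters(
    modelParameters(kg = 0.44, kk = 0.29, v0 = 27, alpha = 0.082),
    omega = c(v0 = 0, gamma = 0, alpha = 0), sigmaProp = 0, sigmaAdd = 6.9)
  fit <- suppressWarnings(fitPopulation(
    obs, dosing, init = init,
    fixed = c("v0", "gamma", "alpha", "a", "b",
              "omega_v0", "omega_gamma", "omega_alpha",
              "sigma_prop", "sigma_add"),
    control = list(maxit = 300, relTol = 1e-10)))
  expect_lt(abs(fit@estimates@fixed@kg - 0.40) / 0.40, 0.01)
  expect_lt(abs(fit@estimates@fixed@kk - 0.26) / 0.26, 0.01)
  expect_true(all(diff(fit@trace) < 0))  # accepted steps only improve
})

test_that("conditional modes match an independent grid search", {
  pop <- populationParameters(omega = c(v0 = 0.35, gamma = 0.4, alpha = 0))
  des <- smallDesign(arms = "radiation", nPerArm = 1, seed = 17)
  sim <- generateStudy(pop, des)
  # evaluation-only run: EBEs at the fixed truth
  fit <- suppressWarnings(fitPopulation(
    sim$observations, sim$dosing, init = pop,
    fixed = c("kg", "kk", "v0", "gamma", "alpha", "a", "b",
              "omega_v0", "omega_gamma", "omega_alpha",
              "sigma_prop", "sigma_add")))
  sched <- schedulesFromDosing(sim$dosing)[[1]]
  dat <- sim$observations
  grid <- seq(-0.6, 0.6, by = 0.04)
  joint <- outer(grid, grid, Vectorize(function(e1, e2) {
    ind <- individualParameters(pop, c(e1, e2, 0))
    individualNeg2LL(ind, dat, sched, pop, pkParameters()) +
      e1^2 / pop@omega[["v0"]]^2 + e2^2 / pop@omega[["gamma"]]^2
  }))
  best <- which(joint == min(joint), arr.ind = TRUE)
  expect_lt(abs(grid[best[1]] - fit@ebes$etaV0[1]), 0.05)
  expect_lt(abs(grid[best[2]] - fit@ebes$etaGamma[1]), 0.05)
})

test_that("rate estimates tighten as the study grows", {
  # truth matches the fitted random-effect structure (BSV on v0 and gamma)
  truth <- populationParameters(
    omega = c(v0 = sqrt(log(1.25)), gamma = sqrt(log(1 + 0.46^2)),
              alpha = 0))
  fitAt <- function(nPerArm, nW, maxit) {
    des <- smallDesign(nPerArm = nPerArm, seed = 61,
                       nWeeksTreatment = nW, nWeeksFollowup = nW)
    sim <- generateStudy(truth, des)
    init <- populationParameters(
      modelParameters(kg = 0.52, kk = 0.34, v0 = 35, gamma = 0.0055,
                      alpha = 0.082),
      omega = c(v0 = 0.4, gamma = 0.4, alpha = 0))
    suppressWarnings(fitPopulation(
      sim$observations, sim$dosing, init = init,
      fixed = c("alpha", "a", "b", "omega_alpha"),
      control = list(maxit = maxit)))
  }
  small <- fitAt(2, 3, maxit = 80)
  large <- fitAt(6, 4, maxit = 80)
  relErr <- function(fit) c(abs(fit@estimates@fixed@kg - 0.40) / 0.40,
                            abs(fit@estimates@fixed@kk - 0.26) / 0.26)
  expect_true(all(relErr(small) < 0.25))
  expect_true(all(relErr(large) < 0.10))
})

test_that("zero true potencies are recovered with intervals covering zero", {
  truth <- populationParameters(
    modelParameters(a = 0, b = 0),
    omega = c(v0 = sqrt(log(1.25)), gamma = sqrt(log(1 + 0.46^2)),
              alpha = 0))
  des <- smallDesign(arms = c("vehicle", "radiation", "combo100"),
                     nPerArm = 3, seed = 23)
  sim <- generateStudy(truth, des)
  init <- populationParameters(
    modelParameters(kg = 0.45, kk = 0.3, v0 = 30, gamma = 0.005,
                    alpha = 0.07, a = 0.1, b = 0.1),
    omega = c(v0 = 0.4, gamma = 0.4, alpha = 0))
  fit <- suppressWarnings(fitPopulation(
    sim$observations, sim$dosing, init = init, computeSE = TRUE,
    fixed = c("omega_alpha"),
    control = list(maxit = 60)))
  expect_true(all(c("a", "b") %in% names(fit@se)))
  est <- c(a = fit@estimates@fixed@a, b = fit@estimates@fixed@b)
  for (nm in c("a", "b")) {
    # Wald test: potency not significantly different from zero
    expect_false(is.na(fit@se[[nm]]))
    expect_lt(est[[nm]] / fit@se[[nm]], 1.96)
  }
})

test_that("shrinkage diagnostics behave at their limits", {
  pop <- populationParameters()
  mkEbes <- function(etas) data.frame(etaV0 = etas[, 1], etaGamma = etas[, 2],
                                      etaAlpha = etas[, 3])
  allZero <- mkEbes(matrix(0, 20, 3))
  expect_equal(unname(ebeShrinkage(allZero, pop)), rep(1, 3))
  set.seed(8)
  drawn <- mkEbes(matrix(rnorm(3 * 2000), ncol = 3) %*%
                  diag(pop@omega[c("v0", "gamma", "alpha")]))
  expect_true(all(abs(ebeShrinkage(drawn, pop)) < 0.1))
  pop0 <- populationParameters(omega = c(v0 = 0.3, gamma = 0.3, alpha = 0))
  expect_true(is.na(ebeShrinkage(allZero, pop0)[["alpha"]]))
})

test_that("visual predictive check collapses without variability and is seeded", {
  des <- smallDesign(nPerArm = 2, seed = 3)
  des@censoringCap <- 1e6
  pop0 <- populationParameters(omega = c(v0 = 0, gamma = 0, alpha = 0),
                               sigmaProp = 0, sigmaAdd = 0)
  v0 <- vpc(pop0, des, nReplicates = 5)
  expect_equal(v0$bands$lower, v0$bands$upper)
  expect_equal(v0$bands$lower, v0$bands$median)
  pop <- populationParameters()
  v1 <- vpc(pop, des, nReplicates = 10)
  v2 <- vpc(pop, des, nReplicates = 10)
  expect_identical(v1$bands, v2$bands)
})

test_that("observed medians fall inside the predictive bands of the generating model", {
  pop <- populationParameters()
  des <- smallDesign(nPerArm = 4, seed = 301)
  des@censoringCap <- 1e6
  obsDes <- des
  obsDes@seed <- 9000
  simObs <- generateStudy(pop, obsDes)
  v <- vpc(pop, des, nReplicates = 100, observed = simObs$observations)
  expect_gte(v$coverage, 0.9)
})
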