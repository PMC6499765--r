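test_that("net growth rate evaluates its closed form and limits", {
  p <- refParams()
  expect_equal(netGrowthRate(0, 0, p), 0.14)
  expect_equal(netGrowthRate(60, 0, p), 0.40 * exp(-0.24) - 0.26)
  expect_equal(netGrowthRate(1e7, 0, p), -0.26)
  expect_error(netGrowthRate(-1, 0, p), "negative")
})

test_that("stasis doses match the closed-form evaluations", {
  p <- refParams()
  expect_equal(tseDose(0, p), log(0.40 / 0.26) / 0.004)
  expect_equal(tseDose(0, p), 107.6957, tolerance = 1e-6)
  expect_equal(tseDose(2, p), 107.6957 / 1.3, tolerance = 1e-6)
  expect_equal(tseDose(0, p, targetRate = 0.14), 0)
  expect_error(tseDose(0, p, targetRate = 0.15), "no finite")
  expect_error(tseDose(0, p, targetRate = -0.26), "no finite")
  expect_error(tseDose(0, refParams(gamma = 0)), "gamma")
})

test_that("dose-for-concentration is the exact inverse with clipping", {
  p <- refParams()
  for (C in c(0.5, 2, 8)) {
    expect_equal(as.numeric(tseConcentration(tseDose(C, p), p)), C,
                 tolerance = 1e-10)
  }
  c0 <- tseConcentration(107.6957, p)
  expect_equal(as.numeric(c0), 0, tolerance = 1e-4)
  c200 <- tseConcentration(200, p)
  expect_equal(as.numeric(c200), 0)
  expect_true(attr(c200, "radiationSufficient"))
  expect_error(tseConcentration(0, p), "positive")
})

test_that("stasis is an exact root of the net rate over the curve", {
  p <- refParams()
  cc <- seq(0, 10, by = 0.25)
  expect_equal(netGrowthRate(tseDose(cc, p), cc, p), rep(0, length(cc)),
               tolerance = 1e-14)
  curve <- tseCurve(p, cc)
  expect_true(all(diff(curve@doses) < 0))     # potency makes doses fall
  # convex in concentration: second differences non-negative
  expect_true(all(diff(diff(curve@doses)) >= 0))
})

test_that("shrinkage isoclines nest with the target rate", {
  p <- refParams()
  cc <- seq(0, 8, by = 0.5)
  dShrink <- tseDose(cc, p, targetRate = -0.1)
  dStasis <- tseDose(cc, p, targetRate = 0)
  dGrow <- tseDose(cc, p, targetRate = 0.1)
  expect_true(all(dShrink > dStasis))
  expect_true(all(dStasis > dGrow))
})

test_that("the heat map matches the TSE curve on its zero contour", {
  p <- refParams()
  cGrid <- seq(0, 10, length.out = 41)
  dGrid <- seq(0, 200, length.out = 81)
  hm <- tseHeatmap(p, cGrid, dGrid)
  expect_equal(hm[1, 1], 0.14)
  expect_equal(dim(hm), c(81, 41))
  # at every grid concentration the sign change brackets the stasis dose
  for (j in seq_along(cGrid)) {
    dStar <- tseDose(cGrid[j], p)
    below <- dGrid < dStar
    expect_true(all(hm[below, j] > 0))
    expect_true(all(hm[!below, j] < 0 | dGrid[!below] == dStar))
  }
  # rates on the map convert to doubling/half times: 0.1/day ~ 7 days
  expect_equal(round(log(2) / 0.1), 7)
  expect_error(tseHeatmap(p, numeric(), dGrid), "empty")
})

test_that("net-rate timelines step down with accumulating dose", {
  p <- refParams()
  pk <- pkParameters()
  scheds <- list(vehicle = treatmentSchedule(),
                 radiation = monFriSchedule(2),
                 combo100 = monFriSchedule(2, 100))
  tl <- netRateTimeline(p, scheds, pk)
  veh <- tl[tl$arm == "vehicle", ]
  expect_equal(veh$knet, 0.14)
  rad <- tl[tl$arm == "radiation", ]
  expect_equal(tail(rad$knet, 1), 0.40 * exp(-0.24) - 0.26, tolerance = 1e-12)
  expect_true(all(rad$knet > 0))                  # never negative: regrowth
  combo <- tl[tl$arm == "combo100", ]
  expect_lt(tail(combo$knet, 1), 0)               # eradication regime
  for (arm in unique(tl$arm))
    expect_true(all(diff(tl$knet[tl$arm == arm]) <= 0))
})

test_that("identical individuals collapse the population fan", {
  p <- refParams()
  fan <- populationTSE(list(p, p, p), concentrations = seq(0, 4, 1))
  expect_equal(fan$curves[1, ], fan$curves[2, ])
  expect_equal(fan$curves[3, ], fan$medianCurve@doses)
  env <- as.matrix(fan$envelope[, -1])
  for (j in seq_len(ncol(env)))
    expect_equal(unname(env[, j]), unname(fan$curves[1, ]))
})

test_that("median-parameter curve tracks the pointwise median of a log-normal fan", {
  pop <- populationParameters()
  set.seed(91)
  n <- 200
  plist <- lapply(seq_len(n), function(i)
    individualParameters(pop, stats::rnorm(3) * pop@omega))
  fan <- populationTSE(plist, concentrations = c(0, 2))
  med <- apply(fan$curves, 2, stats::median)
  expect_equal(med, fan$medianCurve@doses, tolerance = 0.1)
})

test_that("the TSE curve is invariant under joint rate scaling", {
  p <- refParams()
  cc <- c(0, 0.5, 2, 8)
  for (s in c(0.1, 1, 10)) {
    ps <- allometricScale(p, s)
    expect_equal(tseDose(cc, ps), tseDose(cc, p), tolerance = 1e-14)
    expect_equal(netGrowthRate(0, 0, ps), s * 0.14, tolerance = 1e-14)
    # doubling time scales inversely
    expect_equal(log(2) / netGrowthRate(0, 0, ps),
                 (log(2) / 0.14) / s, tolerance = 1e-12)
  }
  expect_error(allometricScale(p, 0), "positive")
})

test_that("sensitivity analysis reproduces the closed-form shifts", {
  p <- refParams()
  sens <- tseSensitivity(p, 0.1, concentrations = c(0, 2))
  kgUp <- sens[sens$parameter == "kg" & sens$scale > 1 &
               sens$concentration == 0, ]
  expect_equal(kgUp$rel_change,
               log(1.1 * 0.40 / 0.26) / log(0.40 / 0.26) - 1,
               tolerance = 1e-12)
  expect_equal(kgUp$rel_change, 0.2212, tolerance = 1e-3)
  # gamma acts as a pure inverse scale: doubling it halves every dose
  pg <- refParams(gamma = 0.008)
  expect_equal(tseDose(c(0, 2, 8), pg), tseDose(c(0, 2, 8), p) / 2)
  # joint rate scaling cancels exactly
  ps <- allometricScale(p, 1.1)
  expect_equal(tseDose(0, ps) / tseDose(0, p), 1, tolerance = 1e-14)
  # rates dominate the exposure parameters at matched perturbation
  gUp <- sens[sens$parameter == "gamma" & sens$scale > 1 &
              sens$concentration == 0, ]
  expect_gt(abs(kgUp$rel_change), abs(gUp$rel_change))
})

test_that("the alternative short-term potency can drive the TSE expressions", {
  pa <- refParams(tsePotency = "a")
  expect_equal(tseDose(2, pa), 107.6957 / (1 + 0.42 * 2), tolerance = 1e-4)
  expect_equal(netGrowthRate(tseDose(2, pa), 2, pa), 0, tolerance = 1e-14)
})
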