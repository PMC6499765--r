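# Population (nonlinear mixed-effects) estimation for the tumor model.
#
# Random effects are log-normal on v0, gamma and alpha. The marginal
# likelihood is approximated by the Laplace method with a Gauss-Newton
# (FOCE-class) curvature at the per-individual conditional mode: for each
# animal the joint -2 log-density in eta is minimised (inner problem), and
# the log-determinant correction uses J'WJ + Omega^-1 with J the
# finite-difference sensitivity of the predicted volumes to eta. Inner modes
# are warm-started across outer iterations.

outerParNames <- c("kg", "kk", "v0", "gamma", "alpha", "a", "b",
                   "omega_v0", "omega_gamma", "omega_alpha",
                   "sigma_prop", "sigma_add")
outerLogScale <- c("kg", "kk", "v0", "gamma", "alpha",
                   "sigma_prop", "sigma_add")

popToVec <- function(pop) {
  f <- pop@fixed
  c(kg = f@kg, kk = f@kk, v0 = f@v0, gamma = f@gamma, alpha = f@alpha,
    a = f@a, b = f@b,
    omega_v0 = unname(pop@omega["v0"]),
    omega_gamma = unname(pop@omega["gamma"]),
    omega_alpha = unname(pop@omega["alpha"]),
    sigma_prop = pop@sigmaProp, sigma_add = pop@sigmaAdd)
}

vecToPop <- function(v, template) {
  fixed <- updateParameters(template@fixed,
    kg = v[["kg"]], kk = v[["kk"]], v0 = v[["v0"]],
    gamma = v[["gamma"]], alpha = v[["alpha"]],
    a = v[["a"]], b = v[["b"]])
  new("PopulationParameters", fixed = fixed,
      omega = c(v0 = v[["omega_v0"]], gamma = v[["omega_gamma"]],
                alpha = v[["omega_alpha"]]),
      sigmaProp = v[["sigma_prop"]], sigmaAdd = v[["sigma_add"]])
}

#' Residual standard deviation of the combined error model
#'
#' \deqn{sd(V) = \sqrt{(\sigma_{prop} V)^2 + \sigma_{add}^2}}
#'
#' @param predicted predicted volumes (mm^3, >= 0); vectorised.
#' @param pop a [PopulationParameters-class] object.
#' @return residual SD (mm^3).
#' @examples
#' residualSD(100, populationParameters())   # sqrt(24^2 + 6.9^2)
#' @export
residualSD <- function(predicted, pop) {
  stopifnot(is(pop, "PopulationParameters"))
  if (any(predicted < 0)) stop("negative predicted volumes")
  sqrt((pop@sigmaProp * predicted)^2 + pop@sigmaAdd^2)
}

# fast internal prediction of total volumes (sorted times >= 0)
predictTotals <- function(kg, kk, v0, alpha, beta, a, gamma, b, evm, times) {
  x0 <- c(v0 * (kk / kg)^(0:3), 0, 0)
  res <- .simulateEngine(x0, evm, times, kg, kk, alpha, beta, a, gamma, b)
  rowSums(res$obs[, 1:6, drop = FALSE])
}

eventMatrix <- function(schedule, pk) {
  ev <- schedule@events
  cbind(ev$time, ev$radiationGy, eventConcentrations(schedule, pk))
}

#' -2 log-likelihood of one animal's data given individual parameters
#'
#' Gaussian likelihood of the observed volumes around the simulated
#' trajectory under the combined proportional + additive error model.
#'
#' @param params individual [ModelParameters-class].
#' @param data `data.frame` with columns `time_days`, `volume_mm3`.
#' @param schedule the animal's [TreatmentSchedule-class].
#' @param pop a [PopulationParameters-class] (residual error source).
#' @param pk a [PKParameters-class] object, or `NULL`.
#' @return -2 log-likelihood (no random-effect prior term).
#' @export
individualNeg2LL <- function(params, data, schedule, pop, pk = NULL) {
  stopifnot(is(params, "ModelParameters"))
  ord <- order(data$time_days)
  traj <- simulateTumor(params, schedule, data$time_days[ord], pk)
  pred <- totalVolume(traj)
  sd <- residualSD(pred, pop)
  sum(log(2 * pi * sd^2) + ((data$volume_mm3[ord] - pred) / sd)^2)
}

# per-animal prepared data: list(times, y, evm)
prepareAnimals <- function(observations, dosing, pk,
                           sensitizerLeadTime = 0.5 / 24, blqLimit = NULL) {
  obs <- as.data.frame(observations)
  need <- c("animal_id", "time_days", "volume_mm3")
  if (!all(need %in% names(obs)))
    stop("observations need columns ", paste(need, collapse = ", "))
  if (!is.null(blqLimit) && "below_limit" %in% names(obs)) {
    # left-censored values imputed at half the quantification limit
    obs$volume_mm3[obs$below_limit] <- blqLimit / 2
  }
  scheds <- schedulesFromDosing(as.data.frame(dosing), sensitizerLeadTime)
  ids <- unique(obs$animal_id)
  out <- lapply(ids, function(id) {
    d <- obs[obs$animal_id == id, , drop = FALSE]
    d <- d[order(d$time_days), , drop = FALSE]
    sched <- scheds[[as.character(id)]]
    if (is.null(sched)) sched <- treatmentSchedule()
    horizon <- max(d$time_days)
    evm <- eventMatrix(sched, pk)
    evm <- evm[evm[, 1L] <= horizon, , drop = FALSE]
    list(id = id, times = d$time_days, y = d$volume_mm3, evm = evm,
         arm = if ("arm" %in% names(d)) d$arm[1L] else NA_character_)
  })
  names(out) <- as.character(ids)
  out
}

# Laplace-approximated -2 log marginal likelihood of one animal.
# Returns list(val, eta) with eta the conditional mode (length 3).
laplaceIndividual <- function(v, animal, etaStart, innerMaxit = 50,
                              omegaMin = 1e-8, h = 1e-4,
                              abRatio = 10, lqQuad = TRUE) {
  omega <- c(v[["omega_v0"]], v[["omega_gamma"]], v[["omega_alpha"]])
  active <- omega > omegaMin
  predFor <- function(eta3) {
    alphaI <- v[["alpha"]] * exp(eta3[3L])
    predictTotals(v[["kg"]], v[["kk"]], v[["v0"]] * exp(eta3[1L]),
                  alphaI, if (lqQuad) alphaI / abRatio else 0,
                  v[["a"]], v[["gamma"]] * exp(eta3[2L]), v[["b"]],
                  animal$evm, animal$times)
  }
  resid2 <- function(pred) {
    sd2 <- (v[["sigma_prop"]] * pred)^2 + v[["sigma_add"]]^2
    sum(log(2 * pi * sd2) + (animal$y - pred)^2 / sd2)
  }
  if (!any(active)) {
    pred <- predFor(c(0, 0, 0))
    return(list(val = resid2(pred), eta = c(0, 0, 0)))
  }
  d <- sum(active)
  priorConst <- sum(log(2 * pi * omega[active]^2))
  joint <- function(ea) {
    eta3 <- c(0, 0, 0)
    eta3[active] <- ea
    resid2(predFor(eta3)) + sum(ea^2 / omega[active]^2) + priorConst
  }
  inner <- stats::nlminb(etaStart[active], joint,
                         control = list(iter.max = innerMaxit))
  eta3 <- c(0, 0, 0)
  eta3[active] <- inner$par
  pred0 <- predFor(eta3)
  sd2 <- (v[["sigma_prop"]] * pred0)^2 + v[["sigma_add"]]^2
  J <- matrix(0, length(pred0), d)
  idx <- which(active)
  for (k in seq_len(d)) {
    etaH <- eta3
    etaH[idx[k]] <- etaH[idx[k]] + h
    J[, k] <- (predFor(etaH) - pred0) / h
  }
  Hl <- crossprod(J, J / sd2) + diag(1 / omega[idx]^2, d)
  ldet <- determinant(Hl, logarithm = TRUE)$modulus
  list(val = inner$objective - d * log(2 * pi) + as.numeric(ldet),
       eta = eta3)
}

#' Fit the population tumor model to longitudinal volume data
#'
#' Maximises the Laplace/FOCE-class approximate marginal likelihood over the
#' fixed effects, between-subject variances (on `v0`, `gamma`, `alpha`) and
#' the combined residual-error parameters, with an inner conditional-mode
#' search per animal. Positive-definite curvature is guaranteed by the
#' Gauss-Newton approximation, and inner modes are warm-started across outer
#' iterations. Strictly positive parameters are estimated on the log scale;
#' potencies `a`, `b` and the omegas are bounded below at 0 (boundary values
#' are reported, not dropped).
#'
#' @param observations `data.frame` with columns `animal_id`, `time_days`,
#'   `volume_mm3` (optionally `arm` and a logical `below_limit`).
#' @param dosing `data.frame` in the [readDosing()] schema.
#' @param init starting [PopulationParameters-class]; a naive starting point
#'   such as literature values or a pooled fit.
#' @param pk a [PKParameters-class] object, or `NULL`.
#' @param fixed character vector of parameter names (from
#'   `kg, kk, v0, gamma, alpha, a, b, omega_v0, omega_gamma, omega_alpha,
#'   sigma_prop, sigma_add`) held at their `init` values.
#' @param computeSE compute asymptotic standard errors from a
#'   finite-difference Hessian of the outer objective (costly).
#' @param blqLimit quantification limit (mm^3); observations flagged
#'   `below_limit` are imputed at `blqLimit/2`. `NULL` disables imputation.
#' @param sensitizerLeadTime days between sensitizer bolus and irradiation.
#' @param control list: `maxit` (outer iterations, default 100), `relTol`
#'   (default 1e-5), `innerMaxit` (default 50).
#' @return a [PopulationFit-class] object.
#' @seealso [parameterTable()], [ebeShrinkage()], [vpc()]
#' @export
fitPopulation <- function(observations, dosing,
                          init = populationParameters(),
                          pk = pkParameters(), fixed = character(),
                          computeSE = FALSE, blqLimit = 4,
                          sensitizerLeadTime = 0.5 / 24,
                          control = list()) {
  stopifnot(is(init, "PopulationParameters"))
  ctl <- utils::modifyList(list(maxit = 100, relTol = 1e-5, innerMaxit = 50),
                           control)
  bad <- setdiff(fixed, outerParNames)
  if (length(bad)) stop("unknown parameter names in 'fixed': ",
                        paste(bad, collapse = ", "))
  animals <- prepareAnimals(observations, dosing, pk, sensitizerLeadTime,
                            blqLimit)
  n <- length(animals)
  if (n < 1L) stop("no individuals in the dataset")
  freeOmega <- setdiff(c("omega_v0", "omega_gamma", "omega_alpha"), fixed)
  if (n < 2L && length(freeOmega))
    warning("fewer than 2 individuals: between-subject variances are not ",
            "identifiable; consider fixing the omegas", call. = FALSE)

  initVec <- popToVec(init)
  free <- setdiff(outerParNames, fixed)
  encode <- function(nat) {
    th <- nat[free]
    isLog <- free %in% outerLogScale
    th[isLog] <- log(th[isLog])
    th
  }
  decode <- function(th) {
    nat <- initVec
    isLog <- free %in% outerLogScale
    vals <- th
    vals[isLog] <- exp(vals[isLog])
    nat[free] <- vals
    nat
  }
  lower <- ifelse(free %in% outerLogScale, -Inf, 0)

  etaStore <- matrix(0, n, 3)
  lastEbes <- NULL
  trace <- numeric()
  objective <- function(th) {
    v <- decode(th)
    vals <- numeric(n)
    for (i in seq_len(n)) {
      li <- laplaceIndividual(v, animals[[i]], etaStore[i, ],
                              innerMaxit = ctl$innerMaxit,
                              abRatio = init@fixed@alphaBetaRatio,
                              lqQuad = init@fixed@lqQuadratic)
      vals[i] <- li$val
      etaStore[i, ] <<- li$eta
    }
    tot <- sum(vals)
    if (!length(trace) || tot < min(trace)) trace <<- c(trace, tot)
    lastEbes <<- vals
    tot
  }

  th0 <- encode(initVec)
  opt <- if (length(free)) {
    stats::nlminb(th0, objective, lower = lower,
                  control = list(iter.max = ctl$maxit,
                                 eval.max = 20 * ctl$maxit,
                                 rel.tol = ctl$relTol))
  } else {
    # evaluation-only mode: conditional modes (EBEs) at fixed parameters
    list(par = th0, convergence = 0, message = "all parameters fixed")
  }
  final <- objective(opt$par)  # refresh etaStore/contributions at optimum
  vOpt <- decode(opt$par)
  est <- vecToPop(vOpt, init)

  se <- numeric()
  rse <- numeric()
  if (computeSE && length(free)) {
    H <- stats::optimHess(opt$par, objective)
    cv <- try(2 * solve(H), silent = TRUE)
    if (inherits(cv, "try-error") || any(!is.finite(diag(cv)))) {
      # singular information (e.g. parameters at a boundary): fall back to a
      # pseudo-inverse and report what is estimable
      warning("outer Hessian is singular; standard errors use a ",
              "pseudo-inverse", call. = FALSE)
      eg <- eigen(H, symmetric = TRUE)
      pos <- eg$values > max(eg$values) * 1e-10
      cv <- 2 * eg$vectors[, pos, drop = FALSE] %*%
        (t(eg$vectors[, pos, drop = FALSE]) / eg$values[pos])
    }
    d2 <- diag(cv)
    seT <- ifelse(d2 > 0, sqrt(pmax(d2, 0)), NA_real_)
    names(seT) <- free
    isLog <- free %in% outerLogScale
    se <- ifelse(isLog, seT * vOpt[free], seT)
    names(se) <- free
    rse <- 100 * se / ifelse(vOpt[free] == 0, NA_real_, abs(vOpt[free]))
    names(rse) <- free
  }

  msg <- if (is.null(opt$message)) "" else opt$message
  omegaOpt <- vOpt[c("omega_v0", "omega_gamma", "omega_alpha")]
  atBound <- names(omegaOpt)[omegaOpt < 1e-6 &
                             !names(omegaOpt) %in% fixed]
  if (length(atBound))
    msg <- paste(msg, sprintf("omegas at boundary: %s",
                              paste(atBound, collapse = ", ")))

  ebes <- data.frame(
    animal_id = vapply(animals, function(a) as.character(a$id), character(1)),
    arm = vapply(animals, function(a) as.character(a$arm), character(1)),
    etaV0 = etaStore[, 1L], etaGamma = etaStore[, 2L],
    etaAlpha = etaStore[, 3L],
    v0 = vOpt[["v0"]] * exp(etaStore[, 1L]),
    gamma = vOpt[["gamma"]] * exp(etaStore[, 2L]),
    alpha = vOpt[["alpha"]] * exp(etaStore[, 3L]),
    objective = lastEbes,
    row.names = NULL)

  new("PopulationFit", estimates = est, se = se, rse = rse, ebes = ebes,
      neg2ll = final, trace = trace, convergence = as.numeric(opt$convergence),
      message = msg, fixedNames = fixed)
}

setMethod("show", "PopulationFit", function(object) {
  cat(sprintf("Population fit: -2LL = %.4f, convergence %d (%s)\n",
              object@neg2ll, as.integer(object@convergence), object@message))
  print(parameterTable(object))
})

#' Parameter table of a population fit
#'
#' One row per parameter: population estimate, relative standard error
#' (percent, when computed), and for the three random-effect parameters the
#' between-subject variability as a CV percentage.
#'
#' @param fit a [PopulationFit-class] object.
#' @return `data.frame` with columns `parameter`, `estimate`, `rse_pct`,
#'   `bsv_cv_pct`, `bsv_rse_pct`, `fixed`.
#' @export
parameterTable <- function(fit) {
  stopifnot(is(fit, "PopulationFit"))
  v <- popToVec(fit@estimates)
  struct <- c("kg", "kk", "v0", "gamma", "alpha", "a", "b",
              "sigma_prop", "sigma_add")
  getRse <- function(nm) {
    if (nm %in% names(fit@rse)) unname(fit@rse[nm]) else NA_real_
  }
  bsvFor <- c(v0 = "omega_v0", gamma = "omega_gamma", alpha = "omega_alpha")
  bsv <- vapply(struct, function(nm) {
    if (nm %in% names(bsvFor))
      100 * sqrt(exp(v[[bsvFor[[nm]]]]^2) - 1) else NA_real_
  }, numeric(1))
  bsvRse <- vapply(struct, function(nm) {
    if (nm %in% names(bsvFor)) getRse(bsvFor[[nm]]) else NA_real_
  }, numeric(1))
  data.frame(parameter = struct,
             estimate = unname(v[struct]),
             rse_pct = vapply(struct, getRse, numeric(1)),
             bsv_cv_pct = bsv,
             bsv_rse_pct = bsvRse,
             fixed = struct %in% fit@fixedNames,
             row.names = NULL)
}

#' Empirical-Bayes shrinkage per random effect
#'
#' `1 - SD(eta)/omega` for each of the three random effects. Values near 0
#' mean the data determine the individual deviations; values near 1 mean the
#' EBEs collapse to the population median. Undefined (NA) when `omega` is 0.
#'
#' @param fit a [PopulationFit-class] object, or a `data.frame` of EBEs with
#'   columns `etaV0`, `etaGamma`, `etaAlpha` (then `pop` is required).
#' @param pop [PopulationParameters-class]; defaults to the fit's estimates.
#' @return named numeric (`v0`, `gamma`, `alpha`) of shrinkage fractions.
#' @export
ebeShrinkage <- function(fit, pop = NULL) {
  if (is(fit, "PopulationFit")) {
    ebes <- fit@ebes
    if (is.null(pop)) pop <- fit@estimates
  } else {
    ebes <- as.data.frame(fit)
    if (is.null(pop)) stop("'pop' is required when passing a raw EBE table")
  }
  omega <- pop@omega[c("v0", "gamma", "alpha")]
  etas <- cbind(v0 = ebes$etaV0, gamma = ebes$etaGamma, alpha = ebes$etaAlpha)
  out <- vapply(c("v0", "gamma", "alpha"), function(nm) {
    if (omega[[nm]] <= 0) return(NA_real_)
    1 - stats::sd(etas[, nm]) / omega[[nm]]
  }, numeric(1))
  out
}

#' Visual predictive check
#'
#' Simulates `nReplicates` full studies from the population model at the
#' given design, computes per-arm prediction quantiles of volume at each
#' measurement time across replicates, and (when observed data are supplied)
#' overlays the observed quantiles and reports the fraction of arm-time bins
#' whose observed median falls inside the simulated-median band.
#'
#' @param pop a [PopulationParameters-class] object.
#' @param design a [StudyDesign-class] object.
#' @param pk a [PKParameters-class] object.
#' @param nReplicates number of replicate studies (>= 100 recommended).
#' @param seed RNG seed for the replicate simulations.
#' @param observed optional observations `data.frame` (generator schema).
#' @param probs prediction quantiles (default 5/50/95 percent).
#' @param level confidence level of the across-replicate band.
#' @return list with `bands` (`data.frame`: arm, time, quantile, lower,
#'   median, upper, observed) and `coverage` (fraction of bins where the
#'   observed median lies in the simulated-median band; `NA` without
#'   observations).
#' @export
vpc <- function(pop, design, pk = pkParameters(), nReplicates = 200,
                seed = 1, observed = NULL, probs = c(0.05, 0.5, 0.95),
                level = 0.95) {
  stopifnot(is(pop, "PopulationParameters"), is(design, "StudyDesign"))
  repQ <- vector("list", nReplicates)
  for (r in seq_len(nReplicates)) {
    des <- design
    des@seed <- (design@seed + r) %% .Machine$integer.max
    sim <- generateStudy(pop, des, pk)
    o <- sim$observations
    agg <- stats::aggregate(o$volume_mm3,
                            by = list(arm = o$arm, time = o$time_days),
                            FUN = stats::quantile, probs = probs)
    q <- data.frame(arm = agg$arm, time = agg$time,
                    as.data.frame(agg$x, check.names = FALSE))
    names(q)[-(1:2)] <- paste0("q", probs)
    repQ[[r]] <- q
  }
  allq <- do.call(rbind, repQ)
  alphaHalf <- (1 - level) / 2
  rows <- list()
  for (p in probs) {
    col <- paste0("q", p)
    agg <- stats::aggregate(allq[[col]],
                            by = list(arm = allq$arm, time = allq$time),
                            FUN = function(x)
                              c(lower = unname(stats::quantile(x, alphaHalf)),
                                median = stats::median(x),
                                upper = unname(stats::quantile(x,
                                                               1 - alphaHalf))))
    rows[[col]] <- data.frame(arm = agg$arm, time = agg$time, quantile = p,
                              lower = agg$x[, "lower"],
                              median = agg$x[, "median"],
                              upper = agg$x[, "upper"])
  }
  bands <- do.call(rbind, rows)
  rownames(bands) <- NULL
  bands$observed <- NA_real_
  coverage <- NA_real_
  if (!is.null(observed)) {
    o <- as.data.frame(observed)
    for (i in seq_len(nrow(bands))) {
      sel <- o$arm == bands$arm[i] & o$time_days == bands$time[i]
      if (any(sel))
        bands$observed[i] <- unname(
          stats::quantile(o$volume_mm3[sel], bands$quantile[i]))
    }
    med <- bands[bands$quantile == 0.5 & !is.na(bands$observed), ]
    if (nrow(med))
      coverage <- mean(med$observed >= med$lower & med$observed <= med$upper)
  }
  list(bands = bands, coverage = coverage)
}
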