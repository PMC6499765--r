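#' Construct tumor model parameters
#'
#' Defaults are the packaged reference estimates from a FaDu xenograft study
#' of fractionated 2 Gy radiotherapy combined with a DNA-damage-repair
#' inhibitor: `kg` = 0.40/day, `kk` = 0.26/day, `v0` = 27 mm^3,
#' `gamma` = 0.004/Gy, `alpha` = 0.082/Gy, `a` = 0.42 mL/ug,
#' `b` = 0.15 mL/ug, alpha/beta = 10 Gy.
#'
#' @param kg,kk growth and kill rates (1/day). A growing untreated tumor needs
#'   `kg > kk`; the constructor warns (does not fail) otherwise.
#' @param v0 initial proliferating-compartment scale (mm^3).
#' @param alpha linear LQ coefficient (1/Gy).
#' @param alphaBetaRatio alpha/beta ratio (Gy); `beta = alpha/alphaBetaRatio`.
#' @param a sensitizer potency on the instantaneous-kill effect (mL/ug).
#' @param gamma long-term growth-inhibition coefficient (1/Gy).
#' @param b sensitizer potency on the long-term effect (mL/ug).
#' @param lqQuadratic include the quadratic LQ term (default `TRUE`).
#' @param tsePotency potency used in static-exposure expressions: `"b"`
#'   (default, the long-term potency) or `"a"`.
#' @return a [ModelParameters-class] object.
#' @examples
#' p <- modelParameters()
#' betaOf(p)                      # alpha/10
#' modelParameters(kg = 0.5, kk = 0.3)
#' @export
modelParameters <- function(kg = 0.40, kk = 0.26, v0 = 27.0,
                            alpha = 0.082, alphaBetaRatio = 10,
                            a = 0.42, gamma = 0.004, b = 0.15,
                            lqQuadratic = TRUE, tsePotency = "b") {
  obj <- new("ModelParameters", kg = kg, kk = kk, v0 = v0, alpha = alpha,
             alphaBetaRatio = alphaBetaRatio, a = a, gamma = gamma, b = b,
             lqQuadratic = lqQuadratic, tsePotency = tsePotency)
  if (kk >= kg)
    warning("kk >= kg: untreated tumor does not grow", call. = FALSE)
  obj
}

#' Quadratic LQ coefficient
#'
#' `beta` is never a free parameter; it is derived as `alpha/alphaBetaRatio`
#' (and is 0 when the quadratic term is switched off).
#'
#' @param params a [ModelParameters-class] object.
#' @return beta (1/Gy^2).
#' @export
betaOf <- function(params) {
  stopifnot(is(params, "ModelParameters"))
  if (params@lqQuadratic) params@alpha / params@alphaBetaRatio else 0
}

#' @describeIn modelParameters named vector of the structural parameters.
#' @param object a `ModelParameters` object.
#' @param ... ignored.
#' @export
setMethod("coef", "ModelParameters", function(object, ...) {
  c(kg = object@kg, kk = object@kk, v0 = object@v0, alpha = object@alpha,
    beta = betaOf(object), a = object@a, gamma = object@gamma, b = object@b)
})

setMethod("show", "ModelParameters", function(object) {
  cat("Tumor model parameters\n")
  cat(sprintf("  kg = %.4g /day, kk = %.4g /day (net %.4g /day)\n",
              object@kg, object@kk, object@kg - object@kk))
  cat(sprintf("  v0 = %.4g mm^3\n", object@v0))
  cat(sprintf("  alpha = %.4g /Gy (beta = %.4g /Gy^2, alpha/beta = %g Gy%s)\n",
              object@alpha, betaOf(object), object@alphaBetaRatio,
              if (object@lqQuadratic) "" else ", quadratic term off"))
  cat(sprintf("  gamma = %.4g /Gy\n", object@gamma))
  cat(sprintf("  a = %.4g, b = %.4g mL/ug (TSE potency: %s)\n",
              object@a, object@b, object@tsePotency))
})

# copy of params with some slots replaced (internal)
updateParameters <- function(params, ...) {
  repl <- list(...)
  for (nm in names(repl)) slot(params, nm) <- repl[[nm]]
  validObject(params)
  params
}

#' Construct population parameters
#'
#' Defaults follow the packaged reference estimates: BSV coefficients of
#' variation 50\% (`v0`), 46\% (`gamma`) and 42\% (`alpha`), proportional
#' residual error 24\% and additive residual error 6.9 mm^3. CVs are
#' converted to log-scale SDs as `omega = sqrt(log(1 + cv^2))`.
#'
#' @param fixed population medians as a [ModelParameters-class] object.
#' @param omega named numeric of log-scale BSV SDs for `v0`, `gamma`, `alpha`.
#'   Alternatively supply `bsvCV`.
#' @param bsvCV named numeric of BSV CVs in percent (used if `omega` missing).
#' @param sigmaProp proportional residual SD (fraction).
#' @param sigmaAdd additive residual SD (mm^3).
#' @param cvApprox if `TRUE`, use the small-variance approximation
#'   `omega = cv` instead of the exact log-normal relation.
#' @return a [PopulationParameters-class] object.
#' @examples
#' pop <- populationParameters()
#' pop@omega
#' @export
populationParameters <- function(fixed = modelParameters(),
                                 omega = NULL,
                                 bsvCV = c(v0 = 50, gamma = 46, alpha = 42),
                                 sigmaProp = 0.24, sigmaAdd = 6.9,
                                 cvApprox = FALSE) {
  if (is.null(omega)) {
    cv <- bsvCV[c("v0", "gamma", "alpha")] / 100
    omega <- if (cvApprox) cv else sqrt(log(1 + cv^2))
    names(omega) <- c("v0", "gamma", "alpha")
  }
  new("PopulationParameters", fixed = fixed,
      omega = omega[c("v0", "gamma", "alpha")],
      sigmaProp = sigmaProp, sigmaAdd = sigmaAdd)
}

setMethod("show", "PopulationParameters", function(object) {
  cat("Population parameters (medians + between-subject variability)\n")
  show(object@fixed)
  cv <- 100 * sqrt(exp(object@omega^2) - 1)
  cat(sprintf("  BSV CV%%: v0 %.1f, gamma %.1f, alpha %.1f\n",
              cv["v0"], cv["gamma"], cv["alpha"]))
  cat(sprintf("  residual: proportional %.3g, additive %.3g mm^3\n",
              object@sigmaProp, object@sigmaAdd))
})

#' Individual parameters from random-effect deviations
#'
#' Applies log-normal deviations to the population medians:
#' `v0_i = v0 * exp(etaV0)` and likewise for `gamma` and `alpha`.
#'
#' @param pop a [PopulationParameters-class] object.
#' @param eta numeric length 3 (etaV0, etaGamma, etaAlpha), log scale.
#' @return a [ModelParameters-class] object for the individual.
#' @export
individualParameters <- function(pop, eta) {
  stopifnot(is(pop, "PopulationParameters"), length(eta) == 3L)
  f <- pop@fixed
  updateParameters(f,
    v0 = f@v0 * exp(eta[[1L]]),
    gamma = f@gamma * exp(eta[[2L]]),
    alpha = f@alpha * exp(eta[[3L]]))
}
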