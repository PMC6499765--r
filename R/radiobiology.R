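#' Lethally irradiated fraction (LQ cell kill with sensitizer enhancement)
#'
#' Fraction of proliferating cells lethally hit by a radiation fraction of
#' dose `D` at concurrent sensitizer concentration `C`:
#' \deqn{F(D, C) = 1 - \exp[-(1 + aC)(\alpha D + \beta D^2)]}
#' with `beta = alpha/alphaBetaRatio` (0 when the quadratic switch is off).
#' Strictly increasing in both arguments when `alpha > 0`, and independent of
#' `C` when `a = 0`.
#'
#' @param D radiation dose (Gy, >= 0); vectorised.
#' @param C sensitizer plasma concentration (ug/mL, >= 0); vectorised.
#' @param params a [ModelParameters-class] object.
#' @return fraction in `[0, 1)`.
#' @examples
#' lethalFraction(2, 0, modelParameters())           # ~0.179
#' lethalFraction(2, 0, modelParameters(lqQuadratic = FALSE))  # ~0.151
#' @export
lethalFraction <- function(D, C, params) {
  stopifnot(is(params, "ModelParameters"))
  if (any(D < 0) || any(C < 0)) stop("negative dose or concentration")
  beta <- betaOf(params)
  1 - exp(-(1 + params@a * C) * (params@alpha * D + beta * D^2))
}

#' Permanent growth-inhibition factor
#'
#' Multiplies the growth rate of surviving proliferating cells:
#' \deqn{I(IR_{Tot}) = \exp(-\gamma \, IR_{Tot})}
#' Equals 1 with no accumulated dose and decreases monotonically; the
#' inhibition never recovers, reflecting irreversible damage to the tumor
#' micro-environment and vasculature.
#'
#' @param irTot accumulated effective dose (Gy, >= 0); vectorised.
#' @param params a [ModelParameters-class] object.
#' @return factor in `(0, 1]`.
#' @examples
#' growthInhibition(60, modelParameters())   # exp(-0.24)
#' @export
growthInhibition <- function(irTot, params) {
  stopifnot(is(params, "ModelParameters"))
  if (any(irTot < 0)) stop("negative accumulated dose")
  exp(-params@gamma * irTot)
}

#' Effective-dose increment of one fraction
#'
#' Contribution of a radiation fraction to the accumulated effective dose:
#' `(1 + b C) * D`. Reduces to the physical dose at zero concentration.
#'
#' @inheritParams lethalFraction
#' @return effective dose (Gy).
#' @examples
#' effectiveDoseIncrement(2, 8, modelParameters())   # 4.4 Gy
#' @export
effectiveDoseIncrement <- function(D, C, params) {
  stopifnot(is(params, "ModelParameters"))
  if (any(D < 0) || any(C < 0)) stop("negative dose or concentration")
  (1 + params@b * C) * D
}
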