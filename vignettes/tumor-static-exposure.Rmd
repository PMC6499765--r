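---
title: "Modelling long-term tumor growth and kill under radiation plus a radiosensitizer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling long-term tumor growth and kill under radiation plus a radiosensitizer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radtse)
```

## The model and its assumptions

`radtse` implements an impulsive-dose tumor growth-and-kill model for
fractionated radiotherapy combined with an orally dosed radiosensitizer (a
DNA-damage-repair inhibitor without intrinsic anti-tumor activity), together
with the Tumor Static Exposure (TSE) analysis layer and a population
estimation workflow for xenograft volume data.

Six compartments carry the volume: proliferating cells $V_1$; three
damage-transit compartments $V_2,V_3,V_4$ through which dying cells pass
(natural cell death sends cells through them even without treatment, at rate
$k_k$); and two compartments for lethally irradiated cells, $U_1$ (capable
of one final mitosis; each departing cell deposits two daughters in $U_2$,
hence the factor 2 in its inflow) and $U_2$. This mitotic-catastrophe
structure delays the volume response to irradiation, which is what caliper
data show.

Radiation acts twice:

* **Instantaneous kill.** At each fraction a lethally hit share of $V_1$
  moves to $U_1$, sized by the linear-quadratic survival model with
  sensitizer enhancement, $F(D,C)=1-\exp[-(1+aC)(\alpha D+\beta D^2)]$.
  $\beta$ is never free: $\beta=\alpha/(\alpha/\beta)$ with the ratio fixed
  at the typical 10 Gy, for identifiability. Total volume is exactly
  conserved at the jump.
* **Permanent growth inhibition.** The accumulated *effective* dose
  $IR_{Tot}$ grows by $(1+bC)D$ per fraction and multiplies the growth rate
  by $I(IR_{Tot})=\exp(-\gamma IR_{Tot})$. No repair term is included: the
  inhibition persists after treatment arrest, allowing the model to produce
  regrowth slower than control as well as outright eradication.

The initial volume is distributed geometrically,
$V_i(0)=V^0 (k_k/k_g)^{i-1}$, which makes the untreated system grow exactly
exponentially at rate $k_g-k_k$ from time zero (the geometric profile is an
eigenvector of the transit cascade). Part of the initial volume therefore
consists of non-proliferating cells — a deliberate modelling choice that
avoids underestimating the exposure needed for regression.

Sensitizer exposure uses a one-compartment disposition model with bolus oral
input (no absorption phase). This is conservative: it cannot underestimate
the concentration at irradiation time, and hence cannot overestimate the
sensitizer potency. Irradiation is evaluated 30 minutes after the sensitizer
dose by default (`sensitizerLeadTime`), with full superposition of
carry-over from earlier doses.

## Parameters

| Parameter | Unit | Default | Meaning |
|---|---|---|---|
| `kg` | 1/day | 0.40 | growth rate of proliferating cells |
| `kk` | 1/day | 0.26 | kill / natural-death rate (transit rate) |
| `v0` | mm³ | 27.0 | initial proliferating-compartment scale |
| `alpha` | 1/Gy | 0.082 | linear LQ coefficient |
| `alphaBetaRatio` | Gy | 10 | fixes `beta = alpha/10` |
| `a` | mL/µg | 0.42 | sensitizer potency on instantaneous kill |
| `gamma` | 1/Gy | 0.004 | long-term growth-inhibition coefficient |
| `b` | mL/µg | 0.15 | sensitizer potency on the long-term effect |

The defaults are the packaged reference estimates from a FaDu xenograft
study. Two of them deserve comment, because the source material reports
each in two slightly different forms. For $\alpha$, 0.082/Gy is the value
that makes a 2 Gy fraction kill 15 % of proliferating cells through the
linear term, while the tabulated estimate 54/kGy (= 0.054/Gy) differs; we
default to 0.082 and both load cleanly through the parameter-file interface
(`alpha_per_gy` / `alpha_per_kgy`). For $\gamma$, the tabulated 4.0/kGy
(0.004/Gy) reproduces the ~110 Gy radiation-only stasis dose, while
0.0034/Gy is also quoted; we default to 0.004. These choices are recorded
here once and not revisited; the I/O layer accepts either value.

Internally everything is in days, Gy, mm³ and µg/mL. Table-style per-kGy
values are converted only at the file boundary, so a silent 1000× error
cannot enter the computation.

PK defaults are calibrated to the reported kinetics — half-life 3 h and peak
concentrations 2 and 8 µg/mL after 25 and 100 mg/kg — via
`ke = ln 2 / 0.125` per day and `V/F` = 12 500 mL/kg. No separate values of
the distribution volume or bioavailability are identifiable from those
facts, and none are needed: only the ratio enters the model.

## Tumor Static Exposure

Long-run behaviour is governed solely by the permanent inhibition: the
instantaneous-kill effect displaces volume but cannot change the sign of the
net growth rate

$$k_{net}(D, C) = k_g e^{-\gamma (1+bC) D} - k_k .$$

Its zero set in the $(C, D)$ plane is the TSE curve,
$D = \log(k_g/k_k) / (\gamma (1+bC))$, with exact inverse
$C = \log(k_g/k_k)/(\gamma b D) - 1/b$ (clipped at zero, with a flag, when
the dose alone suffices). `tseDose()` generalises to any target net rate
$r \in (-k_k,\ k_g-k_k]$ (the `TSE_dV` isoclines); outside that interval no
finite exposure achieves the rate and the function refuses rather than
extrapolate.

A note on symbols: the static-exposure expressions use the *long-term*
parameters $\gamma$ and $b$, because it is the accumulated effective dose
that drives the net rate. Formulations that write the same curve with the
short-term pair ($\alpha$, $a$) conflate the two effects; since the question
is genuinely ambiguous in parts of the literature, `ModelParameters` carries
a `tsePotency` switch (`"b"` default, `"a"` optional) so the alternative
reading can be probed without touching the dynamics.

With the defaults, the radiation-only stasis dose is 107.7 Gy (≈ 110 Gy as
rounded in reports), dropping to 82.8 Gy at 2 µg/mL. The printed 30 Gy at
8 µg/mL is *not* reproducible from any single printed potency (it implies
≈ 0.33 mL/µg where 110→80 implies ≈ 0.19); it was presumably computed from
unrounded estimates, and we treat it as out of reach of the printed
parameter set rather than adjust anything to hit it.

TSE is invariant under joint scaling of $(k_g, k_k)$ — it depends on the
rates only through their quotient — which is the allometric argument for
carrying the curve across species while the growth *trajectories* slow
down. `allometricScale()` exposes exactly this operation, and
`tseSensitivity()` quantifies that matched relative perturbations of the
rates move the curve far more than perturbations of $\gamma$ or $b$.

## Simulation engine

Between irradiation events the system is linear and time-invariant
($IR_{Tot}$ changes only at events), so propagation is computed exactly with
a matrix exponential per segment (compiled, Armadillo `expmat`) rather than
by one global stiff solve across discontinuities: jumps stay exact, and the
trajectory cost is a few hundred microseconds, which is what makes the
mixed-effects fit tractable. The R-level `propagateState()` runs the same
segment through `Matrix::expm()` as an independent route, and the test suite
cross-checks both against `deSolve` adaptive integration to 1e-6 relative
and against the closed-form exponential oracle for untreated growth to
1e-9.

Conventions worth knowing: an observation falling exactly on an event time
records the pre-event (left) limit, with post-event states available from
the trajectory's event table; sensitizer and radiation at the same protocol
time are ordered dose-first (the 30-minute lead implements this by
construction); observation times before day 0 are served by the exact
exponential back-step, which is valid because the initial state is the
cascade eigenvector. Eradication is asymptotic in an ODE, so
`isEradicated()` applies a reporting threshold (default total volume below
10⁻³ mm³ at the last observation), configurable and used only for labels,
never in the likelihood.

## Population estimation

Random effects are log-normal on exactly `v0`, `gamma` and `alpha` — the
three parameters whose between-subject variability is identifiable in this
design — and the residual model is combined proportional (24 %) plus
additive (6.9 mm³). BSV magnitudes given as CV % are converted with the
exact log-normal relation $\omega=\sqrt{\log(1+cv^2)}$ (a small-variance
`cvApprox` option exists).

`fitPopulation()` maximises a Laplace-class approximate marginal
likelihood: for each animal the joint $-2\log$-density is minimised over
its random effects (inner problem, warm-started across outer iterations),
and the log-determinant correction uses the Gauss–Newton curvature
$J^\top W J+\Omega^{-1}$, with $J$ the finite-difference sensitivity of the
predicted volumes — the first-order-conditional family of approximations.
The Gauss–Newton form is positive definite by construction, which keeps the
outer objective well defined everywhere. Strictly positive fixed effects
and the residual SDs are estimated on the log scale; the potencies `a`, `b`
and the $\omega$s live on the natural scale with a lower bound at zero, and
boundary values are reported, not dropped. Standard errors, when requested,
come from a finite-difference Hessian of the outer objective (asymptotic;
a pseudo-inverse fallback covers boundary cases). Empirical Bayes estimates
are the final inner modes; `ebeShrinkage()` reports $1-SD(\eta)/\omega$.

Two practical caveats the test suite encodes rather than hides. First, with
a proportional error component the likelihood contains
$\sum\log\sigma(V_{pred})$, so even noise-free data are *not* recovered
exactly — the "pure least-squares" limit requires an additive-only residual
model, which is how the degenerate-recovery test is phrased. Second, when a
reduced model is fitted (e.g. no BSV on `alpha`), recovery is only clean if
the generating truth matches that structure; deliberately misspecified
reduced fits are biased, as expected.

Below-quantification volumes (eradicated tumors) are left-censored at a
configurable limit (default 4 mm³) and imputed at half the limit — a
documented simplification; a full censored-likelihood treatment is out of
scope.

## The synthetic study generator

`generateStudy()` emulates the reference xenograft protocol: four arms
(vehicle; 2 Gy; 2 Gy + 25 mg/kg; 2 Gy + 100 mg/kg) of ten mice, Mon–Fri
dosing for six weeks with the sensitizer given 30 minutes before
irradiation, caliper measurement Mondays and Thursdays through twelve
follow-up weeks, sacrifice above 2000 mm³ (the crossing record is kept and
flagged), detection limit 4 mm³, and day 0 on the Monday of week 1.
Residual noise is combined proportional + additive, truncated at zero.

By default each animal's `v0` is drawn from the population law (log-normal,
median 27 mm³, CV 50 %), so that generated studies are *exactly* the model
the estimator fits — the right conditions for parameter-recovery
experiments; the resulting median initial total volume (63 mm³) sits inside
the reported 50–110 mm³ enrollment window. An explicit
`enrollmentRange = c(50, 110)` instead draws the initial total volume
uniformly on the window and back-scales `v0` through the geometric initial
distribution, trading exact model-consistency for protocol realism. Random
dropout beyond the volume cap is available (`dropoutHazard`) but off by
default, since the attrition seen in real studies has no stated mechanism.

What the generator does *not* emulate: caliper length/width pairs (volumes
are generated directly; the `L·W²/2` formula is exercised separately),
measurement-day rescheduling, correlated residuals, or any informative
dropout. Passing recovery tests on these data therefore demonstrates
internal consistency of model + estimator, not robustness to the
misspecifications real data carry.

## Problem sizes and numerical settings used by the tests

The packaged tests run the full recovery experiment at the reference design
(4 arms × 10 animals, ~1100 observations) with the outer optimizer capped
at 80 iterations — about two to three minutes of CPU — and the remaining
estimation tests at reduced two- or three-arm designs of 4–16 animals with
three-to-four-week schedules, sizes chosen to probe consistency and null
recovery while keeping each fit under a minute. The predictive-check
self-consistency test uses 100 replicate studies. Inner conditional-mode
searches cap at 50 iterations; finite-difference steps are 1e-4 on the eta
scale. Seeds are fixed throughout; the generator is deterministic given
(config, seed).

## Known limitations

* No repair/misrepair kinetics or dose-rate effects; LQ is trusted only in
  its usual per-fraction validity range (≤ 18 Gy).
* $U_1$ proliferates at the uninhibited `kg`, as the model equations state;
  whether growth inhibition should also slow the final division of lethally
  hit cells is biologically arguable and deliberately not second-guessed.
* One-compartment PK without absorption; fine for concentrations at
  irradiation time under a 30-minute lead, wrong for early-phase AUC
  questions.
* The estimator is a conditional-mode (Laplace/FOCE-class) approximation,
  not exact marginal likelihood; with very sparse per-animal data its omega
  estimates inherit the usual downward/upward finite-sample quirks.
* The sacrifice cap induces informative censoring in fast-growing arms; the
  likelihood ignores this (as does common practice), so vehicle-arm growth
  rates estimated from capped data carry a small selection effect.
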