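---
title: "Model and methods: population pharmacokinetics of inhaled salmeterol for doping control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(salmpk)
```

## The problem

Salmeterol is a long-acting inhaled beta-2 agonist on the WADA Prohibited
List: therapeutic inhaled use is permitted up to 200 micrograms in any 24-h
period, and laboratories flag urine concentrations above a minimum
reporting level (MRL) of 10 ng/mL. Whether that MRL separates permitted
from prohibited use depends on the joint pharmacokinetics of salmeterol
and its major CYP3A4 metabolite, alpha-hydroxysalmeterol, in plasma and
urine — including how urine concentrations depend on voiding behaviour
and hydration. This package implements a population pharmacokinetic
(popPK) model of that system, a Monte Carlo engine for urinary
prediction intervals and MRL-exceedance probabilities under standard
regimens, a Laplace-approximated nonlinear mixed-effects estimator with
MAP Bayesian individual estimation, and a generator of synthetic pooled
multi-study datasets on which estimation is testable end to end.

## Structural model

Plasma salmeterol follows a two-compartment disposition model with
instantaneous (intravenous-like) input of the labelled inhaled dose:
pulmonary absorption is fast relative to every sampling scheme of
interest, and a parallel slow gastrointestinal pathway is deliberately
not modelled. With amounts $A_1$ (central), $A_2$ (peripheral), $A_3$
(plasma metabolite), and cumulative urinary amounts $A_4$ (salmeterol)
and $A_5$ (metabolite):

$$
\begin{aligned}
\dot A_1 &= -(k_{10} + k_{12} + k_{14})\,A_1 + k_{21} A_2 \\
\dot A_2 &= k_{12} A_1 - k_{21} A_2 \\
\dot A_3 &= k_{13} A_1 - (k_{30} + k_{35})\,A_3 \\
\dot A_4 &= k_{14} A_1, \qquad \dot A_5 = k_{35} A_3
\end{aligned}
$$

with $k_{10} = (CL_S/F)/(V_1/F)$, $k_{12} = (Q/F)/(V_1/F)$,
$k_{21} = (Q/F)/(V_2/F)$ and $k_{30} = (CL_\alpha/F)/(V_1/F)$. Two
structural points deserve emphasis:

* **The metabolite system is driven, not mass-transferring.** The
  conversion constant $k_{13}$ feeds $A_3$ without appearing in the loss
  terms of $A_1$. After inhaled dosing with unknown bioavailability the
  fraction metabolized is not identifiable, so the metabolite model rides
  on the parent as a scaled mirror — the standard device when "complete
  conversion" is asserted but absolute elimination fractions cannot be
  resolved. This choice is not cosmetic: only with a driven metabolite
  does the parent terminal half-life equal the classical disposition
  value of ~5 h (with $k_{13}$ as a genuine loss it would be ~3.1 h), and
  only then do the simulated 30-min urine concentrations carry the right
  accumulation from a preceding dose. `half_lives()` exposes the
  disposition convention (the default), the exact implemented slope
  (`"model"`, indistinguishable because $k_{14}$ is four orders of
  magnitude smaller than $k_{10}$), and the depleting variant
  (`"total"`) for comparison.
* **The metabolite central volume equals $V_1/F$** (an identifiability
  constraint), so both plasma concentrations divide by the same apparent
  volume. All parameters are apparent (confounded with $F$); amounts are
  book-kept as if the full labelled dose entered $A_1$.

Because the rate matrix is block-triangular and constant, the solution is
a short sum of exponentials: the parent pair has analytic eigenvalues
$\alpha,\beta$ (roots of a quadratic), $A_3$ is a convolution of the
parent biexponential with a first-order decay, and the urinary and
eliminated amounts are running integrals of first-order fluxes. Doses
superpose. `pk_state()` evaluates this closed form; when the eigenvalue
spectrum degenerates (relative gap below $10^{-9}$, e.g. when
$k_{30}+k_{35}$ collides with $\beta$) a validated `deSolve::lsoda()`
integrator takes over and the `solver` column reports it. Mass balance is
testable exactly: the dose is conserved in the parent system
($A_1+A_2+A_4+k_{10}\!\int\!A_1 = D$) and the formed amount in the
driven system ($A_3+A_5+k_{30}\!\int\!A_3 = k_{13}\!\int\!A_1$), both
held to $10^{-8}$ relative in the tests against an independently coded
ODE oracle.

## Micturition model

Urine is not a well-mixed sampling compartment: a sample's concentration
is the amount excreted since the last void divided by the volume
accumulated since then. Voiding is assumed complete and instantaneous,
every 4 h and additionally immediately before each inhalation. When
collection volumes were recorded they are used directly; otherwise the
volume is reconstructed as a constant urine production rate
(`ur_prod`, typical 0.079 L/h) times the interval length. The
"directly after inhalation" sample — the worst case for doping control —
is the analytic limit of the interval concentration as the interval
shrinks to zero around a pre-dose void plus dose:
$C = k_{14} A_1(t^+)/\mathrm{UR\_PROD}$ for salmeterol (and the
$k_{35} A_3$ analogue for the metabolite). A "30 min post-dose" sample
accumulates from the pre-dose void to dose + 0.5 h with no intervening
void. Residual bladder volume and time-varying urine production
(dehydration/rehydration during exercise) are not modelled; this is the
main acknowledged physiological simplification.

Urine concentrations are standardized for hydration status by the
specific-gravity correction
$C_{corr} = 0.020/((USG+0.002)-1)\cdot C_{obs}$, applied whenever a USG
value is recorded (the printed formula carries no dilute/concentrated
conditional, so none is imposed); USG 1.018 is the identity point.
Simulated urine outputs are reported directly on this standardized scale,
equivalent to every virtual sample being collected at USG 1.018.

## Statistical model

Every structural parameter is log-normal across subjects:
$p_i = \theta \cdot m_i \cdot e^{\eta_i}$, $\eta_i \sim N(0,\omega^2)$,
with IIV magnitudes configured as CV% and converted once via
$\omega = \sqrt{\ln(1+CV^2)}$. The covariate multipliers $m_i$ apply to
athletes/endurance-trained subjects only: 1.63 on $CL_S/F$ and 2.91 on
$k_{14}$ (healthy and asthmatic subjects are statistically
indistinguishable and regrouped as the reference). No IIV correlations
are modelled, none being reported. The random effect on urine production
applies only to observations that are *not* USG-standardized — the
correction itself absorbs hydration-driven volume variability — and the
packaged configuration ships with CV% of
{16, 86, 43, 33, 41, 29, 73} for
$\{V_1, Q, V_2, CL_S, k_{13}, k_{14}, \mathrm{UR\_PROD}\}$ and none for
$CL_\alpha$ and $k_{35}$.

Residual error is proportional, grouped by matrix and compound, with
urine errors further grouped into low/mid/high magnitude classes (CV 22%
and 38% in plasma; 29/41/57% for urinary salmeterol and 38/51% for the
urinary metabolite). Parent and metabolite measured in the same sample
can carry correlated errors (0.53 in plasma, 0.61 in urine) — drawn
jointly in simulation and handled as bivariate normal terms in the
likelihood. Which studies carry the correlation, and which urine
magnitude group each study belongs to, is configuration on the dataset
(the source pooled analysis does not publish the assignment); the
synthetic designs make an explicit choice.

`apply_ruv()` supports two functional forms with identical CV. The
`"proportional"` form, $y = f(1+\varepsilon)$ with Gaussian
$\varepsilon$, matches the arithmetic-scale estimation likelihood;
negative draws are floored at zero and counted (well under 1% at the
packaged CVs). The `"exponential"` form, $y = f e^{\eta}$ with
$\eta \sim N(0,\ln(1+cv^2))$, is the Monte-Carlo default: the published
prediction intervals are geometrically symmetric (the 2.5th x 97.5th
product equals the squared median in every regimen row, and the extreme
tail matches a log-normal quantile), which the arithmetic form cannot
produce at CV 41%, and it cannot generate negative concentrations.

## Monte Carlo engine

`simulate_population()` draws `n` individuals (IIV, covariates), runs the
closed-form kinetics over an explicit 7-day regimen (no analytic
steady-state shortcut — accumulation is small anyway, with a ~5 h
terminal half-life against 8-24 h dosing intervals), applies voiding
every 4 h plus pre-dose, and reports the direct-after-inhalation and
30-min samples after the last dose (for twice-daily regimens, the second
dose of day 7) plus, optionally, the concentration at the end of every
voiding interval. Simulated urine outputs are USG-standardized, so no
urine-production IIV is drawn; residual error uses the mid urine group —
medians are insensitive to this choice, extreme tails are not, which is
one reason the 99.9th percentile should be read as an order of magnitude
only. Percentiles use the inclusive linear-interpolation estimator
(`quantile(type = 7)`); at n = 10,000 the 99.9th percentile interpolates
between the 9990th and 9991st order statistics. `mrl_exceedance()`
reports the fraction of virtual subjects above the 10 ng/mL MRL at a
sampling point; the practically relevant condition is 30 min post-dose.

With the packaged estimates this engine reproduces the published
prediction table within Monte Carlo noise — athlete direct-sample medians
of ~3.6 and ~7.2 ng/mL under 100 and 200 micrograms twice daily, ~6.9
once daily at 200, a healthy-participant median of ~1.3 under 100 twice
daily, and an MRL-exceedance probability of ~4% under the prohibited
200-twice-daily regimen — the quantities recomputed by
`scripts/acceptance.R` and asserted in `tests/testthat/test-acceptance.R`.

## Estimation

`individual_loglik()` evaluates a subject's data likelihood: Gaussian
densities with SD = CV x prediction (floored at $10^{-10}$ nmol/L) for
quantified rows, bivariate normal for correlated parent-metabolite
pairs, and, under the M3 option, the normal probability mass below the
LLOQ for censored rows. Data preparation alternatives are M1 (discard
BQL rows) and M6 (impute the first BQL row of each censored run with
LLOQ/2, drop the rest) via `censor_bql()`.

`map_estimate()` maximizes likelihood plus log-prior over the subject's
random effects — empirical-Bayes individual parameters, the route by
which repeated doping-control measurements on one athlete would sharpen
that athlete's predicted profile. Random effects that cannot influence a
subject's likelihood (metabolite effects without metabolite data; the
urine-production effect when all urine rows carry USG or recorded
volumes) integrate out exactly and are pruned for speed.

`fit_population()` maximizes the summed Laplace-approximated log marginal
likelihood (OFV = $-2\log L$) over any free subset of typical values,
covariate multipliers, log-scale IIV SDs, and residual CVs, all on the
log scale, by a bounded quasi-Newton outer loop. Numerical choices that
matter, found the hard way and documented here deliberately:

* **Inner problem:** per-subject MAP by `nlminb`, warm-started from the
  previous outer iteration; Laplace uses an economical
  finite-difference Hessian (central diagonal, forward cross terms) with
  Cholesky log-determinants and an eigenvalue floor if a Hessian is not
  positive definite. Jittered multi-starts are available
  (`settings$n_starts`) but default to 1: the inner objectives proved
  unimodal in all synthetic experiments, and extra starts triple cost.
* **Outer gradient:** an explicit finite-difference gradient with step
  $10^{-3}$ on the log scale. The warm-started inner solves make the OFV
  reproducible only to ~$10^{-6}$; an optimizer's default differencing
  step (~$10^{-7}$) sits inside that noise and produces garbage
  gradients and false convergence. Convergence tolerances: outer
  relative change $10^{-6}$, inner $10^{-10}$.
* **Error-model interaction:** with proportional error the residual SD
  depends on the random effects, and the $-\sum\log f(\eta)$ term pulls
  each subject's conditional mode downward; the Laplace objective then
  systematically inflates concentration-scaling parameters (about +20%
  for $k_{13}$/$k_{14}$ on the pooled synthetic design — reproducible by
  profiling the OFV at the generating values). The `"lognormal"` error
  model (Gaussian on log concentrations, CV matched) removes the
  interaction, making the inner problem nearly exactly Gaussian; paired
  with data generated under the exponential residual form it recovers
  the generating parameters without that bias, and it is what the
  package's own recovery experiments use. Both error models are
  first-class; the proportional form remains the default for
  compatibility with the arithmetic-scale convention.
* Standard errors (optional, `settings$se`) come from the numerical
  Hessian of the OFV with delta-method back-transformation; eta
  shrinkage is $1-\mathrm{SD}(\hat\eta)/\omega$ in percent.

`compare_models()` applies the OFV chi-squared conventions (forward
addition at $\alpha=0.05$: $\Delta\mathrm{OFV} < -3.84$ for one
parameter; backward deletion at $\alpha=0.01$: removal must cost more
than 6.63) and AIC for non-nested pairs. `pk_bootstrap()` resamples
subjects (stratified by study so replicates keep the pooled design
shape) and refits; `pk_vpc()` is a plain (not prediction-corrected)
visual predictive check binned by time after dose, with
`autoplot()` methods for both the VPC and simulated profiles.

## Synthetic multi-study data

No raw data from the source studies are available, so
`generate_study()`/`generate_pooled_study()` emulate the *structure* of
the pooled design: six studies, 92 subjects (7 + 14 urine-only at
100/200 micrograms with USG; 11 endurance-trained with three occasions
— 400, 200, and a week of 200 once daily — plasma and urine for both
compounds, recorded volumes, USG, correlated errors; 6 + 4 healthy at
50 (MDI) and 200 (DPI) with urinary salmeterol only; 10 + 10 healthy
and asthmatic at 100 with plasma salmeterol and urine for both
compounds; 6 healthy at 100 with recorded volumes; 24 healthy with two
100-microgram occasions). Sampling grids are invented — the source
publishes none — chosen to straddle the 0.13 h and ~5 h phases
(plasma up to 0.05-12 h post-dose, urine as consecutive collection
intervals over 0-24 h) and calibrated so pooled observation counts per
matrix/compound land within 25% of the source totals
(275/398/185/317); the generated pool gives 306/442/198/366. LLOQs are
study-type defaults (0.01 ng/mL plasma salmeterol, 0.005 plasma
metabolite — the metabolite circulates at tens of pg/mL — and
0.1 ng/mL in urine), yielding a realistic ~7% BQL fraction. Per-sample
USG is drawn from N(1.018, 0.006^2) truncated to [1.002, 1.035] and
attached so that the recorded raw value standardizes back exactly to
the simulated concentration; it exercises the correction code path but
is not mechanistically coupled to urine production — a known
simplification. BQL rows are retained uncensored; censoring is the
analyst's downstream choice.

What passing tests on these data do and do not show: they demonstrate
that the estimation machinery recovers the parameters of data generated
by its own model family under a realistic pooled design — a
self-consistency (and software-correctness) claim. They cannot validate
the published estimates against the real six-study pool, which is not
deposited; the packaged configuration is used as simulation truth, never
as a fitting target.

## Problem sizes and experiment design

The package's own experiments use: 10,000 virtual individuals per
regimen for percentile tables and exceedance probabilities (stable to
well under the comparison tolerances; the 99.9th percentile excepted, as
above); the full 92-subject pooled design, fixed seed, free
$\{CL_S/F, k_{13}, k_{14}, \omega_{CL_S}\}$ from deliberately displaced
starting values, M3 censoring and the log-normal error model, for the
parameter-recovery experiment (fixed effects recovered within +/-30%,
the IIV SD within +/-50%); and twenty replicates of a two-arm,
24-subject, plasma-only design with IIV on clearance only for the
covariate power experiment (the 1.63-fold athlete clearance effect is
detected at $\Delta\mathrm{OFV} < -3.84$ in over 90% of replicates —
each replicate's inner problem is one-dimensional, which keeps forty
fits cheap). The bootstrap and VPC examples run at reduced replicate
counts; published practice (2000 bootstrap replicates) is a scale
choice, not a methodological difference.

## Known limitations

Constant urine production ignores genuine micturition physiology;
athlete covariates may proxy unmodelled hydration and activity
differences; the absolute metabolite fraction is unidentifiable by
construction; exact numerical equivalence with gradient-based FOCE-I
implementations in established estimation software is not claimed — the
Laplace objective here is a close relative, not a clone — and extreme
tail percentiles inherit all the usual fragility of parametric
extrapolation.
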