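---
title: "Population pharmacokinetics of vancomycin in neonates: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population pharmacokinetics of vancomycin in neonates: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neovanc)
library(dplyr)
```

## The problem

Vancomycin remains first-line therapy for serious Gram-positive
infections in neonates, and it is dosed against a narrow window:
troughs below ~10 ug/mL risk under-treatment and resistance, high
exposures risk oto- and nephrotoxicity. Neonates and young infants are
also the population in which clearance varies most — renal function
matures rapidly with both gestational and postnatal age — and in which
blood sampling is most constrained, so concentration data arrive as
one to a handful of therapeutic-drug-monitoring (TDM) samples per
patient, mostly troughs. Population pharmacokinetic (PopPK) modelling
is the standard answer: a nonlinear mixed-effects (NLME) model pools
hundreds of sparsely sampled patients, separates between-patient
variability from assay noise, quantifies how covariates such as body
weight and age shift the typical parameters, and then supports
individualized dose selection.

`neovanc` implements this workflow end to end for a two-compartment
vancomycin model in neonates/young infants: structural kinetics,
FOCE estimation, stepwise covariate selection, internal evaluation
(bootstrap, visual predictive check), external validation metrics and
trough prediction — plus a synthetic-cohort generator so every stage
is exercisable and testable without patient data.

## Structural and statistical model

Drug amounts follow the linear two-compartment model with
constant-rate IV infusion input and first-order elimination,
parameterized by the central and peripheral volumes $V_1, V_2$ (L),
clearance $CL$ (L/h) and inter-compartmental clearance $Q$ (L/h).
With micro constants $k_{10} = CL/V_1$, $k_{12} = Q/V_1$,
$k_{21} = Q/V_2$, the disposition exponents $\alpha > \beta$ are the
roots of $x^2 - (k_{10}+k_{12}+k_{21})x + k_{10}k_{21}$, and the
central concentration under any dosing history is the superposition of
the standard per-infusion bi-exponential solution (`predict_conc()`,
implemented in C++ and verified in the test suite against an
independent stiff-ODE integration to $10^{-6}$ relative error).
$Q = 0$ is handled as the exact one-compartment limit, not an error.

Between-subject variability is exponential,
$P_i = P_{pop}\,e^{\eta_i}$ with $\eta_i \sim N(0, \omega^2)$.
Continuous covariates enter as power functions centered at the cohort
median, $P_i = P_{pop}\,(Cov/Cov_{med})^{\theta}$; 0/1 covariates as
$P_i = P_{pop}\,e^{\theta\,Cov}$. Residual error may be additive,
proportional or combined; the packaged final model is additive with
SD `stdev0`.

The packaged final model (`vanco_final_model`) is

$$CL\ (\mathrm{L/h}) = 0.42\cdot(BBW/3.22)^{0.888}\cdot(PNA/29)^{0.449}\cdot e^{\eta_{CL}},$$

with $V_1 = 1.27$ L, $V_2 = 2.422$ L, $Q = 1.161$ L/h,
$\omega_{CL} = 0.317$ and additive residual SD 2.187 ug/mL; birth body
weight (BBW) in kg and postnatal age (PNA) in days. Random effects are
carried on CL only: with almost-all-trough sampling the data carry
very little individual information on $V_1$, $V_2$ and $Q$ (their
shrinkage is extreme), so their $\eta$'s are omitted — any parameter
can carry an $\eta$ in a user-defined `pop_model()`.

**A note on $\omega_{CL} = 0.317$.** Reported IIV magnitudes are
sometimes variances, sometimes SDs. We adopt the SD reading
(conventional in Phoenix-style output tables): as a variance it would
imply a 56% CV of clearance, which would be unusually large given the
covariate model already absorbs weight and age; as an SD it implies a
~32% CV, typical for vancomycin clearance after covariate adjustment.
All simulation defaults follow this reading.

## Estimation: FOCE with interaction

`ppk_fit()` maximizes the approximate marginal likelihood. For subject
$i$ with quantifiable observations $y_i$ and individual prediction
$f_i(\eta)$, the conditional mode $\hat\eta_i$ solves the penalized
least-squares inner problem (Newton iterations on a finite-difference
gradient/Hessian, gradient tolerance $10^{-8}$). The objective is the
first-order-conditional expansion around $\hat\eta_i$:

$$-2\ell \approx \sum_i \Big[ n_i\log 2\pi + \log|V_i| + r_i^\top V_i^{-1} r_i \Big],
\qquad V_i = G_i\,\Omega\,G_i^\top + \Sigma_i,$$

with $G_i = \partial f_i/\partial\eta|_{\hat\eta_i}$,
$r_i = y_i - f_i(\hat\eta_i) + G_i\hat\eta_i$, and (with interaction,
the default) $\Sigma_i$ evaluated at the individual prediction. The
test suite checks this objective against an independent Gauss–Hermite
quadrature of the exact marginal likelihood: the two agree closely at
small $\omega$ (where the linearization is near-exact; the residual
discrepancy is the expected $O(\omega^2)$ term) and to within a
fraction of an OFV unit at $\omega = 0.317$; at $\omega = 0$ the OFV
reduces exactly to the Gaussian least-squares deviance.

Outer optimization runs quasi-Newton (`nlminb`) on transformed
parameters — log scale for all positivity-constrained quantities
(typical values, $\omega$, residual SDs), identity for covariate
exponents — with convergence at relative OFV change $<10^{-6}$ and at
most 500 outer iterations. Standard errors come from the central
finite-difference Hessian (step $10^{-4}$ on the transformed scale) of
OFV/2, delta-transformed back to the natural scale; a non-invertible
Hessian leaves SEs missing but the fit usable. Observations flagged
below the LLOQ are excluded from the likelihood (the M1 convention);
subjects left without quantifiable observations are dropped with a
message. Empirical Bayes estimates (`ppk_ebe()`), shrinkage
($1 - SD(\hat\eta)/\omega$) and conditional weighted residuals
(whitening of $r_i$ by the Cholesky factor of $V_i$; standard normal
under a correct model) are computed at the optimum.

## Covariate selection

`stepwise_covariates()` reproduces the classical OFV-threshold
procedure: greedy forward inclusion — each candidate relation is added
singly, the largest OFV drop wins if it exceeds 6.635 ($\chi^2_1$,
$p<0.01$) — iterated to exhaustion, then backward elimination in which
an effect survives only if its single removal raises the OFV by more
than 10.828 ($p<0.001$), dropping the cheapest-to-remove effect first
and iterating to stability. Continuous candidates are centered at the
dataset median. Ties in $\Delta$OFV break lexicographically on
covariate name — reproducibility over cleverness. Non-converging
candidate fits are skipped with a warning. The emitted ledger logs
every model evaluated with its OFV and exact $\Delta$OFV, so the
selection table can be regenerated from the trace.

Two calibration properties are tested: a pure-noise covariate clears
the forward gate at roughly the nominal $\chi^2_1$ rate, and on
study-scale synthetic cohorts the procedure returns exactly the
{BBW, PNA}-on-CL pair. The backward threshold of 10.828 is demanding:
at cohort sizes much below ~300 subjects even a true effect of this
magnitude cannot clear it, which is why the selection tests run at the
full design size.

## Internal and external evaluation

*Bootstrap* (`ppk_bootstrap()`) resamples **subjects** with
replacement — the only exchangeable unit in hierarchical data — refits
each replicate (initialized at the original estimates), and reports
per-parameter medians, SEs and both percentile and
median $\pm 1.96\cdot$SE intervals; non-converged replicates are
excluded and counted. The reference workflow uses 2000 replicates;
tests run 200.

*VPC* (`ppk_vpc()`) re-simulates the observed design (same doses,
covariates and sampling times) with fresh $\eta$ and $\varepsilon$,
summarizes simulated concentrations into 5th/50th/95th percentile
bands over quantile bins of time-after-most-recent-dose (8 bins by
default; the binning variable makes sparse multi-day TDM designs
comparable), and reports the fraction of observations inside the
5th–95th band — ~90% when the generating model is fitted.

*External validation* (`external_metrics()`) computes
$MPE = \tfrac1n\sum(c_{pred}-c_{obs})$,
$MAE = \tfrac1n\sum|c_{pred}-c_{obs}|$ and
$MSPE = \tfrac1n\sum(c_{obs}-c_{pred})^2$ with elementwise SDs, and
`case_prediction_error()` the per-case percent error
$100\,|c_{pred}-c_{obs}|/c_{obs}$.

*Trough prediction* (`predict_trough()`) evaluates the concentration
immediately before an indexed dose: the population prediction
($\eta = 0$) from covariates alone, or the MAP (empirical Bayes)
prediction when prior concentrations are supplied. Infusion durations
are rarely recorded in routine data, so the package carries an
explicit default of 1.0 h (standard neonatal vancomycin practice),
configurable per dose and per model. Predicted troughs are sensitive
to the true dose history; with only a nominal regimen available,
population predictions should be read as ±30%-level estimates, and the
two bundled worked cases are treated with exactly that tolerance (one
of them sits above it relative to the published model's own
prediction, while lying within ~28% of the measured concentration).

## The synthetic cohort generator

`simulate_cohort()` emulates the *structure* of a neonatal vancomycin
TDM study — it is a study-conditions generator, not an estimate of any
real joint distribution:

* **Covariates.** Continuous covariates are truncated log-normals
  parameterized by the published medians and ranges (only those are
  available; no SDs), e.g. BBW median 3.22 kg on (1.25, 5.38),
  PNA median 29 d on (2, 77). Prematurity is Bernoulli(102/316) with
  GA drawn conditionally (<37 weeks iff preterm); current weight grows
  out of birth weight as $BW = BBW\,(1 + g\cdot PNA)$ with
  $g \approx 0.0077$/day jittered ±30%, keeping the BW median
  plausible. Renal/hepatic markers (SCr, GFR, BUN, ALT, ALB) are drawn
  independently of the PK truth so selection-calibration tests can
  treat them as nulls. PMA, BSA and Schwartz GFR are computed, not
  drawn.
* **Dosing.** Daily dose uniform on 13.7–73.5 mg/kg split evenly over
  2–4 doses (τ = 12, 8 or 6 h) for 2–7 days, amounts rounded to
  0.1 mg, 1-h infusions.
* **Sampling.** 1–6 samples per subject (heavily weighted toward one;
  cohort mean ≈ 1.3), 70% drawn within 1 h before a dose (troughs, as
  in TDM practice) and 30% uniform within a dosing interval, all after
  the third dose.
* **Observation model.** $\eta$ per subject, additive $\varepsilon$
  per sample; values below the LLOQ of 1 ug/mL are flagged `bloq`;
  negative additive draws are truncated at 0 for the simulated record
  (the likelihood itself uses the untruncated Gaussian).

What it does **not** emulate: within-subject covariate time courses
(PNA is a per-subject scalar at sampling — a deliberate simplification
of an ambiguous convention; a time-varying option would change
estimates only marginally at 2–7-day courses), real covariate
correlation (beyond BW–BBW–PNA), irregular dose histories, or
informative sampling. Passing recovery tests therefore demonstrate
estimator correctness under these conditions, not performance on any
real hospital dataset.

One consequence is worth stating explicitly: because the LLOQ censors
the lower residual tail (excluded via M1) and simulated concentrations
are floored at zero, the fitted additive residual SD on default
synthetic cohorts sits systematically ~5–10% below the generating
2.187 ug/mL. Profiling the exact (quadrature) likelihood on the same
data reproduces the same minimum, i.e. this is a property of the
censored data, not an estimator defect.

## Numerical choices and edge cases

* Units: ug/mL ≡ mg/L exactly; doses in mg, volumes in L, times in
  hours from first dose. Creatinine converts at 88.4 umol/L per mg/dL.
* Repeated disposition roots ($\alpha = \beta$, a measure-zero input)
  are split by a $10^{-9}$ relative nudge.
* Non-finite likelihoods (e.g. `stdev0` → 0 with nonzero residuals)
  return a large penalty to the optimizer instead of erroring.
* Identifiability is pre-checked: fewer quantifiable observations (or
  distinct design times) than free parameters is an error, not a
  silent degenerate fit.
* Inner Newton iterations warm-start from the previous outer
  iteration's $\hat\eta$.
* All stochastic entry points (`simulate_cohort()`, `ppk_bootstrap()`,
  `ppk_vpc()`, the CLI) take an explicit seed and are bit-reproducible
  given it; the estimation engine itself is deterministic.

## Problem sizes used in the shipped checks

The packaged test-suite runs the deterministic identities at full
precision and the stochastic properties at these scales, chosen as the
smallest sizes at which each property is statistically meaningful:
parameter recovery on one 316-subject cohort (the study's size) plus
20 replicate cohorts for median bias; forward-gate calibration on 20
cohorts; full stepwise selection on 5 cohorts; bootstrap with 200
resamples of a 50-subject cohort; VPC with 200 simulated replicates of
a 300-subject design. The bootstrap and VPC scales are explicit
scale-downs of the reference workflow's 2000 and 1000.

## Limitations

* FOCE only (with optional no-interaction variant); no SAEM/MCMC, no
  full $\Omega$ covariance matrices, no autocorrelated residuals.
* Linear elimination only — vancomycin shows no saturable clearance in
  this population; Michaelis–Menten and oral absorption are out of
  scope, as are three-compartment models.
* M1 handling of BQL data (exclusion); censored-likelihood (M3)
  handling is not implemented because the motivating dataset contains
  no BQL observations.
* Bootstrap and VPC assume the fitted model family; they evaluate
  stability and predictive coverage, not structural misspecification.
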