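---
title: "Population PK of a body-weight-dosed antibody: model, estimation and qualification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population PK of a body-weight-dosed antibody: model, estimation and qualification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`mabpk` implements a complete sparse-data population-pharmacokinetic
workflow for an intravenously infused monoclonal antibody dosed by body
weight (15 mg/kg every 21 days), of the kind used to compare a biosimilar
with its reference product in a parallel-group oncology trial. This
vignette documents the model, the estimation method, the synthetic-data
generator, and the numerical and design choices a maintainer should know
about.

## Structural model

Drug disposition follows a two-compartment model with zero-order input
(constant-rate infusion) and first-order elimination from the central
compartment, parameterised by clearance $CL$ (L/h), central volume $V_1$
(L), intercompartmental clearance $Q$ (L/h) and peripheral volume $V_2$
(L). With micro constants $k_{10} = CL/V_1$, $k_{12} = Q/V_1$,
$k_{21} = Q/V_2$, the hybrid constants $\alpha \ge \beta$ are the roots of
$\lambda^2 - (k_{10}+k_{12}+k_{21})\lambda + k_{10}k_{21} = 0$.

The production path is the closed-form bi-exponential solution, not an ODE
integrator: the concentration under a never-ending infusion at rate $R$
started at time 0 is
$$C_\infty(t) = \frac{R}{V_1}\left[\frac{A}{\alpha}(1-e^{-\alpha t}) +
\frac{B}{\beta}(1-e^{-\beta t})\right],\qquad
A = \frac{\alpha - k_{21}}{\alpha-\beta},\;
B = \frac{k_{21} - \beta}{\alpha-\beta},$$
and a finite infusion of duration $D$ is the superposition
$C_\infty(t) - C_\infty(t-D)$. Multiple doses superpose linearly. This
choice is driven by speed: the expression sits inside the innermost loop
of the estimation engine. The test suite carries an independent oracle — a
matrix-exponential propagation of the linear mass-balance system — and
requires agreement to $10^{-8}$ relative.

Three numerical guards matter:

* `1 - exp(-x)` is evaluated as `-expm1(-x)`. For near-linear fixtures
  (tiny rate constants) the naive form loses seven significant digits and
  visibly corrupts finite-difference Jacobians.
* runs of identical, equally spaced maintenance doses are collapsed into a
  geometric series in $e^{-\lambda\Delta}$, summed from the most recent
  dose backwards so all terms are $\le 1$. This makes a 16-cycle regimen
  cost the same as ~3 doses and gives a several-fold speedup of a fit.
* $Q = 0$ falls back to the one-compartment closed form, and
  $|\alpha-\beta| < 10^{-10}\alpha$ to a guarded repeated-root limit
  (unreachable from realistic parameters, but cheap insurance).

## Statistical model

Inter-individual variability is exponential, $P_j = TVP \cdot
e^{\eta_j}$, with $\eta \sim N(0, \omega^2)$ on $CL$ and $V_1$ only and a
diagonal $\Omega$; sparse trough-dominated sampling does not support
random effects on the peripheral parameters, mirroring the reference
analyses of this drug class. Residual error is additive on the log scale,
$$\ln Y_{ij} = \ln F_{ij} + W\,\varepsilon_{ij},\qquad
\varepsilon \sim N(0,1),$$
so $W$ is (approximately) the proportional residual CV.

Covariate effects multiply the typical values:
power terms $(\mathrm{COV}/\mathrm{COV_{ref}})^\theta$ for continuous
covariates (reference = population median, 71 kg for weight), fractional
terms $1 + \theta$ for categorical levels, and the ratio form
$\theta^{\mathrm{COV}}$ (COV $\in \{0,1\}$) for the drug-product effect.
The ratio form keeps the reference group at exactly 1 and makes $\theta$
directly the biosimilar-to-reference ratio; it is also estimated on the
log scale, which is numerically kinder around 1 than a fractional term
near 0.

The published final model for this drug, available as
`bev_final_params()`/`bev_final_spec()`, is
$$CL = 0.0113\ \mathrm{L/h} \times (BWT/71)^{0.354} \times 1.262^{[male]}
\times 1.02^{[test]},$$
$$V_1 = 2.99\ \mathrm{L} \times (BWT/71)^{0.468} \times 1.247^{[male]}
\times 1.07^{[test]},$$
with $\omega^2_{CL} = 0.0871$ (CV 29.5%), $\omega^2_{V_1} = 0.117$
(CV 34.2%) and $W = 0.284$. IIV is reported as
$\mathrm{CV\%} = 100\sqrt{\omega^2}$ — the convention under which those
printed CVs and variances are mutually consistent — rather than the exact
log-normal form $100\sqrt{e^{\omega^2}-1}$.

## FOCE-I estimation

`fit_foce()` minimises the first-order-conditional approximation to
$-2\log$ marginal likelihood. Per subject, the empirical Bayes mode
$\hat\eta$ minimises
$\|\ln y - \ln F(\eta)\|^2/W^2 + \eta^\top\Omega^{-1}\eta$
(damped Gauss-Newton in dimension $\le 2$, finite-difference Jacobian,
gradient tolerance $10^{-8}$, warm-started from the previous outer
iteration). The marginal contribution is
$$\mathrm{OFV}_i = \log\det\Sigma_i + r_i^\top\Sigma_i^{-1}r_i,\qquad
\Sigma_i = G_i\,\Omega\,G_i^\top + W^2 I,\quad
r_i = \ln y_i - \ln F_i(\hat\eta_i) + G_i\hat\eta_i,$$
with $G_i$ the Jacobian of the log-predictions at $\hat\eta_i$. Because
the residual scale is constant on the log scale, the $\eta$–$\varepsilon$
interaction term is exact by construction here. The additive
$n\log 2\pi$ constant is omitted, so absolute OFV values are comparable
only within this package; all inference uses OFV differences. On models
linear in $\eta$ the approximation is exact, which the suite checks to
$10^{-6}$ against the closed-form marginal likelihood.

The outer problem runs PORT (`nlminb`) over transformed parameters:
typical values, ratio coefficients, variances and $W$ on the log scale;
power/fractional coefficients unconstrained. PORT's "false convergence"
diagnostic is frequent with finite-difference gradients over a
conditionally optimised objective; the fitter restarts from the candidate
optimum and accepts when a restart no longer improves the OFV by more than
$10^{-3}$. Standard errors come from the inverse central-difference
Hessian of OFV/2 (step $10^{-3}$ on the transformed scale) with a
delta-method back-transform; a sandwich (robust) estimator over
per-subject score cross-products is available via
`se_method = "sandwich"`. The condition number reported is the
eigenvalue ratio of the estimates' correlation matrix, with > 1000 used as
the overparameterisation flag. Shrinkage follows the usual definitions,
$\eta$: $100(1 - SD(\hat\eta)/\omega)$; $\varepsilon$:
$100(1 - SD(\mathrm{IWRES}))$.

## Synthetic trials

`simulate_trial()` emulates a two-product (1:1), 705-subject by default,
21-day-cycle design: 15 mg/kg at the **baseline** body weight each cycle
(the protocol does not describe re-weighing, so doses are fixed at
baseline — flagged as an assumption), infusion durations stepping 90, 60,
30 minutes over the first three cycles, pre-dose troughs from cycle 2
onward, samples 1 h after the end of infusion at cycles 1 and 5, and an
end-of-treatment sample one cycle after the last dose. 16 cycles
(~1 year) by default, optionally with geometric dropout after cycle 6.
The LLOQ is 0.25 mg/L (250 ng/mL); values strictly below are flagged,
never silently deleted.

Covariates: body weight log-normal with median 71 kg, log-SD 0.2,
truncated to the printed 28–135 kg range (the source table gives only
median and range; log-SD 0.2 reproduces a realistic adult spread and is
exposed as a parameter); sex male with probability 0.648; drug product
Bernoulli(1/2). Optional extras (albumin, ALT, ALP, longest tumor
diameter) are log-normal around the printed medians truncated to the
printed ranges with log-SDs (0.12, 0.5, 0.45, 0.55) chosen once to give
plausible clinical spans; they exist for covariate-screening exercises
and carry no effect on the simulated kinetics. Permuted-copy "null"
covariates are available for selection-power tests.

Each subject draws from an independent seed substream, so a subject's
records do not depend on cohort size or ordering. The cycle-1 pre-dose
sample is *not* generated: in a carryover-free simulation its model value
is exactly zero and has no log-scale likelihood; the corresponding
real-data rule (first-dose pre-dose > 2×LLOQ excluded) is exercised on
constructed fixtures instead.

What a green simulation-based test does **not** establish: the generator
has deterministic nominal sampling times by default (a ±0.5 h jitter
option exists), no missed visits or dose interruptions, no
assay batch effects, no time-varying weight and no
target-mediated/nonlinear elimination. Recovery results therefore speak
to estimator correctness under the stated model, not to robustness
against real-world protocol deviations.

## Dataset rules

`apply_exclusions()` implements the two pre-modeling rules with an audit
trail: (a) first-dose pre-dose observations with DV > 2×LLOQ (strict
inequality), and (b) post-dose observations with DV < LLOQ (strict), the
"M1" convention of discarding below-quantification samples — defensible
here because the BLQ fraction is far below 1%. Pre-dose samples at later
cycles are never excluded by rule (a). A handful of missing baseline
covariates can be median-imputed with per-subject flags
(`impute_missing_covariates()`), the least-surprise default when the
source of missingness is uninformative. Dose rows are never removed, and
the operation is idempotent. The BLQ fraction is reported as a percent of
post-dose observations to two decimals (e.g. 37/8004 → "0.46%").

## Covariate selection, outliers, bootstrap, VPC

Stepwise covariate modeling uses forward inclusion at $\alpha = 0.05$ and
backward elimination at $\alpha = 0.001$ (likelihood-ratio tests, df = 1
per term), with deterministic tie-breaking (largest $\Delta$OFV, then
lexicographic). Forced terms — the drug-product ratio, retained to
*quantify* the product effect rather than to test it — never leave the
model. CL and V1 terms for the same covariate are tested separately, the
reading most consistent with separately printed sex effects; candidates
are user-supplied, with `eta_screen()` automating the usual
eta-vs-covariate screening statistics but not the judgment call.

Outliers are observations with |CWRES| > 6 or |IWRES| > 6. CWRES is the
whitened marginal residual of the FOCE linearisation about $\hat\eta$
(the conventional conditional-residual construction, pinned here because
the name alone underdetermines the formula); IWRES is
$(\ln y - \ln F(\hat\eta))/W$. Influence is assessed by refitting without
flagged rows: a change of more than 20% in any key parameter adopts the
no-outlier fit, reproducing the sensitivity-analysis procedure used in
practice.

The bootstrap resamples subjects (the exchangeable unit) with
replacement, refits each replicate, and reports 2.5/50/97.5 percentile
intervals over converged replicates, unstratified by default (a
drug-product stratification option exists). The VPC simulates the
original design (doses, times, covariates) at the estimates, bins by the
protocol's nominal sample tags, and compares observed percentiles with
the simulated percentile distributions; simulated below-LLOQ values are
excluded by default with the fraction reported, and can be retained,
since the source analysis does not state its convention. Production scale
is 1000 bootstrap replicates and 1000 VPC trials; the test profile scales
replicate counts down (never tolerances) to fit a CI budget.

## Known limitations

* Absolute OFV values are not comparable with other software's objective
  conventions; only differences are.
* The inner Jacobian is finite-difference; analytic sensitivities would
  cut another factor from runtime.
* $\Omega$ is diagonal by design; a full covariance is out of scope, as
  are SAEM/Bayesian estimation and likelihood-based (M3) BLQ handling.
* At 100-subject scale the weakly identified $Q$ (its published RSE
  exceeds 100%) wanders; $V_1$ inherits some of that variability, which
  is why recovery criteria average over seeds.
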