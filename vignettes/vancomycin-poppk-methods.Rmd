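---
title: "Methods: population pharmacokinetics of vancomycin after pediatric liver transplantation"
author: "vanpop authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population pharmacokinetics of vancomycin after pediatric liver transplantation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vanpop)
```

This vignette documents the models, numerical methods and design choices
behind `vanpop`, in the spirit of a statistical methods appendix. It states
no empirical result that the package's tests and acceptance script do not
themselves compute.

## Structural and statistical model

Vancomycin disposition is described by a one-compartment model with
zero-order (constant-rate) infusion input and first-order elimination. For
an infusion of rate $R$ (mg/h) starting at $t_0$ with duration $T_{inf}$,

$$
C(t) = \frac{R}{CL}\left(1 - e^{-k_e (t - t_0)}\right), \quad t_0 < t \le t_0 + T_{inf},
$$

decaying as $C(t_1) e^{-k_e (t - t_1)}$ after the infusion ends at $t_1$,
with $k_e = CL/V$. Linear pharmacokinetics lets multiple doses superpose,
which also yields the closed-form steady-state trough and the identity
$AUC_{24,ss} = \text{daily dose}/CL$ used throughout the dosing module.

Individual parameters combine fixed covariate effects and log-normal
between-subject variability:

$$
CL_i = \theta_{CL}\, wt_i^{0.75} \left(\frac{sCr_i}{0.16}\right)^{\theta_{sCr}}
\left(\frac{DFLT_i}{17}\right)^{\theta_{DFLT}} e^{\eta_{CL,i}}, \qquad
V_i = \theta_V\, wt_i\, e^{\eta_{V,i}},
$$

with $\eta \sim N(0, \omega^2)$, diagonal. The allometric weight exponents
(0.75 for clearance, 1.0 for volume) are fixed a priori, the standard
choice for scaling pediatric clearance. Covariate power terms are
normalised at the cohort medians (sCr 0.16 mg/dl, DFLT 17 days) and the
references are deliberately *not* recomputed from input data, so the
coefficients keep their printed interpretation. Days-from-transplant values
of 0 occur in the data; the power term floors DFLT at 1 day
(configurable), the smallest whole day that keeps the model finite while
changing nothing else materially.

Residual error is combined additive/proportional,
$y = f (1 + \varepsilon_p) + \varepsilon_a$, with pure additive,
proportional and exponential (log-normal) variants selectable per model
specification. The final covariate model uses a proportional term only: in
model building the additive component collapses towards zero, and the
published final model lists only the proportional SD.

Covariates are treated as constant within a treatment episode (baseline
values); repeated episodes of one patient are treated as independent
records, mirroring an analysis of ~270 profiles from 161 patients. This
overstates independence slightly but matches the information actually
available at estimation time.

## Estimation

The marginal likelihood of each episode integrates the conditional density
over $(\eta_{CL}, \eta_V)$. The compiled core:

1. maximises the joint log-density $h(\eta)$ by a safeguarded
   Levenberg-style Newton iteration with analytic gradients of the
   closed-form concentration with respect to $\log CL$ and $\log V$ (the
   curvature comes from central differences of the analytic gradient), with
   an expanding gradient-ascent fallback for long flat valleys; the pure
   Laplace path additionally guards the mode search with a deterministic
   three-point multistart;
2. integrates around the mode by adaptive Gauss–Hermite quadrature (5
   nodes per dimension by default, 7 selectable; `nodes = 1` gives the
   pure Laplace approximation, used when benchmarking against high-order
   quadrature). Curvature eigenvalues are floored at a quarter of the
   prior precision, so weakly identified (flat) directions are integrated
   rather than approximated quadratically;
3. episodes whose conditional density can be multimodal are integrated on
   a fixed prior-centred Gauss–Hermite grid (24-point rule pruned to the
   20 nodes within 5.2 prior SDs) instead of mode-centred quadrature.
   Under a large proportional error, multimodality arises when a
   below-quantification observation or a very low quantified
   concentration conflicts with higher ones ("fast clearance" versus
   "outlier" explanations), so the route is chosen by data flags —
   censoring present, or minimum quantified concentration below 1 ug/ml
   with at least an 8-fold spread — plus a flat-curvature check at the
   mode. Because the flags depend only on the data, the route never
   toggles as the population parameters move, and the fixed grid is
   smooth in those parameters: the objective stays well-behaved for the
   outer optimiser while resolving every basin of such densities.

The objective function value (OFV) is $-2 \sum_i \log L_i$. Outer
optimisation runs `nlminb` on transformed parameters (log scale for all
positive quantities, identity for covariate exponents) inside a generous
box ($\pm 15$ on the transformed scale) so that variance components of
truly degenerate magnitude stop at a tiny floor instead of drifting to
$-\infty$. `nlminb` occasionally reports "false convergence" at a genuine
optimum; the fit then probes small coordinate steps ($\pm 0.005, \pm 0.02$)
and either restarts from a real improvement or accepts the point as a local
minimiser. Standard errors come from the numerical Hessian of the OFV
(covariance $2 H^{-1}$), delta-method transformed to the natural scale.

Empirical Bayes (post hoc) estimates are the conditional modes $\hat\eta_i$;
$\eta$-shrinkage is $1 - SD(\hat\eta)/\omega$ (reported as 1 when
$\omega = 0$), and $\varepsilon$-shrinkage is $1 - SD(IWRES)$ at the
individual predictions. Between-subject variability is parameterised and
reported as the SD of the log random effect ($\omega \times 100$ when shown
as a percentage); at the magnitudes involved (~0.46) this is numerically
close to the CV% convention (46 vs 48.6), and the package documents its
choice rather than guessing which convention a given report used.

Observations flagged below the quantification floor (0.1 ug/ml) enter the
likelihood as left-censored terms, $\log \Phi\!\big((L - f)/\sqrt{v}\big)$
(the "M3" method). This matches the observation model of the synthetic
data exactly — values below the floor are recorded at the floor and
flagged — and avoids both the spurious spikes that treating the floored
value as an exact measurement creates in the conditional densities and
the downward bias in the proportional error that simply dropping the
flagged observations (M1) would cause: at the study's 56.5% noise level a
few percent of simulated observations fall below the floor, enough to
truncate the residual distribution noticeably.

## Covariate selection

Candidate effects (age, sex, underlying disease, sCr, albumin, ALT, DFLT on
CL and on V) enter continuous covariates as median-normalised power terms
and categorical covariates (male = 1, biliary atresia = 1) as
multiplicative factors. The search fits every univariate extension
(screening table), then adds the best candidate while the OFV drop exceeds
3.84 ($\chi^2_1$, $p < 0.05$) and finally removes any covariate whose
deletion raises the OFV by less than 7.88 ($p < 0.005$). Candidate fits
that fail to converge are recorded as not selectable and the search
continues.

## Validation

The bootstrap resamples episodes (the independent unit) with replacement,
refits each resample warm-started at the original estimates — documented
because a warm start can in principle mask multimodality of the outer
problem — and summarises percentile 2.5/50/97.5 intervals over converged
refits, with the convergence rate reported. The VPC simulates replicate
datasets at the original design, bins observations on time after the most
recent dose (default 8 quantile-spaced bins; the binning is a package
choice, not prescribed by the study), and overlays observed
5th/50th/95th percentiles on the simulated percentile bands; the summary
statistic is the fraction of observations inside the simulated 90%
prediction interval. CWRES uses the standard FOCE first-order expansion
about the conditional modes.

## Dosing simulations

For each virtual subject (covariates drawn from the synthetic cohort
generator or resampled from a user-supplied table, $\eta$ drawn from the
fitted $\omega$), the steady-state trough (closed form) and
$AUC_{24} = \text{daily dose}/CL$ are evaluated against the targets
trough $\ge 10$ ug/ml and $AUC_{24}/MIC \ge 400$ (MIC 0.5, 1, 2 ug/ml).
The comparison is $\ge$ by default ("\>" is configurable; the difference
has measure zero in a continuous simulation). AUC is computed at steady
state; a first-24-h window would give smaller values early in therapy, and
steady state is the interpretation consistent with a daily-dose/CL
identity. Attainment is reported overall, by DFLT stratum (< 14 vs >= 14
days) and by Schwartz creatinine clearance
($CLCr = k \cdot height / sCr$, $k$ = 0.45 below 12 months, 0.70 for
adolescent males, 0.55 otherwise; CLCr stratifies only — the PK model uses
sCr and DFLT directly). Published attainment percentages depend on the
original cohort's joint covariate distribution, which is not public;
with a synthetic cohort the package reproduces the qualitative structure
(orderings in dose, MIC and DFLT) rather than exact percentages.

## The synthetic cohort generator

The generator emulates — it does not reconstruct — the study population:

* Continuous covariates are truncated log-normals matched to the published
  median and IQR (log-scale SD $(\ln Q3 - \ln Q1)/1.349$) and truncated to
  the published ranges: weight median 9.1 kg (6.8–16.2, range 3.1–61),
  sCr 0.16 mg/dl (0.12–0.23, range 0.06–5.43), DFLT 17 days (6–31, range
  0–357, rounded to whole days), albumin and ALT likewise.
* Height follows an allometric curve through the cohort's median and
  extremes ($ht \approx 23.85\, wt^{0.49}$) with 4.5% log-normal noise;
  age follows a growth-curve approximation
  ($age \approx 0.093\, wt^{2.25}$ months) with 30% noise, both truncated
  to the published ranges. Other covariates are drawn independently; the
  real cohort's full joint distribution (e.g. sCr–age correlation) is not
  published and is not emulated — a stated limitation.
* Sex is male with probability 0.447 and the underlying disease biliary
  atresia with probability 0.522.
* Each subject contributes $1 + \text{Poisson}(0.677)$ treatment episodes
  (mean 1.68, matching 270 episodes from 161 patients). Episodes dose
  15 mg/kg (1-h infusions) q6h below age 13 years and q8h above, for 5
  doses; one trough is sampled 0.05 h before the 4th or 5th dose and
  $\text{Poisson}(3.29)$ further samples are drawn uniformly over the
  treatment window, giving ~4.3 observations per episode and ~1,150 total
  at $n = 161$ — the study's sampling density.
* Residual noise follows the fitted combined model; simulated values below
  0.1 ug/ml are floored there and flagged below-quantification.
* All randomness flows from a single integer seed.

Because the generator shares the structural and residual model with the
estimator, parameter-recovery tests demonstrate the correctness of the
estimation machinery under the study's design — not robustness to model
misspecification, assay artefacts, or covariate measurement error in real
data.

## Numerical choices and problem sizes

Default quadrature is 7 adaptive nodes per random-effect dimension; the
acceptance experiment fits 161 virtual patients (~270 episodes, ~1,150
concentrations) in a few seconds on one core. The test suite scales the
stochastic studies to keep the whole run lightweight: 200 bootstrap
resamples of a 30-subject cohort (the full analysis would use 1,000), a
200-replicate null-calibration study of forward selection on 40-subject
datasets, and 150–200 VPC replicates. These sizes are the package's own
trade-off between Monte Carlo error and runtime and are stated alongside
the corresponding tolerances in the tests.

## Known limitations

* Exact conditional residuals, prediction-corrected VPC and npde are out of
  scope; CWRES uses the FOCE linearisation.
* Inter-occasion variability and correlated (full-block) $\omega$ matrices
  are not implemented — the final model is diagonal.
* Below-quantification observations are excluded (M1) rather than treated
  by censored-likelihood (M3) methods.
* Two-compartment kinetics, nonlinear elimination and continuous-infusion
  regimens are out of scope.
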