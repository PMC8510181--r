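# vanpop

Population pharmacokinetics of intravenous vancomycin in pediatric liver
transplant recipients: model estimation, validation and dosing simulation.

## The problem

Vancomycin is first-line therapy for MRSA infections after pediatric liver
transplantation. Its efficacy tracks the ratio of the 24-hour area under the
concentration-time curve to the pathogen's MIC (target AUC24/MIC >= 400),
with the steady-state trough (>= 10 ug/ml) as the classical surrogate.
Transplant physiology changes both clearance and distribution, so standard
pediatric dosing may under-expose these patients. `vanpop` implements the
full analysis pipeline a pharmacometrician would run on such a cohort:

* **Structural model** — one-compartment, zero-order IV infusion, first-order
  elimination, solved in closed form and superposed over dosing histories.
* **Covariate model** — allometric weight scaling with power-law covariate
  effects on clearance:

  ```
  CL_i (L/h) = theta_CL * wt^0.75 * (sCr/0.16)^theta_sCr * (DFLT/17)^theta_DFLT * exp(eta_CL)
  V_i  (L)   = theta_V * wt * exp(eta_V)
  ```

  where sCr is serum creatinine (mg/dl) and DFLT the number of days from
  liver transplantation to the start of vancomycin; eta ~ N(0, omega^2) are
  log-normal between-subject random effects.
* **Estimation** — nonlinear mixed-effects maximum likelihood. Per-subject
  marginal likelihoods use the Laplace approximation refined by adaptive
  Gauss–Hermite quadrature (compiled core), with empirical Bayes (post hoc)
  individual estimates, shrinkage, and standard errors from the numerical
  Hessian.
* **Covariate selection** — univariate screening, stepwise forward inclusion
  (ΔOFV > 3.84, p < 0.05) and backward elimination (ΔOFV > 7.88, p < 0.005).
* **Validation** — nonparametric bootstrap (subject resampling) and visual
  predictive checks, plus PRED/IPRED/IWRES/CWRES goodness-of-fit tables.
* **Dosing simulation** — Monte Carlo probability-of-target-attainment
  tables for candidate regimens, stratified by DFLT (< 14 vs >= 14 days) and
  Schwartz creatinine clearance.
* **Synthetic cohort generator** — virtual patients whose covariate
  distributions and trough-based TDM sampling emulate the study population,
  so every stage runs and is tested without patient data.

## Worked example

```r
library(vanpop)

# simulate a cohort of 30 virtual patients and fit the final model
d <- simulate_dataset(30, seed = 7)
f <- fit_nlme(d, final_model_spec())
f
#> Population PK fit (Laplace): 64 episodes, 261 observations
#>   OFV 1771.689, converged
#>     parameter estimate     se rse_pct
#>      theta_CL  0.27690 0.0198     7.1
#>   beta_sCr_CL -0.75050 0.1240    16.5
#>  beta_DFLT_CL -0.04235 0.0590   139.4
#>       theta_V  1.00200 0.1130    11.3
#>      omega_CL  0.40900 0.0463    11.3
#>       omega_V  0.52650 0.0677    12.9
#>    sigma_prop  0.53420 0.0339     6.3
#>   eta-shrinkage CL 19.1%, V 23.5%; eps-shrinkage 21.5%
```

Each row is a model parameter with its maximum-likelihood estimate, standard
error and relative standard error; the large RSE on `beta_DFLT_CL` reflects
how weakly a 30-patient cohort identifies that small exponent (the published
analysis reported ~35% at 161 patients).

`theta_CL` is the clearance of a 1-kg reference patient (L/h per kg^0.75 at
sCr 0.16 mg/dl, DFLT 17 days); the negative `beta_sCr_CL` and `beta_DFLT_CL`
say that higher creatinine and longer time since transplantation both lower
clearance. `sigma_prop` is the proportional residual SD (~50% here) and the
omegas are between-subject SDs of log CL and log V.

Dosing simulation against the trough and AUC24/MIC targets:

```r
tab <- simulate_attainment(as_pop_params(f), covariate_distribution_spec(),
                           list(regimen_spec(15, 8), regimen_spec(15, 6),
                                regimen_spec(20, 6)),
                           list(pd_target("trough"),
                                pd_target("auc_mic", mic = 1)),
                           n_profiles = 1000, seed = 1)
attainment_report(tab)
#> Attainment by DFLT (excerpt)
#>                                           <14 days >=14 days
#> 15 mg/kg q6h | Trough >= 10 ug/ml         48.6%    54.5%
#> 15 mg/kg q6h | AUC24/MIC >= 400 (MIC = 1) 44.2%    53.9%
#> 20 mg/kg q6h | Trough >= 10 ug/ml         61.1%    69.5%
#> 20 mg/kg q6h | AUC24/MIC >= 400 (MIC = 1) 66.2%    72.4%
```

Early post-transplant patients (DFLT < 14 days, higher clearance) attain
every target less often, and attainment rises with the daily dose — the
motivation for DFLT-aware dosing. The size of the contrast tracks the
fitted DFLT exponent, which this small example cohort estimates weakly.

A command-line interface with the same functionality (`simulate`, `fit`,
`stepwise`, `bootstrap`, `vpc`, `mcs` subcommands driven by a YAML config)
is available as `exec/vanpop`.

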