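#' Construct intravenous infusion dose events
#'
#' @param start_time infusion start, hours since first dose.
#' @param amount dose amount, mg.
#' @param duration infusion length, hours.
#' @return A data.frame with columns `time`, `amount`, `duration`, `rate`
#'   (mg/h), one row per dose, ordered by time.
#' @examples
#' dose_event(c(0, 6), 150, 1)
#' @export
dose_event <- function(start_time, amount, duration = 1) {
  d <- data.frame(time = start_time, amount = amount, duration = duration)
  if (any(d$amount <= 0)) stop("dose amount must be positive")
  if (any(d$duration <= 0)) stop("infusion duration must be positive")
  if (any(d$time < 0)) stop("dose start time must be >= 0")
  d <- d[order(d$time), , drop = FALSE]
  d$rate <- d$amount / d$duration
  rownames(d) <- NULL
  d
}

#' Typical (population) clearance at given covariates
#'
#' Allometric weight scaling (exponent 0.75) with median-normalised power
#' terms for serum creatinine and days from liver transplantation:
#' `theta_CL * wt^0.75 * (sCr/ref_sCr)^exp_sCr * (DFLT/ref_DFLT)^exp_DFLT`.
#' DFLT values below `p$dflt_floor` (day-0 starts) are floored so the power
#' term stays finite.
#'
#' @param cov covariates: data.frame or named list with at least `weight`
#'   (kg), `sCr` (mg/dl) and `DFLT` (days); vectorised over rows.
#' @param p a [population_params()] object.
#' @return Typical clearance, L/h.
#' @examples
#' typical_clearance(list(weight = 9.1, sCr = 0.16, DFLT = 17),
#'                   population_params())
#' @export
typical_clearance <- function(cov, p) {
  cov <- as_covariates(cov)
  dflt <- pmax(cov$DFLT, p$dflt_floor)
  p$theta_CL * cov$weight^0.75 *
    (cov$sCr / p$ref_sCr)^p$exp_sCr *
    (dflt / p$ref_DFLT)^p$exp_DFLT
}

#' Typical (population) volume of distribution
#'
#' Linear in body weight: `theta_V * wt`.
#'
#' @inheritParams typical_clearance
#' @return Typical volume, L.
#' @export
typical_volume <- function(cov, p) {
  cov <- as_covariates(cov)
  p$theta_V * cov$weight
}

#' Individual parameters from covariates and random effects
#'
#' Applies the exponential (log-normal) between-subject model:
#' `CL = TVCL * exp(eta_CL)`, `V = TVV * exp(eta_V)`.
#'
#' @inheritParams typical_clearance
#' @param eta_CL,eta_V random-effect values on the log scale.
#' @return A list with elements `CL` (L/h), `V` (L) and `k_e` (1/h).
#' @export
individual_params <- function(cov, p, eta_CL = 0, eta_V = 0) {
  stopifnot(all(is.finite(eta_CL)), all(is.finite(eta_V)))
  CL <- typical_clearance(cov, p) * exp(eta_CL)
  V <- typical_volume(cov, p) * exp(eta_V)
  structure(list(CL = CL, V = V, k_e = CL / V), class = "indiv_params")
}

#' Concentration-time profile under intermittent infusions
#'
#' Closed-form one-compartment solution with zero-order infusion input and
#' first-order elimination, superposed over all doses. During an infusion
#' started at \eqn{t_0}: \eqn{(R/CL)(1 - e^{-k_e (t - t_0)})}; afterwards the
#' end-of-infusion value decays as \eqn{e^{-k_e (t - t_1)}}.
#'
#' @param t times, hours since first dose (vectorised). Times before the
#'   first dose return 0.
#' @param doses dose table from [dose_event()] (columns `time`, `amount`,
#'   `duration`, `rate`).
#' @param ip individual parameters from [individual_params()], or any list
#'   with scalar `CL` and `V`.
#' @return Concentrations, ug/ml.
#' @examples
#' ip <- list(CL = 1.52, V = 9.19)
#' concentration(c(0, 1, 6), dose_event(0, 136.5, 1), ip)
#' @export
concentration <- function(t, doses, ip) {
  stopifnot(all(t >= 0), ip$CL > 0, ip$V > 0)
  conc_profile_cpp(as.numeric(t), as.numeric(doses$time),
                   as.numeric(doses$rate), as.numeric(doses$duration),
                   ip$CL, ip$V)
}

#' Steady-state trough concentration of an intermittent regimen
#'
#' Closed form for dosing every `interval` hours with infusion length
#' `infusion_duration`:
#' \deqn{C_{min,ss} = \frac{R}{CL}\,(1 - e^{-k_e T_{inf}})\,
#'       \frac{e^{-k_e(\tau - T_{inf})}}{1 - e^{-k_e \tau}}}
#'
#' @param reg a [regimen_spec()]; the mg/kg dose is converted to mg with the
#'   subject's weight.
#' @param cov covariates (needs `weight`).
#' @param ip individual parameters (scalar `CL`, `V`).
#' @return Trough concentration immediately before a steady-state dose, ug/ml.
#' @export
steady_state_trough <- function(reg, cov, ip) {
  if (reg$interval <= reg$infusion_duration)
    stop("dosing interval must exceed the infusion duration")
  cov <- as_covariates(cov)
  amt <- reg$dose_mg_kg * cov$weight
  R <- amt / reg$infusion_duration
  ke <- ip$CL / ip$V
  (R / ip$CL) * (1 - exp(-ke * reg$infusion_duration)) *
    exp(-ke * (reg$interval - reg$infusion_duration)) /
    (1 - exp(-ke * reg$interval))
}

#' Steady-state 24-hour AUC
#'
#' For linear pharmacokinetics the steady-state area under the curve over a
#' 24-h window equals daily dose / CL.
#'
#' @param daily_dose total daily dose, mg.
#' @param CL clearance, L/h.
#' @return AUC over 24 h at steady state, mg·h/L.
#' @examples
#' auc24_at_steady_state(546, 1.52)
#' @export
auc24_at_steady_state <- function(daily_dose, CL) {
  if (any(daily_dose <= 0) || any(CL <= 0))
    stop("daily_dose and CL must be positive")
  daily_dose / CL
}

#' Candidate dosing regimen
#'
#' @param dose_mg_kg dose per administration, mg/kg.
#' @param interval dosing interval, hours.
#' @param infusion_duration infusion length, hours (default 1 h, standard
#'   intermittent vancomycin practice).
#' @param label display label; defaults to e.g. `"15 mg/kg q6h"`.
#' @return An object of class `regimen_spec`.
#' @export
regimen_spec <- function(dose_mg_kg, interval, infusion_duration = 1,
                         label = sprintf("%g mg/kg q%gh", dose_mg_kg, interval)) {
  stopifnot(dose_mg_kg > 0, infusion_duration > 0)
  if (interval <= infusion_duration)
    stop("dosing interval must exceed the infusion duration")
  structure(list(dose_mg_kg = dose_mg_kg, interval = interval,
                 infusion_duration = infusion_duration, label = label),
            class = "regimen_spec")
}

#' @export
print.regimen_spec <- function(x, ...) {
  cat(sprintf("Regimen: %s (%g-h infusion)\n", x$label, x$infusion_duration))
  invisible(x)
}
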