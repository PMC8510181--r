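#' Population pharmacokinetic parameters
#'
#' Container for the fixed effects, between-subject variability and residual
#' error of the vancomycin population model
#' \deqn{CL_i = \theta_{CL}\, wt^{0.75} (sCr/0.16)^{\theta_{sCr}}
#'       (DFLT/17)^{\theta_{DFLT}} e^{\eta_{CL}}, \qquad
#'       V_i = \theta_V\, wt\, e^{\eta_V}}
#' with clearance in L/h, volume in L, weight in kg, serum creatinine (sCr) in
#' mg/dl and days from liver transplantation (DFLT) in days. Defaults are the
#' final-model study estimates.
#'
#' @param theta_CL clearance coefficient, L/h per kg^0.75 at reference
#'   covariates (sCr 0.16 mg/dl, DFLT 17 days).
#' @param theta_V volume coefficient, L/kg.
#' @param exp_sCr power exponent of sCr/0.16 on clearance (negative: higher
#'   creatinine, lower clearance).
#' @param exp_DFLT power exponent of DFLT/17 on clearance.
#' @param ref_sCr,ref_DFLT reference covariate values (study medians) used to
#'   normalise the power terms; fixed, not recomputed from data, so the
#'   coefficients keep their printed interpretation.
#' @param omega_CL,omega_V standard deviations of the log-normal
#'   between-subject random effects on CL and V.
#' @param sigma_prop proportional residual SD (fraction of the prediction).
#' @param sigma_add additive residual SD, ug/ml.
#' @param dflt_floor smallest DFLT (days) entered into the power term; day-0
#'   records are floored here so the power model stays finite.
#' @return An object of class `pop_params`.
#' @examples
#' p <- population_params()
#' p$theta_CL
#' @export
population_params <- function(theta_CL = 0.29, theta_V = 1.00,
                              exp_sCr = -0.70, exp_DFLT = -0.09,
                              ref_sCr = 0.16, ref_DFLT = 17,
                              omega_CL = 0.4647, omega_V = 0.4814,
                              sigma_prop = 0.565, sigma_add = 0,
                              dflt_floor = 1) {
  stopifnot(theta_CL > 0, theta_V > 0, ref_sCr > 0, ref_DFLT > 0,
            omega_CL >= 0, omega_V >= 0, sigma_prop >= 0, sigma_add >= 0,
            dflt_floor > 0, is.finite(exp_sCr), is.finite(exp_DFLT))
  if (sigma_prop == 0 && sigma_add == 0)
    stop("at least one residual-error term must be positive")
  structure(list(theta_CL = theta_CL, theta_V = theta_V,
                 exp_sCr = exp_sCr, exp_DFLT = exp_DFLT,
                 ref_sCr = ref_sCr, ref_DFLT = ref_DFLT,
                 omega_CL = omega_CL, omega_V = omega_V,
                 sigma_prop = sigma_prop, sigma_add = sigma_add,
                 dflt_floor = dflt_floor),
            class = "pop_params")
}

#' @export
print.pop_params <- function(x, ...) {
  cat("Population PK parameters (one-compartment IV infusion)\n")
  cat(sprintf("  CL (L/h) = %.4g * wt^0.75 * (sCr/%.3g)^%.3g * (DFLT/%g)^%.3g * exp(eta_CL)\n",
              x$theta_CL, x$ref_sCr, x$exp_sCr, x$ref_DFLT, x$exp_DFLT))
  cat(sprintf("  V  (L)   = %.4g * wt * exp(eta_V)\n", x$theta_V))
  cat(sprintf("  omega_CL = %.4g, omega_V = %.4g (SD of log random effects)\n",
              x$omega_CL, x$omega_V))
  cat(sprintf("  residual: proportional SD %.4g, additive SD %.4g ug/ml\n",
              x$sigma_prop, x$sigma_add))
  invisible(x)
}

# normalise a covariate argument into a data.frame with the canonical columns;
# accepts a named list or data.frame. Only columns that are used need be given.
as_covariates <- function(cov) {
  if (is.data.frame(cov)) df <- cov else df <- as.data.frame(cov, stringsAsFactors = FALSE)
  need <- c("weight", "sCr", "DFLT")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("covariates missing required fields: ", paste(miss, collapse = ", "))
  if (any(!is.finite(df$weight)) || any(df$weight <= 0) || any(df$weight > 200))
    stop("weight must be in (0, 200] kg")
  if (any(!is.finite(df$sCr)) || any(df$sCr <= 0) || any(df$sCr > 10))
    stop("sCr must be in (0, 10] mg/dl")
  if (any(df$DFLT < 0)) stop("DFLT must be >= 0 days")
  df
}
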