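#' Covariate distribution specification for the virtual study population
#'
#' Continuous covariates are drawn from truncated log-normal distributions
#' parameterised by their target median and interquartile range (log-scale SD
#' = (ln Q3 - ln Q1)/1.349) and truncated to the observed covariate ranges of
#' the study cohort. Height and age are derived from weight through smooth
#' pediatric growth approximations with multiplicative noise, so that
#' weight/height/age stay jointly plausible; this emulates, not reconstructs,
#' the joint distribution of the real cohort. Days from liver transplantation
#' (DFLT) is rounded to whole days.
#'
#' @param weight,sCr,albumin,ALT,DFLT lists with elements `median`, `q1`,
#'   `q3`, `lo`, `hi` (units: kg, mg/dl, g/dl, U/L, days).
#' @param height_range,age_range truncation bounds for the derived height
#'   (cm) and age (months).
#' @param p_biliary probability of biliary atresia as underlying disease.
#' @param p_male probability of male sex.
#' @return An object of class `cov_dist_spec`.
#' @export
covariate_distribution_spec <- function(
    weight = list(median = 9.1, q1 = 6.8, q3 = 16.2, lo = 3.1, hi = 61.0),
    sCr = list(median = 0.16, q1 = 0.12, q3 = 0.23, lo = 0.06, hi = 5.43),
    albumin = list(median = 3.1, q1 = 2.8, q3 = 3.3, lo = 1.5, hi = 4.8),
    ALT = list(median = 54.7, q1 = 27.4, q3 = 134.9, lo = 2.5, hi = 1215),
    DFLT = list(median = 17, q1 = 6, q3 = 31, lo = 0.4, hi = 357.4),
    height_range = c(48.0, 175.5),
    age_range = c(1, 186),
    p_biliary = 0.522, p_male = 0.447) {
  spec <- list(weight = weight, sCr = sCr, albumin = albumin, ALT = ALT,
               DFLT = DFLT, height_range = height_range, age_range = age_range,
               p_biliary = p_biliary, p_male = p_male)
  for (nm in c("weight", "sCr", "albumin", "ALT", "DFLT")) {
    m <- spec[[nm]]
    if (!(m$lo < m$median && m$median < m$hi))
      stop("infeasible covariate spec for ", nm,
           ": median must lie inside the truncation bounds")
    if (!(m$q1 < m$q3)) stop("infeasible covariate spec for ", nm, ": q1 >= q3")
  }
  if (p_biliary < 0 || p_biliary > 1 || p_male < 0 || p_male > 1)
    stop("probabilities must be in [0, 1]")
  structure(spec, class = "cov_dist_spec")
}

# truncated log-normal draw matched to a median/IQR target
rtrunc_lnorm <- function(n, m) {
  mu <- log(m$median)
  sdl <- (log(m$q3) - log(m$q1)) / 1.34898
  u <- runif(n, plnorm(m$lo, mu, sdl), plnorm(m$hi, mu, sdl))
  qlnorm(u, mu, sdl)
}

#' Sample baseline covariate sets for a virtual population
#'
#' @param n number of covariate sets.
#' @param spec a [covariate_distribution_spec()].
#' @param seed optional integer seed; if `NULL` the current RNG stream is
#'   used (so callers can embed this in a larger seeded simulation).
#' @return data.frame with columns `weight`, `height`, `age`, `sex` (1 =
#'   male), `sCr`, `DFLT`, `albumin`, `ALT`, `UD` (1 = biliary atresia).
#' @examples
#' head(sample_covariates(5, seed = 1))
#' @export
sample_covariates <- function(n, spec = covariate_distribution_spec(),
                              seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  wt <- rtrunc_lnorm(n, spec$weight)
  # height from weight: allometric curve through the cohort median/extremes
  ht <- 23.85 * wt^0.4855 * exp(rnorm(n, 0, 0.045))
  ht <- pmin(pmax(ht, spec$height_range[1]), spec$height_range[2])
  # age from weight: smooth growth-curve approximation, months
  age <- 0.0927 * wt^2.249 * exp(rnorm(n, 0, 0.30))
  age <- round(pmin(pmax(age, spec$age_range[1]), spec$age_range[2]), 1)
  data.frame(
    weight = wt,
    height = ht,
    age = age,
    sex = as.integer(runif(n) < spec$p_male),
    sCr = rtrunc_lnorm(n, spec$sCr),
    DFLT = round(rtrunc_lnorm(n, spec$DFLT)),
    albumin = rtrunc_lnorm(n, spec$albumin),
    ALT = rtrunc_lnorm(n, spec$ALT),
    UD = as.integer(runif(n) < spec$p_biliary)
  )
}

#' Trough-based therapeutic drug monitoring sampling design
#'
#' Emulates the study design: one trough sample drawn immediately before the
#' fourth or fifth dose, plus a random number of additional samples across
#' the treatment course. Defaults give ~4.3 observations per episode and
#' ~1.68 episodes per subject (270 episodes / 161 patients), reproducing the
#' study's overall sampling density (~1,158 observations from 161 patients).
#'
#' @param trough_dose_idx dose indices before which the monitoring trough is
#'   drawn (one is picked at random per episode).
#' @param extra_obs_rate Poisson mean of additional random samples per
#'   episode.
#' @param n_doses administered doses per episode (>= max trough index).
#' @param episodes_extra_rate Poisson mean of additional treatment episodes
#'   per subject beyond the first.
#' @param trough_offset hours before the dose at which the trough is drawn.
#' @return An object of class `sampling_design_spec`.
#' @export
sampling_design_spec <- function(trough_dose_idx = c(4, 5),
                                 extra_obs_rate = 3.29,
                                 n_doses = 5,
                                 episodes_extra_rate = 270 / 161 - 1,
                                 trough_offset = 0.05) {
  stopifnot(all(trough_dose_idx >= 2), n_doses >= max(trough_dose_idx),
            extra_obs_rate >= 0, episodes_extra_rate >= 0, trough_offset > 0)
  structure(list(trough_dose_idx = trough_dose_idx,
                 extra_obs_rate = extra_obs_rate, n_doses = n_doses,
                 episodes_extra_rate = episodes_extra_rate,
                 trough_offset = trough_offset),
            class = "sampling_design_spec")
}

#' Build an intermittent-infusion dosing history for one subject
#'
#' Doses of `dose_mg_kg * weight` mg (rounded to 0.1 mg) every `interval`
#' hours starting at time 0.
#'
#' @param cov covariates (needs `weight`).
#' @param reg a [regimen_spec()].
#' @param n_doses number of doses.
#' @return Dose table as from [dose_event()].
#' @examples
#' build_regimen_doses(list(weight = 10, sCr = 0.16, DFLT = 17),
#'                     regimen_spec(15, 6), 4)
#' @export
build_regimen_doses <- function(cov, reg, n_doses) {
  stopifnot(n_doses >= 1)
  cov <- as_covariates(cov)
  amt <- round(reg$dose_mg_kg * cov$weight, 1)
  dose_event(seq(0, by = reg$interval, length.out = n_doses),
             rep(amt, n_doses), reg$infusion_duration)
}

# study dosing policy: 15 mg/kg q6h under 13 years, q8h for adolescents
default_regimen_policy <- function(age_months) {
  if (age_months >= 156) regimen_spec(15, 8) else regimen_spec(15, 6)
}

#' Simulate a complete synthetic TDM dataset
#'
#' For each subject, episodes are generated with freshly drawn baseline
#' covariates; random effects (eta_CL, eta_V) are drawn independently per
#' episode from N(0, omega^2); doses follow the study's age-based default
#' policy (or a fixed regimen); true concentrations come from the closed-form
#' model; observations add combined residual error
#' `y = f (1 + eps_prop) + eps_add`. Simulated values falling below
#' 0.1 ug/ml are floored there and flagged `bql`.
#'
#' @param n_subjects number of virtual patients.
#' @param p true [population_params()].
#' @param cov_spec a [covariate_distribution_spec()].
#' @param design a [sampling_design_spec()].
#' @param regimen optional fixed [regimen_spec()] applied to every episode;
#'   default `NULL` uses the age-based study policy.
#' @param seed integer seed; the whole dataset is a deterministic function of
#'   it.
#' @return A [pk_dataset()]; each record carries its simulated
#'   `eta_CL`/`eta_V` as attributes `"eta"` for test harnesses.
#' @examples
#' d <- simulate_dataset(5, seed = 42)
#' d
#' @export
simulate_dataset <- function(n_subjects, p = population_params(),
                             cov_spec = covariate_distribution_spec(),
                             design = sampling_design_spec(),
                             regimen = NULL, seed = 1) {
  stopifnot(n_subjects >= 1)
  set.seed(seed)
  records <- list()
  for (i in seq_len(n_subjects)) {
    n_epi <- 1 + rpois(1, design$episodes_extra_rate)
    for (e in seq_len(n_epi)) {
      cov <- sample_covariates(1, cov_spec)
      reg <- if (is.null(regimen)) default_regimen_policy(cov$age) else regimen
      doses <- build_regimen_doses(cov, reg, design$n_doses)
      idx <- if (length(design$trough_dose_idx) > 1)
        sample(design$trough_dose_idx, 1) else design$trough_dose_idx
      t_trough <- (idx - 1) * reg$interval - design$trough_offset
      n_extra <- rpois(1, design$extra_obs_rate)
      t_extra <- runif(n_extra, 0.5, design$n_doses * reg$interval)
      times <- sort(c(t_trough, t_extra))
      eta <- c(rnorm(1, 0, p$omega_CL), rnorm(1, 0, p$omega_V))
      ip <- individual_params(cov, p, eta[1], eta[2])
      f <- concentration(times, doses, ip)
      y <- f * (1 + rnorm(length(f), 0, p$sigma_prop)) +
        rnorm(length(f), 0, p$sigma_add)
      bql <- y < 0.1
      y[bql] <- 0.1
      rec <- pk_subject(sprintf("S%04d-E%d", i, e), cov, doses,
                        data.frame(time = times, conc = y, bql = bql))
      attr(rec, "eta") <- eta
      records[[length(records) + 1L]] <- rec
    }
  }
  pk_dataset(records)
}
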