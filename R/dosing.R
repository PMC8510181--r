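#' Schwartz estimate of creatinine clearance
#'
#' `CLCr = k * height / sCr`, normalised to 1.73 m2 body surface area. When
#' `k` is not given it is chosen by age/sex band: 0.45 below 12 months, 0.70
#' for adolescent (>= 13 y) males, 0.55 otherwise.
#'
#' @param height cm.
#' @param sCr mg/dl.
#' @param k proportionality constant; `NULL` selects by age/sex.
#' @param age_months,sex needed when `k` is `NULL` (sex: 1 = male).
#' @return CLCr in ml/min/1.73 m2 (vectorised).
#' @examples
#' schwartz_clcr(100, 0.55, k = 0.55)
#' @export
schwartz_clcr <- function(height, sCr, k = NULL, age_months = NULL, sex = NULL) {
  if (any(height <= 0) || any(sCr <= 0))
    stop("height and sCr must be positive")
  if (is.null(k)) {
    if (is.null(age_months) || is.null(sex))
      stop("age_months and sex are required when k is not given")
    k <- ifelse(age_months < 12, 0.45,
                ifelse(age_months >= 156 & sex == 1, 0.70, 0.55))
  }
  k * height / sCr
}

#' Pharmacodynamic target definition
#'
#' @param kind `"trough"` (steady-state trough above `threshold` ug/ml) or
#'   `"auc_mic"` (steady-state AUC24/MIC at least `threshold`).
#' @param threshold ug/ml for trough (default 10) or ratio (default 400).
#' @param mic assumed MIC, ug/ml (auc_mic targets).
#' @param strict use strict `>` instead of `>=` for attainment.
#' @return An object of class `pd_target` with a display `label`.
#' @export
pd_target <- function(kind = c("trough", "auc_mic"), threshold = NULL,
                      mic = 1, strict = FALSE) {
  kind <- match.arg(kind)
  if (is.null(threshold)) threshold <- if (kind == "trough") 10 else 400
  stopifnot(threshold > 0, mic > 0)
  label <- if (kind == "trough")
    sprintf("Trough >%s %g ug/ml", if (strict) "" else "=", threshold)
  else sprintf("AUC24/MIC >%s %g (MIC = %g)", if (strict) "" else "=",
               threshold, mic)
  structure(list(kind = kind, threshold = threshold, mic = mic,
                 strict = strict, label = label), class = "pd_target")
}

# CLCr strata used in the supplementary dosing tables
clcr_bins <- function(clcr) {
  cut(clcr, c(21, 40, 60, 90, Inf),
      labels = c("21-40", "41-60", "60-90", ">90"), include.lowest = TRUE)
}

#' Monte Carlo probability-of-target-attainment simulation
#'
#' Simulates `n_profiles` virtual patients: covariates are resampled with
#' replacement from `cohort` (or drawn from a
#' [covariate_distribution_spec()]), random effects are drawn from the
#' between-subject distribution, and for every regimen the steady-state
#' trough (closed form) and AUC24 (= daily dose / CL) are evaluated against
#' each pharmacodynamic target. Attainment fractions are reported overall
#' and stratified by days from transplantation (< 14 vs >= 14 days) and by
#' Schwartz creatinine-clearance band.
#'
#' @param p [population_params()] (typically from a final-model fit).
#' @param cohort covariate source: a data.frame (as from
#'   [sample_covariates()] or [covariate_table()]) or a
#'   `cov_dist_spec` to draw from.
#' @param regimens list of [regimen_spec()] objects.
#' @param targets list of [pd_target()] objects.
#' @param n_profiles number of simulated profiles.
#' @param seed integer seed.
#' @return An object of class `attainment_table`: data.frame with columns
#'   `regimen`, `target`, `stratum_type` (`total`, `DFLT`, `CLCr`),
#'   `stratum`, `n`, `fraction` (NA for empty strata).
#' @examples
#' tab <- simulate_attainment(population_params(),
#'                            covariate_distribution_spec(),
#'                            list(regimen_spec(15, 6)),
#'                            list(pd_target("trough")),
#'                            n_profiles = 200, seed = 1)
#' attainment_report(tab)
#' @export
simulate_attainment <- function(p, cohort = covariate_distribution_spec(),
                                regimens, targets, n_profiles = 1000,
                                seed = 1) {
  set.seed(seed)
  if (inherits(cohort, "cov_dist_spec")) {
    cov <- sample_covariates(n_profiles, cohort)
  } else {
    cov <- as.data.frame(cohort)
    cov <- cov[sample.int(nrow(cov), n_profiles, replace = TRUE), ,
               drop = FALSE]
  }
  eta_cl <- rnorm(n_profiles, 0, p$omega_CL)
  eta_v <- rnorm(n_profiles, 0, p$omega_V)
  CL <- typical_clearance(cov, p) * exp(eta_cl)
  V <- typical_volume(cov, p) * exp(eta_v)
  strata <- list(
    total = factor(rep("all", n_profiles)),
    DFLT = factor(ifelse(cov$DFLT < 14, "<14 days", ">=14 days"),
                  levels = c("<14 days", ">=14 days")))
  if (!is.null(cov$height)) {
    clcr <- schwartz_clcr(cov$height, cov$sCr,
                          age_months = cov$age, sex = cov$sex)
    strata$CLCr <- clcr_bins(clcr)
  }
  rows <- list()
  for (reg in regimens) {
    amt <- reg$dose_mg_kg * cov$weight
    R <- amt / reg$infusion_duration
    ke <- CL / V
    trough <- (R / CL) * (1 - exp(-ke * reg$infusion_duration)) *
      exp(-ke * (reg$interval - reg$infusion_duration)) /
      (1 - exp(-ke * reg$interval))
    auc24 <- amt * (24 / reg$interval) / CL
    for (tg in targets) {
      met <- if (tg$kind == "trough") {
        if (tg$strict) trough > tg$threshold else trough >= tg$threshold
      } else {
        ratio <- auc24 / tg$mic
        if (tg$strict) ratio > tg$threshold else ratio >= tg$threshold
      }
      for (st in names(strata)) {
        for (lv in levels(strata[[st]])) {
          sel <- strata[[st]] == lv & !is.na(strata[[st]])
          rows[[length(rows) + 1]] <- data.frame(
            regimen = reg$label, target = tg$label, stratum_type = st,
            stratum = lv, n = sum(sel),
            fraction = if (sum(sel)) mean(met[sel]) else NA_real_)
        }
      }
    }
  }
  structure(do.call(rbind, rows), class = c("attainment_table", "data.frame"))
}

#' Format an attainment table as percentage grids
#'
#' Renders the regimen-by-target attainment fractions as percentage strings
#' (one decimal), one grid per stratification (overall + days from
#' transplantation, and creatinine-clearance bands when available). Empty
#' strata render as `"NA"`.
#'
#' @param table an `attainment_table` from [simulate_attainment()].
#' @return Invisibly, a named list of character matrices; printed as
#'   formatted grids.
#' @export
attainment_report <- function(table) {
  stopifnot(inherits(table, "attainment_table"))
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.1f%%", 100 * x))
  grids <- list()
  for (st in unique(table$stratum_type)) {
    sub <- table[table$stratum_type == st, ]
    rowskey <- unique(sub[, c("regimen", "target")])
    cols <- unique(sub$stratum)
    m <- matrix("NA", nrow(rowskey), length(cols),
                dimnames = list(paste(rowskey$regimen, "|", rowskey$target),
                                cols))
    for (i in seq_len(nrow(sub))) {
      rk <- paste(sub$regimen[i], "|", sub$target[i])
      m[rk, sub$stratum[i]] <- fmt(sub$fraction[i])
    }
    grids[[st]] <- m
  }
  for (st in names(grids)) {
    cat("\nAttainment by", st, "\n")
    print(grids[[st]], quote = FALSE)
  }
  invisible(grids)
}
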