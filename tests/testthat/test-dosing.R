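test_that("Schwartz creatinine clearance formula", {
  expect_equal(schwartz_clcr(100, 0.55, k = 0.55), 100)
  expect_equal(schwartz_clcr(69.7, 0.16, k = 0.45), 0.45 * 69.7 / 0.16,
               tolerance = 1e-12)
  expect_equal(schwartz_clcr(69.7, 0.16, k = 0.45), 196.03, tolerance = 1e-3)
  expect_equal(schwartz_clcr(100, 0.8, k = 0.55),
               schwartz_clcr(100, 0.4, k = 0.55) / 2)
  # k selected by age/sex band
  expect_equal(schwartz_clcr(60, 0.2, age_months = 6, sex = 0),
               0.45 * 60 / 0.2)
  expect_equal(schwartz_clcr(170, 0.8, age_months = 170, sex = 1),
               0.70 * 170 / 0.8)
  expect_equal(schwartz_clcr(160, 0.8, age_months = 170, sex = 0),
               0.55 * 160 / 0.8)
  expect_error(schwartz_clcr(-1, 0.5, k = 0.55), "positive")
})

regs <- list(regimen_spec(15, 8), regimen_spec(15, 6), regimen_spec(20, 6))
tgts <- list(pd_target("trough", 10),
             pd_target("auc_mic", 400, mic = 0.5),
             pd_target("auc_mic", 400, mic = 1),
             pd_target("auc_mic", 400, mic = 2))

test_that("attainment obeys MIC, daily-dose and DFLT orderings", {
  tab <- simulate_attainment(population_params(),
                             covariate_distribution_spec(),
                             regs, tgts, n_profiles = 2000, seed = 3)
  tot <- tab[tab$stratum_type == "total", ]
  get <- function(reg, tgt) tot$fraction[tot$regimen == reg &
                                           tot$target == tgt$label]
  for (reg in vapply(regs, `[[`, character(1), "label")) {
    # attainment non-increasing in MIC
    expect_gte(get(reg, tgts[[2]]), get(reg, tgts[[3]]))
    expect_gte(get(reg, tgts[[3]]), get(reg, tgts[[4]]))
  }
  for (tg in tgts) {
    # daily dose 45 -> 60 -> 80 mg/kg/day: attainment non-decreasing
    expect_lte(get("15 mg/kg q8h", tg), get("15 mg/kg q6h", tg) + 1e-12)
    expect_lte(get("15 mg/kg q6h", tg), get("20 mg/kg q6h", tg) + 1e-12)
  }
  # early post-transplant (DFLT < 14, higher clearance) attains less
  dflt <- tab[tab$stratum_type == "DFLT", ]
  for (reg in vapply(regs, `[[`, character(1), "label")) {
    for (tg in tgts[c(1, 3)]) {
      lo <- dflt$fraction[dflt$regimen == reg & dflt$target == tg$label &
                            dflt$stratum == "<14 days"]
      hi <- dflt$fraction[dflt$regimen == reg & dflt$target == tg$label &
                            dflt$stratum == ">=14 days"]
      expect_lte(lo, hi + 0.02)
    }
  }
  # fractions valid and stratum sizes add up
  expect_true(all(tab$fraction >= 0 & tab$fraction <= 1, na.rm = TRUE))
  expect_equal(sum(dflt$n[dflt$regimen == regs[[1]]$label &
                            dflt$target == tgts[[1]]$label]), 2000)
})

test_that("a degenerate population attains exactly 0 or 1 at the AUC boundary", {
  p0 <- population_params(omega_CL = 0, omega_V = 0)
  one <- data.frame(weight = 10, sCr = 0.16, DFLT = 17)
  cl <- typical_clearance(one, p0)
  # pick the dose so AUC24 = daily_dose / CL sits just each side of 400
  reg_above <- regimen_spec(cl * 401 / (4 * 10), 6)
  reg_below <- regimen_spec(cl * 399 / (4 * 10), 6)
  tab <- simulate_attainment(p0, one, list(reg_above, reg_below),
                             list(pd_target("auc_mic", 400, mic = 1)),
                             n_profiles = 50, seed = 1)
  tot <- tab[tab$stratum_type == "total", ]
  expect_equal(tot$fraction[tot$regimen == reg_above$label], 1)
  expect_equal(tot$fraction[tot$regimen == reg_below$label], 0)
})

test_that("repeated runs vary within binomial sampling error", {
  f1 <- simulate_attainment(population_params(),
                            covariate_distribution_spec(),
                            regs[2], tgts[3], n_profiles = 1000, seed = 5)
  f2 <- simulate_attainment(population_params(),
                            covariate_distribution_spec(),
                            regs[2], tgts[3], n_profiles = 1000, seed = 6)
  p1 <- f1$fraction[f1$stratum_type == "total"]
  p2 <- f2$fraction[f2$stratum_type == "total"]
  se <- sqrt(p1 * (1 - p1) / 1000 + p2 * (1 - p2) / 1000)
  expect_lt(abs(p1 - p2), 4 * se)
})

test_that("attainment report renders one-decimal percentages and NA cells", {
  tab <- structure(data.frame(
    regimen = "15 mg/kg q6h",
    target = c("Trough >= 10 ug/ml", "Trough >= 10 ug/ml"),
    stratum_type = "DFLT", stratum = c("<14 days", ">=14 days"),
    n = c(100, 0), fraction = c(0.121, NA)),
    class = c("attainment_table", "data.frame"))
  out <- attainment_report(tab)
  expect_equal(unname(out$DFLT[1, "<14 days"]), "12.1%")
  expect_equal(unname(out$DFLT[1, ">=14 days"]), "NA")
  expect_true(grepl("15 mg/kg q6h", rownames(out$DFLT)[1]))
  fr <- c(0.121, 0.821)
  expect_equal(sprintf("%.1f%%", 100 * fr), c("12.1%", "82.1%"))
})
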