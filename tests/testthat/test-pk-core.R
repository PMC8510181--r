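p_final <- population_params()

test_that("typical clearance follows the covariate power model", {
  # reference covariates: both ratios are 1 and wt^0.75 = 1
  expect_equal(typical_clearance(list(weight = 1, sCr = 0.16, DFLT = 17),
                                 p_final), 0.29)
  # median-weight subject: 0.29 * 9.1^0.75
  expect_equal(typical_clearance(list(weight = 9.1, sCr = 0.16, DFLT = 17),
                                 p_final),
               0.29 * 9.1^0.75, tolerance = 1e-12)
  # doubling sCr multiplies clearance by 2^exp_sCr
  cl1 <- typical_clearance(list(weight = 9.1, sCr = 0.16, DFLT = 17), p_final)
  cl2 <- typical_clearance(list(weight = 9.1, sCr = 0.32, DFLT = 17), p_final)
  expect_equal(cl2, cl1 * 2^-0.70, tolerance = 1e-12)
  expect_equal(cl1, 1.5195, tolerance = 1e-4)
  expect_equal(cl2, 0.9354, tolerance = 1e-3)
  # strictly decreasing in sCr and DFLT at the fitted (negative) exponents
  scr <- seq(0.1, 2, length.out = 20)
  cls <- typical_clearance(data.frame(weight = 9.1, sCr = scr, DFLT = 17),
                           p_final)
  expect_true(all(diff(cls) < 0))
  dflt <- seq(1, 300, length.out = 20)
  cld <- typical_clearance(data.frame(weight = 9.1, sCr = 0.16, DFLT = dflt),
                           p_final)
  expect_true(all(diff(cld) < 0))
  # day-0 DFLT is floored, not an error
  expect_equal(typical_clearance(list(weight = 9.1, sCr = 0.16, DFLT = 0),
                                 p_final),
               typical_clearance(list(weight = 9.1, sCr = 0.16, DFLT = 1),
                                 p_final))
  expect_error(typical_clearance(list(weight = -1, sCr = 0.16, DFLT = 17),
                                 p_final), "weight")
  expect_error(typical_clearance(list(weight = 9.1, sCr = 0, DFLT = 17),
                                 p_final), "sCr")
})

test_that("typical volume is linear in weight", {
  for (w in c(1, 9.1, 61.0))
    expect_equal(typical_volume(list(weight = w, sCr = 0.16, DFLT = 17),
                                p_final), 1.00 * w)
})

test_that("individual parameters apply exponential random effects", {
  cov <- list(weight = 9.1, sCr = 0.16, DFLT = 17)
  tv <- individual_params(cov, p_final, 0, 0)
  expect_equal(tv$CL, typical_clearance(cov, p_final))
  expect_equal(tv$V, typical_volume(cov, p_final))
  up <- individual_params(cov, p_final, log(2), 0)
  expect_equal(up$CL, 2 * tv$CL)
  expect_equal(up$V, tv$V)
  # eta_CL = -ln 2 and eta_V = +ln 2 quarter the elimination rate
  q <- individual_params(cov, p_final, -log(2), log(2))
  expect_equal(q$k_e, tv$k_e / 4, tolerance = 1e-12)
})

test_that("closed-form concentration matches the worked example and limits", {
  ip <- list(CL = 1.52, V = 9.19)
  doses <- dose_event(0, 136.5, 1)
  expect_equal(concentration(0, doses, ip), 0)
  expect_equal(concentration(1, doses, ip),
               (136.5 / 1.52) * (1 - exp(-(1.52 / 9.19) * 1)),
               tolerance = 1e-12)
  # long constant-rate infusion approaches R/CL
  long <- dose_event(0, 500 * 2000, 2000)
  expect_equal(concentration(1500, long, ip), 500 / 1.52, tolerance = 1e-4)
})

test_that("superposition: multi-dose profile is the sum of single doses", {
  ip <- list(CL = 2.3, V = 11)
  d1 <- dose_event(0, 200, 1)
  d2 <- dose_event(6, 150, 0.5)
  both <- dose_event(c(0, 6), c(200, 150), c(1, 0.5))
  t <- seq(0, 30, by = 0.25)
  expect_equal(concentration(t, both, ip),
               concentration(t, d1, ip) + concentration(t, d2, ip),
               tolerance = 1e-9)
})

test_that("closed form agrees with numerical ODE integration", {
  skip_if_not_installed("deSolve")
  set.seed(42)
  for (rep in 1:100) {
    CL <- runif(1, 0.2, 8)
    V <- runif(1, 1, 40)
    amt <- runif(1, 50, 500)
    dur <- runif(1, 0.5, 2)
    tq <- runif(1, 0.1, 30)
    doses <- dose_event(c(0, 6, 12), amt, dur)
    # integrate segment-by-segment so the piecewise-constant infusion input
    # is exact at the breakpoints
    brk <- sort(unique(c(0, doses$time, doses$time + doses$duration, tq)))
    brk <- brk[brk <= tq]
    if (max(brk) < tq) brk <- c(brk, tq)
    A <- 0
    for (k in seq_len(length(brk) - 1)) {
      if (brk[k + 1] - brk[k] < 1e-12) next
      tm <- (brk[k] + brk[k + 1]) / 2
      inp <- sum(doses$rate[tm >= doses$time &
                              tm < doses$time + doses$duration])
      rhs <- function(t, A, parms) list(inp - (CL / V) * A)
      seg <- deSolve::lsoda(c(A = A), c(brk[k], brk[k + 1]), rhs, NULL,
                            rtol = 1e-11, atol = 1e-12)
      A <- unname(seg[nrow(seg), "A"])
    }
    cf <- concentration(tq, doses, list(CL = CL, V = V))
    expect_equal(cf, unname(A / V), tolerance = 1e-6)
  }
})

test_that("steady-state trough matches the superposition engine at dose 30", {
  cov <- list(weight = 9.1, sCr = 0.16, DFLT = 17)
  ip <- individual_params(cov, p_final, 0.2, -0.1)
  reg <- regimen_spec(15, 6)
  doses <- build_regimen_doses(cov, reg, 31)
  trough_ss <- steady_state_trough(reg, cov, ip)
  # concentration immediately before the 31st dose (t = 30 * tau)
  amt <- round(15 * 9.1, 1)
  trough_num <- concentration(30 * 6 - 1e-9,
                              dose_event(seq(0, by = 6, length.out = 30),
                                         amt, 1), ip)
  expect_equal(trough_ss, trough_num, tolerance = 2e-3)
  # linear PK: doubling the dose doubles the trough
  reg2 <- regimen_spec(30, 6)
  expect_equal(steady_state_trough(reg2, cov, ip), 2 * trough_ss)
  # fast elimination drives the trough to 0
  fast <- list(CL = 500, V = 5)
  expect_lt(steady_state_trough(reg, cov, fast), 1e-10)
  expect_error(steady_state_trough(regimen_spec(15, 6, 0.9), cov, ip), NA)
  expect_error(regimen_spec(15, 1, 2), "interval")
})

test_that("AUC24 identity: daily dose / CL matches numerical integration", {
  expect_equal(auc24_at_steady_state(546, 1.52), 546 / 1.52)
  expect_equal(auc24_at_steady_state(2 * 546, 1.52),
               2 * auc24_at_steady_state(546, 1.52))
  # boundary: CL = daily_dose / 400 gives AUC24 = 400 exactly
  expect_equal(auc24_at_steady_state(546, 546 / 400), 400)
  expect_error(auc24_at_steady_state(-5, 1), "positive")
  # trapezoidal integration over a steady-state day
  ip <- list(CL = 1.52, V = 9.19)
  amt <- 136.5
  doses <- dose_event(seq(0, by = 6, length.out = 44), amt, 1)
  t <- seq(240, 264, by = 0.005)  # day 11, effectively at steady state
  conc <- concentration(t, doses, ip)
  auc_num <- sum(diff(t) * (head(conc, -1) + tail(conc, -1)) / 2)
  expect_equal(auc24_at_steady_state(amt * 4, ip$CL), auc_num,
               tolerance = 0.01)
})

test_that("dose events validate their invariants", {
  d <- dose_event(c(6, 0), c(100, 100), 2)
  expect_equal(d$time, c(0, 6))           # sorted
  expect_equal(d$rate, d$amount / d$duration)
  expect_error(dose_event(0, -5, 1), "amount")
  expect_error(dose_event(0, 100, 0), "duration")
})
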