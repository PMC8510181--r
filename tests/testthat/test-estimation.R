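truth <- population_params()

test_that("with no random effects the OFV is the plain Gaussian -2LL", {
  d <- pk_dataset(list(
    make_record("a", 9.1, times = c(3, 11, 23), conc = c(8, 12, 6)),
    make_record("b", 15, times = c(5, 17.9), conc = c(10, 9))))
  p0 <- population_params(omega_CL = 0, omega_V = 0, sigma_prop = 0.3,
                          sigma_add = 0.5)
  val <- ofv(d, final_model_spec("combined"), p0)
  # direct evaluation of sum[(y-f)^2/v + log(2 pi v)]
  direct <- 0
  for (s in d) {
    f <- r_conc(s$observations$time, s$doses,
                typical_clearance(s$covariates, p0),
                typical_volume(s$covariates, p0))
    v <- 0.5^2 + 0.3^2 * f^2
    direct <- direct + sum((s$observations$conc - f)^2 / v + log(2 * pi * v))
  }
  expect_equal(val, direct, tolerance = 1e-8)
})

test_that("OFV is additive over independent episodes", {
  d1 <- pk_dataset(list(
    make_record("a", 9.1, times = c(3, 11, 23), conc = c(8, 12, 6))))
  d2 <- pk_dataset(list(d1[[1]], make_record("a2", 9.1,
                                             times = c(3, 11, 23),
                                             conc = c(8, 12, 6))))
  spec <- final_model_spec()
  expect_equal(2 * ofv(d1, spec, truth), ofv(d2, spec, truth),
               tolerance = 1e-10)
})

test_that("Laplace OFV matches 64-node adaptive quadrature on a tiny toy", {
  # two episodes, one observation each, a single active random effect
  d <- pk_dataset(list(
    make_record("a", 9.1, times = 23.9, conc = 7.2),
    make_record("b", 6.5, times = 17.9, conc = 14.1)))
  p1 <- population_params(omega_CL = 0.4, omega_V = 0, sigma_prop = 0.3)
  lap <- ofv(d, final_model_spec(), p1, nodes = 1)
  orc <- r_oracle_ofv(d, p1)
  expect_equal(lap, orc, tolerance = 0.1)
  # the quadrature-refined default is at least as close
  agq <- ofv(d, final_model_spec(), p1)
  expect_lte(abs(agq - orc), abs(lap - orc) + 1e-6)
})

test_that("noise-free data identify the fixed effects to within 1%", {
  p0 <- population_params(omega_CL = 0, omega_V = 0, sigma_prop = 0.01,
                          sigma_add = 0)
  d <- simulate_dataset(25, p = p0, seed = 17)
  f <- fit_nlme(d, final_model_spec(), control = list(se = FALSE))
  expect_equal(f$estimates[["theta_CL"]], 0.29, tolerance = 0.01)
  expect_equal(f$estimates[["theta_V"]], 1.00, tolerance = 0.01)
  expect_equal(f$estimates[["beta_sCr_CL"]], -0.70, tolerance = 0.02)
  expect_equal(f$estimates[["beta_DFLT_CL"]], -0.09, tolerance = 0.02)
})

test_that("estimates are invariant to episode ordering", {
  d <- simulate_dataset(20, seed = 23)
  f1 <- fit_nlme(d, final_model_spec(), control = list(se = FALSE))
  f2 <- fit_nlme(d[rev(seq_along(d))], final_model_spec(),
                 control = list(se = FALSE))
  expect_equal(unname(f1$estimates), unname(f2$estimates), tolerance = 1e-3)
  expect_equal(f1$ofv, f2$ofv, tolerance = 1e-6)
})

test_that("post hoc estimates behave like conditional modes", {
  cov <- list(weight = 9.1, sCr = 0.16, DFLT = 17, height = 70, age = 13,
              sex = 1, albumin = 3.1, ALT = 50, UD = 0)
  spec <- final_model_spec()
  # no observations: prior mode (0, 0)
  empty <- pk_subject("e", cov, dose_event(0, 136.5, 1))
  expect_equal(unname(posthoc_ebe(empty, spec, truth)[1, ]), c(0, 0))
  # rich, nearly noise-free data recover the simulated eta
  eta_true <- c(0.35, -0.22)
  ip <- individual_params(cov, truth, eta_true[1], eta_true[2])
  doses <- dose_event(seq(0, by = 6, length.out = 5), 136.5, 1)
  tt <- seq(0.5, 28, by = 1.5)
  rich <- pk_subject("r", cov, doses,
                     data.frame(time = tt,
                                conc = concentration(tt, doses, ip)))
  p_tight <- population_params(sigma_prop = 1e-4)
  eb <- posthoc_ebe(rich, spec, p_tight)
  expect_equal(unname(eb[1, ]), eta_true, tolerance = 1e-3)
  # omega -> 0 pins the EBEs at 0
  p_om0 <- population_params(omega_CL = 0, omega_V = 0)
  expect_equal(unname(posthoc_ebe(rich, spec, p_om0)[1, ]), c(0, 0))
})

test_that("shrinkage rises as the design gets sparser", {
  p0 <- population_params(sigma_prop = 0.15)
  dense <- simulate_dataset(60, p = p0,
                            design = sampling_design_spec(extra_obs_rate = 7,
                                                          episodes_extra_rate = 0),
                            seed = 41)
  sparse <- simulate_dataset(60, p = p0,
                             design = sampling_design_spec(extra_obs_rate = 0,
                                                           episodes_extra_rate = 0),
                             seed = 41)
  fd <- fit_nlme(dense, final_model_spec(), control = list(se = FALSE))
  fs <- fit_nlme(sparse, final_model_spec(), control = list(se = FALSE))
  expect_lt(fd$shrinkage[["eta_shrinkage_CL"]], 0.25)
  expect_gt(fs$shrinkage[["eta_shrinkage_CL"]],
            fd$shrinkage[["eta_shrinkage_CL"]])
  # noise-free data give IWRES ~ 0 at any fixed residual SD, hence
  # epsilon-shrinkage ~ 1
  p_nf <- population_params(omega_CL = 0, omega_V = 0, sigma_prop = 1e-12)
  dn <- simulate_dataset(10, p = p_nf, seed = 2)
  fn <- fit_nlme(dn, final_model_spec(),
                 init = population_params(sigma_prop = 0.05),
                 control = list(se = FALSE))
  fn$estimates[["sigma_prop"]] <- 0.2   # judge residuals on a fixed scale
  expect_gt(shrinkage(fn)[["eps_shrinkage"]], 0.99)
})

test_that("a strong simulated sCr effect is found and kept by the search", {
  p_scr <- population_params(exp_DFLT = 0, sigma_prop = 0.25,
                             omega_CL = 0.3, omega_V = 0.3)
  d <- simulate_dataset(40, p = p_scr, seed = 19)
  cand <- data.frame(covariate = c("sCr", "albumin"), param = "CL",
                     type = "power", ref = c(0.16, 3.1), floor = NA_real_)
  sw <- stepwise_covariate_search(d, base_model_spec("proportional"), cand)
  sel <- sw$final_spec$covariates
  expect_true("sCr" %in% sel$covariate[sel$param == "CL"])
  # dropping sCr from the final model raises the OFV far beyond 7.88
  back <- sw$steps[[length(sw$steps)]]
  expect_identical(back$phase, "backward")
  rise <- back$table$delta_ofv[back$table$removed == "sCr on CL"]
  expect_gt(rise, 7.88)
  # screening table has the Table-2 shape
  expect_named(sw$screening,
               c("covariate", "parameter", "delta_ofv", "converged"))
  # forward threshold defaults to the chi-square(1) 5% cut
  expect_equal(formals(stepwise_covariate_search)$forward_dofv, 3.84)
  expect_equal(formals(stepwise_covariate_search)$backward_dofv, 7.88)
})

test_that("coefficient table reports estimates with finite RSEs", {
  d <- simulate_dataset(25, seed = 29)
  f <- fit_nlme(d, final_model_spec())
  expect_true(f$converged)
  expect_true(all(is.finite(f$coef_table$se)))
  expect_true(all(f$coef_table$rse_pct >= 0))
  expect_true(all(f$shrinkage >= -0.05 & f$shrinkage <= 1))
  pp <- as_pop_params(f)
  expect_s3_class(pp, "pop_params")
  expect_equal(pp$theta_CL, f$estimates[["theta_CL"]])
})
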