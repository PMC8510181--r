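test_that("covariate sampling matches the target distributions and bounds", {
  spec <- covariate_distribution_spec()
  cov <- sample_covariates(1000, spec, seed = 31)
  expect_gt(median(cov$weight), 8.2)   # target median 9.1 kg
  expect_lt(median(cov$weight), 10.0)
  expect_true(all(cov$weight >= 3.1 & cov$weight <= 61.0))
  expect_true(all(cov$sCr >= 0.06 & cov$sCr <= 5.43))
  expect_true(all(cov$DFLT >= 0 & cov$DFLT <= 358))
  expect_true(all(cov$albumin >= 1.5 & cov$albumin <= 4.8))
  expect_true(all(cov$height >= 48 & cov$height <= 175.5))
  expect_true(all(cov$age >= 1 & cov$age <= 186))
  expect_true(all(cov$sex %in% 0:1) && all(cov$UD %in% 0:1))
  # joint plausibility of the derived covariates
  expect_gt(cor(log(cov$weight), log(cov$height)), 0.9)
  expect_gt(cor(log(cov$weight), log(cov$age)), 0.8)
  # same seed reproduces exactly
  expect_identical(cov, sample_covariates(1000, spec, seed = 31))
})

test_that("an infeasible covariate spec is rejected", {
  expect_error(covariate_distribution_spec(
    sCr = list(median = 10, q1 = 0.12, q3 = 0.23, lo = 0.06, hi = 5.43)),
    "infeasible")
})

test_that("regimen dose building lays out equal doses on the interval grid", {
  cov <- list(weight = 10, sCr = 0.16, DFLT = 17)
  d <- build_regimen_doses(cov, regimen_spec(15, 6), 4)
  expect_equal(d$time, c(0, 6, 12, 18))
  expect_equal(d$amount, rep(150, 4))
  d8 <- build_regimen_doses(cov, regimen_spec(15, 8), 3)
  expect_equal(d8$time, c(0, 8, 16))
  d20 <- build_regimen_doses(list(weight = 9.1, sCr = 0.16, DFLT = 17),
                             regimen_spec(20, 6), 1)
  expect_equal(d20$amount, 182)
})

test_that("noise-free simulation reproduces the structural model exactly", {
  p0 <- population_params(omega_CL = 0, omega_V = 0, sigma_prop = 1e-12,
                          sigma_add = 0)
  d <- simulate_dataset(8, p = p0, seed = 5)
  for (s in d) {
    ip <- individual_params(s$covariates, p0, 0, 0)
    expect_equal(s$observations$conc,
                 concentration(s$observations$time, s$doses, ip),
                 tolerance = 1e-8)
  }
})

test_that("the default design reproduces the study's sampling density", {
  d <- simulate_dataset(161, seed = 7)
  nobs <- sum(vapply(d, function(s) nrow(s$observations), integer(1)))
  expect_gt(nobs, 1158 * 0.8)
  expect_lt(nobs, 1158 * 1.2)
  # episodes roughly as 270 from 161 patients
  expect_gt(length(d), 230)
  expect_lt(length(d), 320)
  # concentrations have positive support and a plausible median
  conc <- unlist(lapply(d, function(s) s$observations$conc))
  expect_true(all(conc > 0))
  expect_gt(median(conc), 0.3)
  expect_lt(median(conc), 61.6)
  # trough sample sits just before the 4th or 5th dose
  s <- d[[1]]
  tau <- diff(s$doses$time)[1]
  expect_true(any(abs(s$observations$time - (c(3, 4) * tau - 0.05)) < 1e-6))
  # determinism
  d2 <- simulate_dataset(161, seed = 7)
  expect_identical(covariate_table(d), covariate_table(d2))
  expect_identical(d[[5]]$observations, d2[[5]]$observations)
})

test_that("residual error magnitude propagates into log-residual spread", {
  # with omega = 0 and moderate proportional error, SD(log(obs/pred)) is
  # approximately sigma_prop (delta method)
  p0 <- population_params(omega_CL = 0, omega_V = 0, sigma_prop = 0.2,
                          sigma_add = 0)
  d <- simulate_dataset(400, p = p0, seed = 13)
  lr <- unlist(lapply(d, function(s) {
    ip <- individual_params(s$covariates, p0, 0, 0)
    keep <- !s$observations$bql
    log(s$observations$conc[keep] /
          concentration(s$observations$time[keep], s$doses, ip))
  }))
  expect_equal(sd(lr), 0.2, tolerance = 0.1)
})

test_that("below-quantification simulated values are floored and flagged", {
  d <- simulate_dataset(120, seed = 3)   # sigma_prop 0.565 generates some
  obs <- do.call(rbind, lapply(d, function(s) s$observations))
  expect_true(any(obs$bql))
  expect_true(all(obs$conc[obs$bql] == 0.1))
  expect_true(all(obs$conc >= 0.1 | !obs$bql))
})
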