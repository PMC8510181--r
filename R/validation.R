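# time after the most recent dose start, per observation
time_after_dose <- function(times, dose_times) {
  vapply(times, function(t) {
    prior <- dose_times[dose_times <= t]
    if (!length(prior)) t else t - max(prior)
  }, numeric(1))
}

#' Nonparametric bootstrap of a fitted population model
#'
#' Episodes (the independent sampling units) are resampled with replacement
#' `n_boot` times; the model is refitted to each resample, warm-started at
#' the original estimates, and parameter medians with percentile 95%
#' confidence intervals are summarised over the converged refits.
#'
#' @param data a [pk_dataset()] (the original fitting data).
#' @param spec the fitted [model_spec()].
#' @param fit the original [fit_nlme()] result (used as warm start).
#' @param n_boot number of bootstrap resamples.
#' @param seed integer seed; resample indices are deterministic given it.
#' @param control passed to the refits.
#' @return An object of class `bootstrap_result`: `summary` (parameter,
#'   median, lower, upper), `estimates` matrix, `convergence_rate`,
#'   `low_convergence` flag (TRUE when more than half the refits failed).
#' @export
bootstrap_model <- function(data, spec, fit, n_boot = 1000, seed = 1,
                            control = list()) {
  stopifnot(inherits(fit, "pop_fit"))
  set.seed(seed)
  n <- length(data)
  info <- fit$info
  est <- matrix(NA_real_, n_boot, length(info$names),
                dimnames = list(NULL, info$names))
  conv <- logical(n_boot)
  ctl <- control
  ctl$se <- FALSE
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    fb <- try(fit_nlme(data[idx], spec, init = fit$estimates, control = ctl),
              silent = TRUE)
    if (!inherits(fb, "try-error")) {
      conv[b] <- fb$converged
      if (fb$converged) est[b, ] <- fb$estimates
    }
  }
  keep <- est[conv, , drop = FALSE]
  qs <- apply(keep, 2, quantile, probs = c(0.025, 0.5, 0.975), names = FALSE)
  structure(list(
    summary = data.frame(parameter = info$names,
                         original = unname(fit$estimates),
                         median = qs[2, ], lower = qs[1, ], upper = qs[3, ]),
    estimates = est, converged = conv,
    n_requested = n_boot, n_converged = sum(conv),
    convergence_rate = mean(conv),
    low_convergence = mean(conv) < 0.5), class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("Bootstrap: %d/%d refits converged (%.1f%%)\n",
              x$n_converged, x$n_requested, 100 * x$convergence_rate))
  if (x$low_convergence)
    cat("  WARNING: more than half of the refits failed to converge\n")
  s <- x$summary
  s[-1] <- lapply(s[-1], signif, 4)
  print(s, row.names = FALSE)
  invisible(x)
}

#' Visual predictive check
#'
#' Simulates `n_sim` replicate datasets at the original design (same
#' episodes, doses, sampling times and covariates) from the fitted model,
#' then compares observed 5th/50th/95th concentration percentiles per
#' time-after-dose bin with the distribution of the same percentiles across
#' the simulated replicates. Simulated observations are floored at the
#' 0.1 ug/ml quantification limit, mirroring the observation model.
#'
#' @param data a [pk_dataset()].
#' @param spec the fitted [model_spec()].
#' @param fit the [fit_nlme()] result.
#' @param n_sim number of simulated replicates.
#' @param bins number of quantile-spaced bins on time after most recent
#'   dose.
#' @param seed integer seed.
#' @return An object of class `vpc_result`: `bins` (per-bin observed and
#'   simulated percentiles), `fraction_in_pi` (share of observations inside
#'   the simulated 90% prediction interval of their bin).
#' @export
vpc <- function(data, spec, fit, n_sim = 1000, bins = 8, seed = 1) {
  set.seed(seed)
  nd <- fit$nlme
  e <- fit$estimates
  s <- residual_sigmas(fit)
  n <- nd$n
  tad <- numeric(nd$n_obs)
  for (i in seq_len(n)) {
    oi <- (nd$obs_ptr[i] + 1):nd$obs_ptr[i + 1]
    di <- (nd$dose_ptr[i] + 1):nd$dose_ptr[i + 1]
    tad[oi] <- time_after_dose(nd$obs_t[oi], nd$dose_t0[di])
  }
  br <- unique(quantile(tad, probs = seq(0, 1, length.out = bins + 1)))
  bin <- cut(tad, br, include.lowest = TRUE)
  nonempty <- table(bin) > 0
  if (any(!nonempty)) warning("dropping empty VPC bins")

  probs <- c(0.05, 0.5, 0.95)
  sim_q <- array(NA_real_, c(n_sim, nlevels(bin), 3))
  sim_pool_lo <- matrix(NA_real_, n_sim, nlevels(bin))
  y <- nd$obs_y
  expmod <- spec$residual == "exponential"
  for (r in seq_len(n_sim)) {
    etas <- cbind(rnorm(n, 0, e[["omega_CL"]]), rnorm(n, 0, e[["omega_V"]]))
    f <- indiv_pred(fit, etas)
    ysim <- if (expmod) f * exp(rnorm(length(f), 0, s[["sprop"]]))
    else f * (1 + rnorm(length(f), 0, s[["sprop"]])) +
      rnorm(length(f), 0, s[["sadd"]])
    ysim <- pmax(ysim, 0.1)
    for (bi in which(nonempty)) {
      sim_q[r, bi, ] <- quantile(ysim[bin == levels(bin)[bi]], probs,
                                 names = FALSE)
    }
  }
  tab <- data.frame()
  frac_num <- 0
  for (bi in which(nonempty)) {
    sel <- bin == levels(bin)[bi]
    oq <- quantile(y[sel], probs, names = FALSE)
    # simulated percentile bands: 5/50/95 of each percentile across replicates
    bands <- apply(sim_q[, bi, , drop = FALSE], 3, quantile,
                   probs = probs, names = FALSE)
    lo <- median(sim_q[, bi, 1])
    hi <- median(sim_q[, bi, 3])
    frac_num <- frac_num + sum(y[sel] >= lo & y[sel] <= hi)
    tab <- rbind(tab, data.frame(
      bin = levels(bin)[bi], n = sum(sel), tad_mid = median(tad[sel]),
      obs_p5 = oq[1], obs_p50 = oq[2], obs_p95 = oq[3],
      sim_p5 = lo, sim_p50 = median(sim_q[, bi, 2]), sim_p95 = hi,
      sim_p50_lo = bands[1, 2], sim_p50_hi = bands[3, 2]))
  }
  structure(list(bins = tab, fraction_in_pi = frac_num / length(y),
                 n_sim = n_sim), class = "vpc_result")
}

#' @export
print.vpc_result <- function(x, ...) {
  cat(sprintf("VPC (%d replicates): %.1f%% of observations inside the simulated 90%% PI\n",
              x$n_sim, 100 * x$fraction_in_pi))
  tb <- x$bins
  tb[-1] <- lapply(tb[-1], function(z) round(z, 2))
  print(tb, row.names = FALSE)
  invisible(x)
}

#' Goodness-of-fit residual diagnostics
#'
#' Per-observation population predictions (PRED, at eta = 0), individual
#' predictions (IPRED, at the empirical Bayes modes), individually weighted
#' residuals (IWRES) and conditional weighted residuals (CWRES) from the
#' standard FOCE first-order expansion about the conditional modes.
#'
#' @param data a [pk_dataset()] (must be the fitted data).
#' @param spec the fitted [model_spec()].
#' @param fit the [fit_nlme()] result.
#' @return data.frame with columns `id`, `time`, `tad`, `dv`, `pred`,
#'   `ipred`, `iwres`, `cwres`; attributes `cwres_mean` and `cwres_sd` hold
#'   the CWRES summary.
#' @export
gof_diagnostics <- function(data, spec, fit) {
  nd <- fit$nlme
  e <- fit$estimates
  s <- residual_sigmas(fit)
  om <- diag(c(e[["omega_CL"]], e[["omega_V"]])^2)
  zero <- matrix(0, nd$n, 2)
  pred <- indiv_pred(fit, zero)
  ipred <- indiv_pred(fit)
  iw <- iwres(fit, keep_censored = TRUE)
  iw[nd$obs_cens == 1] <- NA_real_
  clv <- indiv_clv(fit)
  expmod <- spec$residual == "exponential"
  cwres <- numeric(nd$n_obs)
  tad <- numeric(nd$n_obs)
  ids <- character(nd$n_obs)
  for (i in seq_len(nd$n)) {
    oi <- (nd$obs_ptr[i] + 1):nd$obs_ptr[i + 1]
    di <- (nd$dose_ptr[i] + 1):nd$dose_ptr[i + 1]
    tad[oi] <- time_after_dose(nd$obs_t[oi], nd$dose_t0[di])
    ids[oi] <- data[[i]]$id
    sen <- conc_sens_cpp(nd$obs_t[oi], nd$dose_t0[di], nd$dose_rate[di],
                         nd$dose_dur[di], clv$CL[i], clv$V[i])
    G <- cbind(sen$dlogCL, sen$dlogV)
    eta <- fit$etas[i, ]
    if (expmod) {
      G <- G / sen$f
      r <- log(nd$obs_y[oi]) - (log(sen$f) - drop(G %*% eta))
      v <- rep(s[["sprop"]]^2, length(oi))
    } else {
      r <- nd$obs_y[oi] - (sen$f - drop(G %*% eta))
      v <- s[["sadd"]]^2 + s[["sprop"]]^2 * sen$f^2
    }
    C <- diag(v, nrow = length(v)) + G %*% om %*% t(G)
    cwres[oi] <- drop(forwardsolve(t(chol(C)), r))
  }
  cwres[nd$obs_cens == 1] <- NA_real_   # censored values have no residual
  out <- data.frame(id = ids, time = nd$obs_t, tad = tad, dv = nd$obs_y,
                    cens = nd$obs_cens == 1, pred = pred, ipred = ipred,
                    iwres = iw, cwres = cwres)
  attr(out, "cwres_mean") <- mean(cwres, na.rm = TRUE)
  attr(out, "cwres_sd") <- sd(cwres, na.rm = TRUE)
  out
}
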