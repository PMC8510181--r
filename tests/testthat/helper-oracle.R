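# Independent oracles, implemented in plain R (no calls into the package's
# compiled code): closed-form concentration, joint log-density of one
# episode, and an adaptive Gauss-Hermite marginal likelihood.

# one-compartment zero-order-infusion concentration, plain R
r_conc <- function(t, doses, CL, V) {
  k <- CL / V
  sapply(t, function(tt) {
    f <- 0
    for (i in seq_len(nrow(doses))) {
      tau <- tt - doses$time[i]
      if (tau <= 0) next
      R <- doses$rate[i]
      D <- doses$duration[i]
      if (tau <= D) {
        f <- f + (R / CL) * (1 - exp(-k * tau))
      } else {
        f <- f + (R / CL) * (1 - exp(-k * D)) * exp(-k * (tau - D))
      }
    }
    f
  })
}

# joint log density log p(y | eta) + log p(eta) for one pk_subject record
r_joint_logdens <- function(eta, s, ltvcl, ltvv, omega, sadd, sprop,
                            residual = "proportional") {
  CL <- exp(ltvcl + eta[1])
  V <- exp(ltvv + eta[2])
  f <- r_conc(s$observations$time, s$doses, CL, V)
  y <- s$observations$conc
  ll <- if (residual == "exponential") {
    if (any(f <= 0)) return(-Inf)
    sum(dnorm(log(y), log(f), sprop, log = TRUE) - log(y))
  } else {
    v <- switch(residual,
                additive = rep(sadd^2, length(f)),
                proportional = sprop^2 * f^2,
                combined = sadd^2 + sprop^2 * f^2)
    if (any(v <= 1e-300)) return(-Inf)   # concentration underflow far from mode
    sum(-0.5 * log(2 * pi * v) - 0.5 * (y - f)^2 / v)
  }
  act <- omega > 0
  out <- ll + sum(dnorm(eta[act], 0, omega[act], log = TRUE))
  if (!is.finite(out)) return(-Inf)
  out
}

# adaptive Gauss-Hermite -2 log marginal likelihood for one record; the mode
# is located with stats::optim, the curvature by finite differences
r_aghq_m2ll <- function(s, ltvcl, ltvv, omega, sadd, sprop,
                        residual = "proportional", nodes = 64) {
  act <- which(omega > 0)
  d <- length(act)
  hf <- function(ea) {
    eta <- c(0, 0)
    eta[act] <- ea
    r_joint_logdens(eta, s, ltvcl, ltvv, omega, sadd, sprop, residual)
  }
  if (d == 0) return(-2 * hf(numeric(0)))
  op <- optim(rep(0, d),
              function(e) { v <- hf(e); if (is.finite(v)) -v else 1e10 },
              method = "BFGS",
              control = list(reltol = 1e-14, maxit = 500))
  mu <- op$par
  hs <- 1e-4
  H <- matrix(0, d, d)
  for (i in seq_len(d)) for (j in seq_len(d)) {
    ei <- ej <- rep(0, d)
    ei[i] <- hs; ej[j] <- hs
    H[i, j] <- -(hf(mu + ei + ej) - hf(mu + ei - ej) -
                   hf(mu - ei + ej) + hf(mu - ei - ej)) / (4 * hs^2)
  }
  H <- (H + t(H)) / 2
  ev <- eigen(H, symmetric = TRUE)
  lam <- pmax(ev$values, 0.25 / max(omega[act])^2)
  A <- ev$vectors %*% diag(1 / sqrt(lam), d) %*% t(ev$vectors)
  gh <- pracma::gaussHermite(nodes)
  grid <- if (d == 1) matrix(gh$x, ncol = 1) else
    as.matrix(expand.grid(gh$x, gh$x))
  logw <- if (d == 1) log(gh$w) + gh$x^2 else
    log(outer(gh$w, gh$w))[cbind(rep(seq_len(nodes), times = nodes),
                                 rep(seq_len(nodes), each = nodes))] +
      rowSums(grid^2)
  terms <- apply(cbind(grid, logw), 1, function(z) {
    x <- z[seq_len(d)]
    hf(mu + sqrt(2) * drop(A %*% x)) + z[d + 1]
  })
  mx <- max(terms)
  logL <- 0.5 * d * log(2) - 0.5 * sum(log(lam)) + mx + log(sum(exp(terms - mx)))
  -2 * logL
}

# OFV oracle for a whole dataset under the final-model parameterisation
r_oracle_ofv <- function(data, p, residual = "proportional", nodes = 64) {
  total <- 0
  for (s in data) {
    cov <- s$covariates
    ltvcl <- log(p$theta_CL) + 0.75 * log(cov$weight) +
      p$exp_sCr * log(cov$sCr / p$ref_sCr) +
      p$exp_DFLT * log(max(cov$DFLT, p$dflt_floor) / p$ref_DFLT)
    ltvv <- log(p$theta_V) + log(cov$weight)
    total <- total + r_aghq_m2ll(s, ltvcl, ltvv,
                                 c(p$omega_CL, p$omega_V),
                                 p$sigma_add, p$sigma_prop, residual, nodes)
  }
  total
}

# compact builders for hand-made records
make_record <- function(id, weight, sCr = 0.16, DFLT = 17, times, conc,
                        dose_amt = 15 * weight, n_doses = 5, interval = 6) {
  pk_subject(id,
             list(weight = weight, sCr = sCr, DFLT = DFLT, height = 70,
                  age = 13, sex = 1, albumin = 3.1, ALT = 50, UD = 0),
             dose_event(seq(0, by = interval, length.out = n_doses),
                        rep(dose_amt, n_doses), 1),
             data.frame(time = times, conc = conc))
}
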