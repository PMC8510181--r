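#' Nonlinear mixed-effects model specification
#'
#' The structural model is fixed (one-compartment IV infusion with allometric
#' weight scaling: CL ~ wt^0.75, V ~ wt^1.0). A specification adds covariate
#' effects on top of that base and chooses the residual-error model.
#' Continuous covariates enter as median-normalised power terms
#' `(x/ref)^beta`; categorical covariates as multiplicative factors
#' `exp(beta * indicator)`.
#'
#' @param covariates `NULL` or a data.frame with columns `covariate` (name of
#'   a covariate column), `param` (`"CL"` or `"V"`), `type` (`"power"` or
#'   `"categorical"`), `ref` (normalising reference; ignored for
#'   categorical) and optionally `floor` (lower floor applied before the
#'   power term; used for DFLT).
#' @param residual one of `"combined"`, `"additive"`, `"proportional"`,
#'   `"exponential"`.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(covariates = NULL,
                       residual = c("combined", "additive", "proportional",
                                    "exponential")) {
  residual <- match.arg(residual)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    need <- c("covariate", "param", "type", "ref")
    if (!all(need %in% names(covariates)))
      stop("covariates needs columns: ", paste(need, collapse = ", "))
    if (is.null(covariates$floor)) covariates$floor <- NA_real_
    if (!all(covariates$param %in% c("CL", "V")))
      stop("covariate param must be 'CL' or 'V'")
    if (!all(covariates$type %in% c("power", "categorical")))
      stop("covariate type must be 'power' or 'categorical'")
    key <- paste(covariates$covariate, covariates$param)
    if (anyDuplicated(key))
      stop("each covariate may attach to a parameter only once")
  }
  structure(list(covariates = covariates, residual = residual),
            class = "model_spec")
}

#' @rdname model_spec
#' @export
base_model_spec <- function(residual = "combined") {
  model_spec(NULL, residual)
}

#' @rdname model_spec
#' @export
final_model_spec <- function(residual = "proportional") {
  model_spec(data.frame(covariate = c("sCr", "DFLT"), param = "CL",
                        type = "power", ref = c(0.16, 17),
                        floor = c(NA, 1)),
             residual)
}

#' Add one covariate effect to a specification
#'
#' @param spec a [model_spec()].
#' @param covariate covariate column name.
#' @param param `"CL"` or `"V"`.
#' @param type `"power"` or `"categorical"`; defaults to categorical for
#'   `sex`/`UD`, power otherwise.
#' @param ref normalising reference; defaults to the study median for the
#'   known covariates.
#' @return The extended `model_spec`.
#' @export
add_covariate <- function(spec, covariate, param, type = NULL, ref = NULL) {
  if (is.null(type))
    type <- if (covariate %in% c("sex", "UD")) "categorical" else "power"
  if (is.null(ref)) {
    meds <- c(age = 13.3, sCr = 0.16, albumin = 3.1, ALT = 54.7, DFLT = 17,
              weight = 9.1, height = 69.7)
    ref <- if (type == "categorical") 1 else unname(meds[covariate])
    if (is.na(ref)) stop("no default reference for covariate ", covariate)
  }
  row <- data.frame(covariate = covariate, param = param, type = type,
                    ref = ref, floor = if (covariate == "DFLT") 1 else NA_real_)
  model_spec(rbind(spec$covariates, row), spec$residual)
}

#' @export
print.model_spec <- function(x, ...) {
  cat("NLME model spec: one-compartment infusion, CL~wt^0.75, V~wt\n")
  cat("  residual model:", x$residual, "\n")
  if (is.null(x$covariates)) cat("  no covariate effects\n")
  else {
    for (i in seq_len(nrow(x$covariates)))
      cat(sprintf("  %s on %s (%s, ref %g)\n", x$covariates$covariate[i],
                  x$covariates$param[i], x$covariates$type[i],
                  x$covariates$ref[i]))
  }
  invisible(x)
}

res_model_code <- function(residual) {
  c(additive = 1L, proportional = 2L, combined = 3L, exponential = 4L)[[residual]]
}

# Flatten a pk_dataset for the compiled likelihood: 0-based slice pointers,
# per-record log-typical offsets and covariate design matrices.
build_nlme_data <- function(data, spec) {
  stopifnot(inherits(data, "pk_dataset"))
  n <- length(data)
  nobs <- vapply(data, function(s) nrow(s$observations), integer(1))
  if (any(nobs == 0))
    stop("every episode needs at least one observation to be fitted")
  ndose <- vapply(data, function(s) nrow(s$doses), integer(1))
  obs_t <- unlist(lapply(data, function(s) s$observations$time), use.names = FALSE)
  obs_y <- unlist(lapply(data, function(s) s$observations$conc), use.names = FALSE)
  obs_cens <- unlist(lapply(data, function(s)
    as.integer(s$observations$bql %||% rep(FALSE, nrow(s$observations)))),
    use.names = FALSE)
  dose_t0 <- unlist(lapply(data, function(s) s$doses$time), use.names = FALSE)
  dose_rate <- unlist(lapply(data, function(s) s$doses$rate), use.names = FALSE)
  dose_dur <- unlist(lapply(data, function(s) s$doses$duration), use.names = FALSE)
  cov <- covariate_table(data)
  ocl <- 0.75 * log(cov$weight)
  ov <- log(cov$weight)
  zcols <- function(param) {
    Z <- matrix(1, n, 1)
    cn <- "(intercept)"
    cv <- spec$covariates
    if (!is.null(cv)) {
      for (i in which(cv$param == param)) {
        x <- cov[[cv$covariate[i]]]
        if (is.null(x)) stop("dataset lacks covariate ", cv$covariate[i])
        z <- if (cv$type[i] == "power") {
          if (!is.na(cv$floor[i])) x <- pmax(x, cv$floor[i])
          log(x / cv$ref[i])
        } else as.numeric(x)
        Z <- cbind(Z, z)
        cn <- c(cn, cv$covariate[i])
      }
    }
    colnames(Z) <- cn
    Z
  }
  list(n = n, n_obs = sum(nobs),
       obs_t = obs_t, obs_y = obs_y, obs_cens = obs_cens,
       obs_ptr = c(0L, cumsum(nobs)),
       dose_t0 = dose_t0, dose_rate = dose_rate, dose_dur = dose_dur,
       dose_ptr = c(0L, cumsum(ndose)),
       ocl = ocl, ov = ov, Zcl = zcols("CL"), Zv = zcols("V"),
       cov = cov)
}

# parameter vector layout and log/identity transforms for a spec
spec_par_info <- function(spec) {
  cv <- spec$covariates
  ncl <- if (is.null(cv)) 0L else sum(cv$param == "CL")
  nv <- if (is.null(cv)) 0L else sum(cv$param == "V")
  nm_cl <- if (ncl) paste0("beta_", cv$covariate[cv$param == "CL"], "_CL") else character()
  nm_v <- if (nv) paste0("beta_", cv$covariate[cv$param == "V"], "_V") else character()
  sig <- switch(spec$residual,
                additive = "sigma_add", proportional = "sigma_prop",
                combined = c("sigma_add", "sigma_prop"),
                exponential = "sigma_exp")
  names <- c("theta_CL", nm_cl, "theta_V", nm_v, "omega_CL", "omega_V", sig)
  logpar <- !grepl("^beta_", names)
  list(names = names, logpar = logpar, ncl = ncl, nv = nv,
       resm = res_model_code(spec$residual))
}

to_tpar <- function(par, info) {
  out <- par
  out[info$logpar] <- log(par[info$logpar])
  out
}
from_tpar <- function(tpar, info) {
  p <- ifelse(info$logpar, exp(tpar), tpar)
  names(p) <- info$names
  p
}

# expand a natural-scale named parameter vector into the pieces the compiled
# likelihood needs
par_pieces <- function(par, info) {
  p1 <- 1L + info$ncl
  thcl <- par[seq_len(p1)]
  thcl[1] <- log(thcl[1])
  thv <- par[p1 + seq_len(1L + info$nv)]
  thv[1] <- log(thv[1])
  sadd <- if ("sigma_add" %in% info$names) par[["sigma_add"]] else 0
  sprop <- if ("sigma_prop" %in% info$names) par[["sigma_prop"]]
  else if ("sigma_exp" %in% info$names) par[["sigma_exp"]] else 0
  list(thcl = thcl, thv = thv,
       omCL = par[["omega_CL"]], omV = par[["omega_V"]],
       sadd = sadd, sprop = sprop)
}

ofv_eval <- function(nd, pieces, resm, want_eta = FALSE, nodes = 5L) {
  ltvcl <- nd$ocl + drop(nd$Zcl %*% pieces$thcl)
  ltvv <- nd$ov + drop(nd$Zv %*% pieces$thv)
  ofv_laplace_cpp(nd$obs_t, nd$obs_y, nd$obs_cens, nd$obs_ptr,
                  nd$dose_t0, nd$dose_rate, nd$dose_dur, nd$dose_ptr,
                  ltvcl, ltvv, pieces$omCL, pieces$omV,
                  pieces$sadd, pieces$sprop, resm, want_eta, as.integer(nodes))
}

# map a pop_params object onto a spec's parameter vector
pop_params_to_par <- function(p, spec, info) {
  par <- setNames(numeric(length(info$names)), info$names)
  par["theta_CL"] <- p$theta_CL
  par["theta_V"] <- p$theta_V
  par["omega_CL"] <- p$omega_CL
  par["omega_V"] <- p$omega_V
  if ("sigma_add" %in% info$names) par["sigma_add"] <- p$sigma_add
  if ("sigma_prop" %in% info$names) par["sigma_prop"] <- p$sigma_prop
  if ("sigma_exp" %in% info$names) par["sigma_exp"] <- p$sigma_prop
  for (nm in names(par)[grepl("^beta_", names(par))]) {
    par[nm] <- switch(nm, beta_sCr_CL = p$exp_sCr, beta_DFLT_CL = p$exp_DFLT, 0)
  }
  par
}

#' Objective function value (-2 log marginal likelihood)
#'
#' Laplace approximation to the marginal likelihood, summed over independent
#' episodes: for each record the joint density of observations and random
#' effects is maximised over (eta_CL, eta_V) and corrected with the curvature
#' at the mode.
#'
#' @param data a [pk_dataset()].
#' @param spec a [model_spec()].
#' @param p parameters: a [population_params()] object or a named numeric
#'   vector matching the spec's parameters (see [fit_nlme()] coefficients).
#' @param nodes quadrature nodes per random-effect dimension: 1 gives the
#'   pure Laplace approximation; the default 5 (7 also supported) refines it
#'   by adaptive Gauss-Hermite quadrature around each subject's conditional
#'   mode (more accurate, and stable for weakly identified subjects).
#' @return OFV (numeric scalar).
#' @export
ofv <- function(data, spec, p, nodes = 5L) {
  info <- spec_par_info(spec)
  par <- if (inherits(p, "pop_params")) pop_params_to_par(p, spec, info)
  else p[info$names]
  nd <- build_nlme_data(data, spec)
  r <- ofv_eval(nd, par_pieces(par, info), info$resm, nodes = nodes)
  if (!r$ok)
    stop("non-finite likelihood for episode ", data[[r$bad_subject]]$id,
         " (zero predicted concentration with a proportional-only error?)")
  r$ofv
}

default_init <- function(info) {
  par <- setNames(numeric(length(info$names)), info$names)
  par["theta_CL"] <- 0.15
  par["theta_V"] <- 0.7
  par["omega_CL"] <- 0.3
  par["omega_V"] <- 0.3
  if ("sigma_add" %in% info$names) par["sigma_add"] <- 1
  if ("sigma_prop" %in% info$names) par["sigma_prop"] <- 0.3
  if ("sigma_exp" %in% info$names) par["sigma_exp"] <- 0.3
  par  # betas stay 0
}

#' Fit the population model by Laplace/FOCE maximum likelihood
#'
#' Minimises the Laplace-approximated OFV over fixed effects, between-subject
#' SDs and residual SDs. Variance parameters and the positive structural
#' coefficients are optimised on the log scale; covariate exponents are
#' unconstrained. Standard errors come from the numerical Hessian of the OFV
#' at the optimum (delta method back to the natural scale).
#'
#' @param data a [pk_dataset()].
#' @param spec a [model_spec()].
#' @param init optional starting values: a [population_params()] object, a
#'   named natural-scale vector (possibly partial), or `NULL` for neutral
#'   defaults.
#' @param control list; `iter.max` (default 500), `se` (compute standard
#'   errors, default TRUE), `nodes` (quadrature nodes per dimension, default
#'   5; 1 = pure Laplace).
#' @return An object of class `pop_fit` with elements `estimates` (named,
#'   natural scale), `coef_table`, `ofv`, `etas` (empirical Bayes modes),
#'   `shrinkage`, `converged`, `n_subjects`, `n_obs`.
#' @examples
#' \donttest{
#' d <- simulate_dataset(30, seed = 7)
#' f <- fit_nlme(d, final_model_spec())
#' f
#' }
#' @export
fit_nlme <- function(data, spec = final_model_spec(), init = NULL,
                     control = list()) {
  nodes <- control$nodes %||% 5L
  info <- spec_par_info(spec)
  nd <- build_nlme_data(data, spec)
  par0 <- default_init(info)
  if (inherits(init, "pop_params")) {
    par0 <- pop_params_to_par(init, spec, info)
  } else if (!is.null(init)) {
    par0[intersect(names(init), names(par0))] <-
      init[intersect(names(init), names(par0))]
  }
  # zero variances cannot be represented on the log scale; nudge them
  par0[info$logpar & par0 <= 0] <- 1e-3
  obj <- function(tpar) {
    par <- from_tpar(tpar, info)
    r <- ofv_eval(nd, par_pieces(par, info), info$resm, nodes = nodes)
    if (!r$ok || !is.finite(r$ofv)) return(1e10)
    r$ofv
  }
  ctl <- list(iter.max = control$iter.max %||% 500,
              eval.max = control$eval.max %||% 2000,
              rel.tol = control$rel.tol %||% 1e-8)
  # generous box on the transformed scale keeps log-variances from drifting
  # to -Inf when a variance component is truly 0
  run_outer <- function(start) nlminb(start, obj, control = ctl,
                                      lower = -15, upper = 15)
  coord_probe <- function(x, f0) {
    best <- NULL
    for (i in seq_along(x)) {
      for (step in c(-0.02, -0.005, 0.005, 0.02)) {
        xp <- x
        xp[i] <- xp[i] + step
        fp <- obj(xp)
        if (fp < f0 - 0.05 && (is.null(best) || fp < best$f)) {
          best <- list(x = xp, f = fp)
        }
      }
    }
    best
  }
  opt <- run_outer(to_tpar(par0, info))
  converged <- opt$convergence == 0
  if (!converged) {
    # nlminb's "false convergence" usually fires at a genuine optimum:
    # accept the point when no small coordinate step improves the OFV
    # materially. A real stall (an improving step exists) is rescued by a
    # Nelder-Mead stage - the simplex is insensitive to the rare residual
    # cliffs of the objective - and a final nlminb polish.
    probe <- coord_probe(opt$par, opt$objective)
    if (is.null(probe)) {
      converged <- TRUE
    } else {
      nm <- optim(probe$x, obj, method = "Nelder-Mead",
                  control = list(maxit = 1000, reltol = 1e-12))
      opt2 <- run_outer(nm$par)
      if (opt2$objective <= opt$objective + 1e-8) opt <- opt2
      converged <- opt$convergence == 0
      if (!converged)
        converged <- is.null(coord_probe(opt$par, opt$objective))
    }
  }
  est <- from_tpar(opt$par, info)
  pieces <- par_pieces(est, info)
  r <- ofv_eval(nd, pieces, info$resm, want_eta = TRUE, nodes = nodes)
  se <- rep(NA_real_, length(est))
  if (isTRUE(control$se %||% TRUE)) {
    H <- try(optimHess(opt$par, obj), silent = TRUE)
    if (!inherits(H, "try-error")) {
      Vc <- try(2 * solve(H), silent = TRUE)
      if (!inherits(Vc, "try-error")) {
        se_t <- sqrt(pmax(diag(Vc), 0))
        se <- ifelse(info$logpar, se_t * est, se_t)  # delta method
      }
    }
  }
  etas <- r$eta
  colnames(etas) <- c("eta_CL", "eta_V")
  rownames(etas) <- vapply(data, function(s) s$id, character(1))
  fit <- structure(list(
    estimates = est,
    coef_table = data.frame(parameter = info$names, estimate = unname(est),
                            se = unname(se),
                            rse_pct = unname(100 * se / abs(est))),
    ofv = r$ofv, etas = etas,
    converged = converged && r$ok,
    message = opt$message,
    n_subjects = nd$n, n_obs = nd$n_obs,
    spec = spec, data = data, nlme = nd, info = info), class = "pop_fit")
  fit$shrinkage <- shrinkage(fit)
  fit
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pop_fit <- function(x, ...) {
  cat(sprintf("Population PK fit (Laplace): %d episodes, %d observations\n",
              x$n_subjects, x$n_obs))
  cat(sprintf("  OFV %.3f, %s\n", x$ofv,
              if (x$converged) "converged" else "NOT converged"))
  ct <- x$coef_table
  ct$estimate <- signif(ct$estimate, 4)
  ct$se <- signif(ct$se, 3)
  ct$rse_pct <- round(ct$rse_pct, 1)
  print(ct, row.names = FALSE)
  s <- x$shrinkage
  cat(sprintf("  eta-shrinkage CL %.1f%%, V %.1f%%; eps-shrinkage %.1f%%\n",
              100 * s[["eta_shrinkage_CL"]], 100 * s[["eta_shrinkage_V"]],
              100 * s[["eps_shrinkage"]]))
  invisible(x)
}

#' Convert a final-model fit to a `pop_params` object
#'
#' @param fit a [fit_nlme()] result whose spec uses (at most) the sCr and
#'   DFLT power effects on CL.
#' @return A [population_params()] object.
#' @export
as_pop_params <- function(fit) {
  e <- fit$estimates
  population_params(
    theta_CL = e[["theta_CL"]], theta_V = e[["theta_V"]],
    exp_sCr = if ("beta_sCr_CL" %in% names(e)) e[["beta_sCr_CL"]] else 0,
    exp_DFLT = if ("beta_DFLT_CL" %in% names(e)) e[["beta_DFLT_CL"]] else 0,
    omega_CL = e[["omega_CL"]], omega_V = e[["omega_V"]],
    sigma_prop = if ("sigma_prop" %in% names(e)) e[["sigma_prop"]]
    else if ("sigma_exp" %in% names(e)) e[["sigma_exp"]] else 0,
    sigma_add = if ("sigma_add" %in% names(e)) e[["sigma_add"]] else 0)
}

#' Empirical Bayes (post hoc) random-effect estimates
#'
#' Returns the mode of the conditional distribution of (eta_CL, eta_V) given
#' a subject's observations, at fixed population parameters. Episodes with no
#' observations get the prior mode (0, 0).
#'
#' @param data a [pk_dataset()] or single [pk_subject()].
#' @param spec a [model_spec()].
#' @param p parameters as in [ofv()].
#' @return Matrix with columns `eta_CL`, `eta_V` (one row per episode).
#' @export
posthoc_ebe <- function(data, spec, p) {
  # conditional modes do not depend on the quadrature refinement
  if (inherits(data, "pk_subject")) data <- pk_dataset(list(data))
  info <- spec_par_info(spec)
  par <- if (inherits(p, "pop_params")) pop_params_to_par(p, spec, info)
  else p[info$names]
  # zero-observation episodes get the prior mode
  n <- length(data)
  nobs <- vapply(data, function(s) nrow(s$observations), integer(1))
  keep <- which(nobs > 0)
  out <- matrix(0, n, 2, dimnames = list(vapply(data, `[[`, character(1), "id"),
                                         c("eta_CL", "eta_V")))
  if (length(keep)) {
    nd <- build_nlme_data(data[keep], spec)
    r <- ofv_eval(nd, par_pieces(par, info), info$resm, want_eta = TRUE)
    out[keep, ] <- r$eta
  }
  out
}

#' Shrinkage diagnostics of a fit
#'
#' Eta-shrinkage is `1 - SD(EBE)/omega` per random effect (reported as 1 when
#' omega is 0); epsilon-shrinkage is `1 - SD(IWRES)`, with
#' `IWRES = (y - IPRED)/sqrt(sigma_add^2 + sigma_prop^2 IPRED^2)` at the
#' individual (EBE) predictions.
#'
#' @param fit a [fit_nlme()] result.
#' @return Named vector `eta_shrinkage_CL`, `eta_shrinkage_V`,
#'   `eps_shrinkage` (fractions).
#' @export
shrinkage <- function(fit) {
  e <- fit$estimates
  sh <- function(ebe, om) if (om <= 1e-8) 1 else 1 - sd(ebe) / om
  iw <- iwres(fit)
  c(eta_shrinkage_CL = sh(fit$etas[, 1], e[["omega_CL"]]),
    eta_shrinkage_V = sh(fit$etas[, 2], e[["omega_V"]]),
    eps_shrinkage = 1 - sd(iw))
}

#' Post hoc individual pharmacokinetic parameters of a fit
#'
#' Empirical-Bayes individual clearance and volume (typical value at the
#' episode's covariates times `exp(eta)` at the conditional mode), with
#' per-kilogram normalisations.
#'
#' @param fit a [fit_nlme()] result.
#' @return data.frame with columns `id`, `CL` (L/h), `V` (L), `CL_per_kg`,
#'   `V_per_kg`, `eta_CL`, `eta_V`.
#' @export
posthoc_params <- function(fit) {
  stopifnot(inherits(fit, "pop_fit"))
  clv <- indiv_clv(fit)
  wt <- fit$nlme$cov$weight
  data.frame(id = rownames(fit$etas), CL = clv$CL, V = clv$V,
             CL_per_kg = clv$CL / wt, V_per_kg = clv$V / wt,
             eta_CL = fit$etas[, 1], eta_V = fit$etas[, 2],
             row.names = NULL)
}

# per-record individual CL and V at given etas (general covariate specs)
indiv_clv <- function(fit, etas = fit$etas) {
  nd <- fit$nlme
  pieces <- par_pieces(fit$estimates, fit$info)
  ltvcl <- nd$ocl + drop(nd$Zcl %*% pieces$thcl)
  ltvv <- nd$ov + drop(nd$Zv %*% pieces$thv)
  list(CL = exp(ltvcl + etas[, 1]), V = exp(ltvv + etas[, 2]))
}

# per-observation model predictions at given etas
indiv_pred <- function(fit, etas = fit$etas) {
  nd <- fit$nlme
  clv <- indiv_clv(fit, etas)
  f <- numeric(nd$n_obs)
  for (i in seq_len(nd$n)) {
    oi <- (nd$obs_ptr[i] + 1):nd$obs_ptr[i + 1]
    di <- (nd$dose_ptr[i] + 1):nd$dose_ptr[i + 1]
    f[oi] <- conc_profile_cpp(nd$obs_t[oi], nd$dose_t0[di], nd$dose_rate[di],
                              nd$dose_dur[di], clv$CL[i], clv$V[i])
  }
  f
}

residual_sigmas <- function(fit) {
  e <- fit$estimates
  c(sadd = if ("sigma_add" %in% names(e)) e[["sigma_add"]] else 0,
    sprop = if ("sigma_prop" %in% names(e)) e[["sigma_prop"]]
    else if ("sigma_exp" %in% names(e)) e[["sigma_exp"]] else 0)
}

# individually weighted residuals; censored (below-quantification)
# observations have no defined residual and are excluded
iwres <- function(fit, keep_censored = FALSE) {
  f <- indiv_pred(fit)
  s <- residual_sigmas(fit)
  r <- if (fit$spec$residual == "exponential")
    (log(fit$nlme$obs_y) - log(f)) / s[["sprop"]]
  else
    (fit$nlme$obs_y - f) / sqrt(s[["sadd"]]^2 + s[["sprop"]]^2 * f^2)
  if (keep_censored) r else r[fit$nlme$obs_cens == 0]
}
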