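#' Default covariate candidate grid for model building
#'
#' All screened covariates (age, sex, underlying disease, sCr, albumin, ALT,
#' DFLT) crossed with both structural parameters (CL, V). Continuous
#' covariates enter as study-median-normalised power terms, sex and
#' underlying disease as multiplicative categorical factors.
#'
#' @return data.frame usable as `candidates` in
#'   [stepwise_covariate_search()].
#' @export
default_candidates <- function() {
  covs <- c("age", "sex", "UD", "sCr", "albumin", "ALT", "DFLT")
  meds <- c(age = 13.3, sCr = 0.16, albumin = 3.1, ALT = 54.7, DFLT = 17)
  grid <- expand.grid(covariate = covs, param = c("CL", "V"),
                      stringsAsFactors = FALSE)
  grid$type <- ifelse(grid$covariate %in% c("sex", "UD"),
                      "categorical", "power")
  grid$ref <- ifelse(grid$type == "categorical", 1,
                     unname(meds[grid$covariate]))
  grid$floor <- ifelse(grid$covariate == "DFLT", 1, NA_real_)
  grid
}

#' Stepwise covariate model building
#'
#' Univariate screening followed by forward inclusion / backward elimination
#' on the Laplace OFV. Forward: at each step every remaining candidate is
#' added to the current model; the one with the largest OFV drop is included
#' if the drop exceeds `forward_dofv` (3.84 = chi-square 1 df, p < 0.05).
#' Backward: each included covariate is removed in turn; a covariate is
#' eliminated when its removal raises the OFV by less than `backward_dofv`
#' (7.88, p < 0.005). Candidate fits that fail to converge are recorded as
#' not selectable and the search continues.
#'
#' @param data a [pk_dataset()].
#' @param base_spec starting [model_spec()] (no covariates by default).
#' @param candidates candidate data.frame as from [default_candidates()].
#' @param forward_dofv,backward_dofv OFV-change thresholds.
#' @param init optional starting values for the base fit.
#' @param control passed to [fit_nlme()].
#' @return An object of class `stepwise_result`: `final_spec`, `final_fit`,
#'   `screening` (Table-2-shaped: covariate, parameter, delta-OFV), `steps`
#'   (forward/backward log).
#' @export
stepwise_covariate_search <- function(data, base_spec = base_model_spec(),
                                      candidates = default_candidates(),
                                      forward_dofv = 3.84,
                                      backward_dofv = 7.88,
                                      init = NULL, control = list()) {
  base_fit <- fit_nlme(data, base_spec, init = init, control = control)
  warm <- function(fit, extra = NULL) {
    st <- fit$estimates
    if (!is.null(extra)) st <- c(st, setNames(0, extra))
    st
  }
  fit_with <- function(cov_rows, start) {
    spec <- model_spec(cov_rows, base_spec$residual)
    out <- try(fit_nlme(data, spec, init = start, control = control),
               silent = TRUE)
    if (inherits(out, "try-error")) NULL else out
  }
  cand_name <- function(r) paste0(r$covariate, " on ", r$param)
  beta_name <- function(r) paste0("beta_", r$covariate, "_", r$param)

  # univariate screening against the base model
  screening <- candidates
  screening$delta_ofv <- NA_real_
  screening$converged <- FALSE
  for (i in seq_len(nrow(candidates))) {
    r <- candidates[i, , drop = FALSE]
    ft <- fit_with(rbind(base_spec$covariates, r), warm(base_fit, beta_name(r)))
    if (!is.null(ft)) {
      screening$delta_ofv[i] <- ft$ofv - base_fit$ofv
      screening$converged[i] <- ft$converged
    }
  }

  steps <- list()
  current_rows <- base_spec$covariates
  current_fit <- base_fit
  remaining <- seq_len(nrow(candidates))
  # forward inclusion
  repeat {
    best <- NULL
    best_d <- 0
    step_log <- data.frame()
    for (i in remaining) {
      r <- candidates[i, , drop = FALSE]
      ft <- fit_with(rbind(current_rows, r), warm(current_fit, beta_name(r)))
      d <- if (is.null(ft) || !ft$converged) NA_real_ else ft$ofv - current_fit$ofv
      step_log <- rbind(step_log,
                        data.frame(candidate = cand_name(r), delta_ofv = d))
      if (!is.na(d) && -d > best_d && -d > forward_dofv) {
        best <- list(i = i, fit = ft); best_d <- -d
      }
    }
    steps[[length(steps) + 1]] <- list(phase = "forward", table = step_log,
                                       added = if (is.null(best)) NA_character_
                                       else cand_name(candidates[best$i, ]))
    if (is.null(best)) break
    current_rows <- rbind(current_rows, candidates[best$i, , drop = FALSE])
    current_fit <- best$fit
    remaining <- setdiff(remaining, best$i)
    if (!length(remaining)) break
  }
  # backward elimination
  repeat {
    if (is.null(current_rows) || !nrow(current_rows)) break
    worst <- NULL
    worst_rise <- Inf
    step_log <- data.frame()
    for (j in seq_len(nrow(current_rows))) {
      rows <- current_rows[-j, , drop = FALSE]
      if (!nrow(rows)) rows <- NULL
      ft <- fit_with(rows, warm(current_fit))
      rise <- if (is.null(ft) || !ft$converged) NA_real_
      else ft$ofv - current_fit$ofv
      step_log <- rbind(step_log,
                        data.frame(removed = cand_name(current_rows[j, ]),
                                   delta_ofv = rise))
      if (!is.na(rise) && rise < worst_rise) {
        worst <- list(j = j, fit = ft); worst_rise <- rise
      }
    }
    steps[[length(steps) + 1]] <- list(phase = "backward", table = step_log,
                                       removed = if (!is.null(worst) &&
                                                     worst_rise < backward_dofv)
                                         cand_name(current_rows[worst$j, ])
                                       else NA_character_)
    if (is.null(worst) || worst_rise >= backward_dofv) break
    current_rows <- current_rows[-worst$j, , drop = FALSE]
    if (!nrow(current_rows)) current_rows <- NULL
    current_fit <- worst$fit
  }
  structure(list(
    final_spec = model_spec(current_rows, base_spec$residual),
    final_fit = current_fit, base_fit = base_fit,
    screening = data.frame(covariate = screening$covariate,
                           parameter = screening$param,
                           delta_ofv = screening$delta_ofv,
                           converged = screening$converged),
    steps = steps), class = "stepwise_result")
}

#' @export
print.stepwise_result <- function(x, ...) {
  cat("Stepwise covariate search\n\nUnivariate screening (delta OFV vs base):\n")
  scr <- x$screening
  scr$delta_ofv <- round(scr$delta_ofv, 2)
  print(scr, row.names = FALSE)
  cat("\nFinal model covariates:\n")
  if (is.null(x$final_spec$covariates)) cat("  (none)\n")
  else print(x$final_spec$covariates[, c("covariate", "param", "type", "ref")],
             row.names = FALSE)
  cat(sprintf("\nFinal OFV %.2f (base %.2f)\n", x$final_fit$ofv, x$base_fit$ofv))
  invisible(x)
}
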