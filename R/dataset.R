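#' One treatment episode: covariates, dosing history, observations
#'
#' @param id identifier (coerced to character).
#' @param covariates named list or one-row data.frame of baseline covariates
#'   (`weight`, `height`, `age`, `sex`, `sCr`, `DFLT`, `albumin`, `ALT`,
#'   `UD`); covariates are treated as constant within the episode.
#' @param doses dose table from [dose_event()].
#' @param observations data.frame with columns `time` (h), `conc` (ug/ml) and
#'   optionally `bql` (logical, value floored at the quantification limit).
#' @return An object of class `pk_subject`.
#' @export
pk_subject <- function(id, covariates, doses,
                       observations = data.frame(time = numeric(),
                                                 conc = numeric())) {
  cov <- as_covariates(covariates)
  obs <- as.data.frame(observations)
  if (nrow(obs)) {
    if (!all(c("time", "conc") %in% names(obs)))
      stop("observations need columns 'time' and 'conc'")
    if (any(obs$time < 0)) stop("observation times must be >= 0")
    if (any(obs$conc < 0)) stop("concentrations must be >= 0")
    if (is.unsorted(obs$time)) obs <- obs[order(obs$time), , drop = FALSE]
  }
  if (is.null(obs$bql)) obs$bql <- rep(FALSE, nrow(obs))
  if (nrow(doses) && is.unsorted(doses$time))
    doses <- doses[order(doses$time), , drop = FALSE]
  rownames(obs) <- NULL
  structure(list(id = as.character(id), covariates = cov, doses = doses,
                 observations = obs),
            class = "pk_subject")
}

#' @export
print.pk_subject <- function(x, ...) {
  cat(sprintf("<pk_subject %s> %d doses, %d observations; wt %.1f kg, sCr %.2f mg/dl, DFLT %g d\n",
              x$id, nrow(x$doses), nrow(x$observations),
              x$covariates$weight, x$covariates$sCr, x$covariates$DFLT))
  invisible(x)
}

#' Collection of treatment episodes
#'
#' @param records list of [pk_subject()] objects.
#' @return An object of class `pk_dataset` (a list of episodes).
#' @export
pk_dataset <- function(records) {
  stopifnot(all(vapply(records, inherits, logical(1), "pk_subject")))
  structure(records, class = c("pk_dataset", "list"))
}

#' @export
print.pk_dataset <- function(x, ...) {
  nobs <- sum(vapply(x, function(s) nrow(s$observations), integer(1)))
  cat(sprintf("<pk_dataset> %d episodes, %d observations\n", length(x), nobs))
  invisible(x)
}

#' @export
`[.pk_dataset` <- function(x, i) {
  pk_dataset(unclass(x)[i])
}

#' Covariate table of a dataset
#'
#' @param data a [pk_dataset()].
#' @return data.frame with one row per episode (plus an `id` column).
#' @export
covariate_table <- function(data) {
  df <- do.call(rbind, lapply(data, function(s) s$covariates))
  df <- cbind(id = vapply(data, function(s) s$id, character(1)), df)
  rownames(df) <- NULL
  df
}
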