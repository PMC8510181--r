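# NONMEM-style dataset dialect: one CSV row per event.
#   ID, TIME (h), DV (ug/ml), AMT (mg), RATE (mg/h), EVID (0 obs, 1 dose),
#   MDV (1 = DV missing), covariates WT, HT, AGE, SEX (1 male), SCR, DFLT,
#   ALB, ALT, UD (1 biliary atresia). Missing-value token ".".
pk_dialect_cols <- c("ID", "TIME", "DV", "AMT", "RATE", "EVID", "MDV",
                     "WT", "HT", "AGE", "SEX", "SCR", "DFLT", "ALB", "ALT",
                     "UD")
cov_map <- c(WT = "weight", HT = "height", AGE = "age", SEX = "sex",
             SCR = "sCr", DFLT = "DFLT", ALB = "albumin", ALT = "ALT",
             UD = "UD")

#' Read a NONMEM-style PK dataset
#'
#' Reads the CSV event dialect (columns `ID`, `TIME`, `DV`, `AMT`, `RATE`,
#' `EVID`, `MDV` plus covariates `WT`, `HT`, `AGE`, `SEX`, `SCR`, `DFLT`,
#' `ALB`, `ALT`, `UD`; missing token `"."`) and validates it: dose rows must
#' have `EVID = 1`, `AMT > 0`, `MDV = 1`; observation rows `EVID = 0`,
#' `MDV = 0` and a present `DV`; times must be non-decreasing within an
#' episode. Violations are reported with their row number.
#'
#' @param path CSV file path.
#' @return A [pk_dataset()] (baseline covariates taken from each episode's
#'   first row).
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("dataset file not found: ", path)
  df <- read.csv(path, na.strings = ".", stringsAsFactors = FALSE)
  if (!nrow(df)) stop("empty dataset: ", path)
  miss <- setdiff(pk_dialect_cols, names(df))
  if (length(miss))
    stop("dataset schema error: missing required column(s) ",
         paste(miss, collapse = ", "))
  rowno <- seq_len(nrow(df)) + 1L  # header is line 1
  bad <- function(cond, msg) {
    if (any(cond, na.rm = TRUE)) {
      r <- rowno[which(cond)[1]]
      stop(sprintf("dataset row %d: %s", r, msg))
    }
  }
  bad(!df$EVID %in% c(0, 1), "EVID must be 0 (observation) or 1 (dose)")
  dose <- df$EVID == 1
  bad(dose & (is.na(df$AMT) | df$AMT <= 0), "dose row needs AMT > 0")
  bad(dose & (is.na(df$RATE) | df$RATE <= 0), "dose row needs RATE > 0")
  bad(dose & df$MDV != 1, "dose row must have MDV = 1")
  bad(!dose & df$MDV != 0, "observation row must have MDV = 0")
  bad(!dose & is.na(df$DV), "observation row needs a DV value")
  bad(!dose & df$DV < 0, "DV must be >= 0")
  bad(is.na(df$TIME) | df$TIME < 0, "TIME must be >= 0")
  records <- list()
  for (id in unique(df$ID)) {
    sub <- df[df$ID == id, , drop = FALSE]
    if (is.unsorted(sub$TIME))
      stop("dataset episode ", id, ": TIME must be non-decreasing")
    cov <- setNames(as.list(sub[1, names(cov_map)]), unname(cov_map))
    dr <- sub[sub$EVID == 1, , drop = FALSE]
    orow <- sub[sub$EVID == 0, , drop = FALSE]
    doses <- dose_event(dr$TIME, dr$AMT, dr$AMT / dr$RATE)
    records[[length(records) + 1]] <-
      pk_subject(id, cov, doses,
                 data.frame(time = orow$TIME, conc = orow$DV))
  }
  pk_dataset(records)
}

#' Write a dataset in the NONMEM-style dialect
#'
#' Inverse of [read_dataset()]: numeric fields are written at 6 significant
#' digits so that a read/write cycle round-trips.
#'
#' @param data a [pk_dataset()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  stopifnot(inherits(data, "pk_dataset"))
  rows <- lapply(data, function(s) {
    cov <- s$covariates
    covcols <- lapply(setNames(names(cov_map), names(cov_map)),
                      function(k) cov[[cov_map[[k]]]])
    d <- data.frame(ID = s$id, TIME = s$doses$time, DV = NA_real_,
                    AMT = s$doses$amount, RATE = s$doses$rate,
                    EVID = 1L, MDV = 1L, covcols)
    o <- data.frame(ID = s$id, TIME = s$observations$time,
                    DV = s$observations$conc, AMT = NA_real_,
                    RATE = NA_real_, EVID = 0L, MDV = 0L, covcols)
    ev <- rbind(d, o)
    ev[order(ev$TIME, -ev$EVID), , drop = FALSE]
  })
  df <- do.call(rbind, rows)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 6))
  df[] <- lapply(df, function(x) ifelse(is.na(x), ".", as.character(x)))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
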