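#' @importFrom rlang .data
#' @importFrom Rcpp sourceCpp
#' @useDynLib dapapkpd, .registration = TRUE
NULL

# Mandatory columns of the flat longitudinal dataset (NONMEM-convention):
# ID subject, TIME days since first dose, EVID 1 = dose / 0 = observation,
# DVID 1 = plasma concentration (ng/mL) / 2 = HbA1c (%), AMT dose (ng),
# DV observed value, BLQ below-LLOQ flag. Covariate columns ride along.
.et_mandatory <- c("ID", "TIME", "EVID", "DVID", "AMT", "DV")
.et_covariates <- c("WT", "AGE", "SEX", "HT", "AST", "ALT", "GGT", "SCR", "EGFR")

#' Construct a longitudinal PK-PD event table
#'
#' An event table is a tibble with one row per dose or observation event,
#' in the flat NONMEM-style dialect used throughout the package: columns
#' `ID`, `TIME` (days since first dose), `EVID` (1 = dose, 0 = observation),
#' `DVID` (1 = plasma concentration in ng/mL, 2 = HbA1c in \%), `AMT`
#' (dose in ng), `DV` (observed value), `BLQ` (below-LLOQ flag, set by the
#' constructor), plus any covariate columns (`WT`, `AGE`, `SEX`, `HT`,
#' `AST`, `ALT`, `GGT`, `SCR`, `EGFR`). Rows are sorted by subject and time
#' with dose events ordered before observations at tied times.
#'
#' @param x A data frame with at least the mandatory columns.
#' @param lloq Lower limit of quantification for concentrations (ng/mL).
#'   Concentration observations below it are retained but flagged `BLQ = 1`.
#' @return A tibble of class `event_table` with an `lloq` attribute.
#' @examples
#' tab <- event_table(data.frame(
#'   ID = 1, TIME = c(0, 1, 1), EVID = c(1, 0, 0), DVID = c(NA, 1, 2),
#'   AMT = c(5e6, NA, NA), DV = c(NA, 3.2, 6.8)
#' ))
#' event_counts(tab)
#' @export
event_table <- function(x, lloq = 0.5) {
  x <- tibble::as_tibble(x)
  missing_cols <- setdiff(.et_mandatory, names(x))
  if (length(missing_cols) > 0) {
    stop("event table format error: missing mandatory column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad_time <- which(!is.na(x$TIME) & x$TIME < 0)
  if (length(bad_time) > 0) {
    stop("event table validation error: negative TIME in row(s) ",
         paste(utils::head(bad_time, 5), collapse = ", "), call. = FALSE)
  }
  bad_amt <- which(x$EVID == 1 & (is.na(x$AMT) | x$AMT <= 0))
  if (length(bad_amt) > 0) {
    stop("event table validation error: dose row(s) with missing or ",
         "non-positive AMT: ", paste(utils::head(bad_amt, 5), collapse = ", "),
         call. = FALSE)
  }
  bad_dv <- which(x$EVID == 0 & (is.na(x$DV) | x$DV < 0))
  if (length(bad_dv) > 0) {
    stop("event table validation error: observation row(s) with missing or ",
         "negative DV: ", paste(utils::head(bad_dv, 5), collapse = ", "),
         call. = FALSE)
  }
  x <- dplyr::arrange(x, .data$ID, .data$TIME, dplyr::desc(.data$EVID))
  x$BLQ <- as.integer(x$EVID == 0 & !is.na(x$DVID) & x$DVID == 1 &
                        x$DV < lloq)
  .check_dose_precedes_obs(x)
  structure(x, lloq = lloq, class = c("event_table", class(tibble::tibble())))
}

.check_dose_precedes_obs <- function(x) {
  obs <- x[x$EVID == 0, ]
  if (nrow(obs) == 0) return(invisible(TRUE))
  first_dose <- x[x$EVID == 1, ] |>
    dplyr::group_by(.data$ID) |>
    dplyr::summarise(first_dose = min(.data$TIME), .groups = "drop")
  chk <- dplyr::left_join(obs, first_dose, by = "ID")
  # baseline HbA1c (time 0) is allowed before any dose
  bad <- chk$TIME > 0 | chk$DVID == 1
  bad <- bad & (is.na(chk$first_dose) | chk$first_dose > chk$TIME)
  if (any(bad)) {
    ids <- unique(chk$ID[bad])
    stop("event table validation error: observation(s) without a preceding ",
         "dose for subject(s) ", paste(utils::head(ids, 5), collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Read / write an event table CSV
#'
#' The on-disk format is a single UTF-8 CSV with a mandatory header,
#' '.' decimal separator, and the column dialect described in
#' [event_table()]. Reading validates the table and (re)computes the
#' `BLQ` flag from `DV` and `lloq`; a write-then-read round trip preserves
#' every field.
#'
#' @param path File path.
#' @param lloq Lower limit of quantification (ng/mL).
#' @return `read_event_table()` returns an `event_table`;
#'   `write_event_table()` returns `path` invisibly.
#' @export
read_event_table <- function(path, lloq = 0.5) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  event_table(x, lloq = lloq)
}

#' @rdname read_event_table
#' @param table An `event_table`.
#' @export
write_event_table <- function(table, path) {
  stopifnot(inherits(table, "event_table"))
  readr::write_csv(tibble::as_tibble(table), path, progress = FALSE)
  invisible(path)
}

#' Count events by kind
#'
#' @param table An `event_table`.
#' @param by_subject Also break counts down per subject?
#' @return A tibble with columns `kind` (`dose`, `pk_obs`, `pd_obs`) and `n`
#'   (plus `ID` when `by_subject = TRUE`).
#' @export
event_counts <- function(table, by_subject = FALSE) {
  x <- tibble::as_tibble(table)
  x$kind <- dplyr::case_when(
    x$EVID == 1 ~ "dose",
    x$DVID == 1 ~ "pk_obs",
    x$DVID == 2 ~ "pd_obs"
  )
  if (by_subject) {
    dplyr::count(x, .data$ID, .data$kind, name = "n")
  } else {
    dplyr::count(x, .data$kind, name = "n")
  }
}

#' Drop concentration observations below the limit of quantification
#'
#' Removes `pk_obs` rows flagged below the LLOQ (the "flag and exclude"
#' M1 approach used for the source analysis); dose and HbA1c rows are
#' untouched. The number of removed rows is reported via `message()`.
#'
#' @param table An `event_table`.
#' @return The filtered `event_table`.
#' @examples
#' \dontrun{
#' tab <- generate_event_table(cohort_spec(seed = 1))
#' exclude_blq(tab)
#' }
#' @export
exclude_blq <- function(table) {
  stopifnot(inherits(table, "event_table"))
  drop <- table$BLQ == 1
  n_pk <- sum(table$EVID == 0 & table$DVID == 1, na.rm = TRUE)
  if (sum(drop) > 0 && sum(drop) == n_pk) {
    warning("all ", n_pk, " concentration observations are below the LLOQ",
            call. = FALSE)
  }
  message(sum(drop), " below-LLOQ concentration observation(s) excluded")
  out <- table[!drop, , drop = FALSE]
  structure(out, lloq = attr(table, "lloq"),
            class = c("event_table", class(tibble::tibble())))
}

#' Covariate value in force at a given time
#'
#' Time-varying covariates are recorded at visit rows; between records the
#' value in force follows last-observation-carried-forward (the
#' conventional step rule for NLME covariates) or, optionally, linear
#' interpolation. Queries before the first record return the first recorded
#' value with a warning; queries after the last record carry it forward.
#'
#' @param table An `event_table`.
#' @param subject_id Subject `ID`.
#' @param name Covariate column name (e.g. `"WT"`).
#' @param time Query time (days).
#' @param rule `"locf"` (default) or `"linear"`.
#' @return The covariate value at `time`.
#' @examples
#' tab <- event_table(data.frame(
#'   ID = 1, TIME = c(0, 90), EVID = 1, DVID = NA,
#'   AMT = 5e6, DV = NA, WT = c(77, 75)
#' ))
#' covariate_at(tab, 1, "WT", 45) # 77 under LOCF
#' @export
covariate_at <- function(table, subject_id, name, time,
                         rule = c("locf", "linear")) {
  rule <- match.arg(rule)
  if (!name %in% names(table)) {
    stop("unknown covariate: ", name, call. = FALSE)
  }
  rows <- table[table$ID == subject_id & !is.na(table[[name]]), ]
  if (nrow(rows) == 0) {
    stop("subject ", subject_id, " carries no record of covariate ", name,
         call. = FALSE)
  }
  tt <- rows$TIME
  vv <- rows[[name]]
  keep <- !duplicated(tt)
  tt <- tt[keep]; vv <- vv[keep]
  if (time < tt[1]) {
    warning("query time precedes first ", name, " record for subject ",
            subject_id, "; returning the baseline value", call. = FALSE)
    return(vv[1])
  }
  if (rule == "locf") {
    vv[findInterval(time, tt)]
  } else {
    stats::approx(tt, vv, xout = time, rule = 2)$y
  }
}

#' @export
print.event_table <- function(x, ...) {
  cnt <- event_counts(x)
  cat("<event_table> ", length(unique(x$ID)), " subjects, lloq = ",
      attr(x, "lloq"), " ng/mL\n", sep = "")
  cat(paste0("  ", cnt$kind, ": ", cnt$n, collapse = "\n"), "\n")
  NextMethod()
}
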