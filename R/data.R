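#' Longitudinal person-time data for g-formula estimation
#'
#' Wraps a long-format person-time table (one row per subject per follow-up
#' interval) together with the column roles needed by [gformula()]. The time
#' index must start at 0 for each subject (or at `-i` when `i` pre-baseline
#' records per subject are supplied) and increase in increments of 1.
#'
#' @param data a data.frame in long format.
#' @param id name of the subject identifier column. Identifiers may be
#'   arbitrary strings; they only need to be unique per subject.
#' @param time_name name of the integer time-index column.
#' @param covnames character vector of time-varying covariate columns, in the
#'   order used to factorise their joint distribution.
#' @param outcome_name name of the outcome column (`Y[k+1]` on row `k` for
#'   survival outcomes; the end-of-follow-up value, read from row `k = K`,
#'   otherwise).
#' @param basecovs optional character vector of baseline covariate columns
#'   (constant within subject).
#' @param compevent_name optional name of the competing-event indicator
#'   column (`D[k+1]` on row `k`).
#' @return An object of class `gf_data`: the data.frame ordered by subject
#'   and time, with attributes `id`, `time_name`, `covnames`, `basecovs`,
#'   `outcome_name`, `compevent_name`, `n` (baseline sample size), `K`
#'   (maximum follow-up index) and `prebaseline` (maximum number of
#'   pre-baseline records, 0 if none).
#' @seealso [load_table()], [validate_gf_data()]
#' @export
gf_data <- function(data, id, time_name, covnames, outcome_name,
                    basecovs = NULL, compevent_name = NULL) {
  stopifnot(is.data.frame(data))
  data <- as.data.frame(data)
  needed <- c(id, time_name, covnames, outcome_name, basecovs, compevent_name)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0L) {
    stop("column(s) not found in data: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(data) == 0L) stop("input table has no rows", call. = FALSE)
  tvals <- data[[time_name]]
  if (!is.numeric(tvals) || any(is.na(tvals)) || any(tvals != round(tvals))) {
    stop("time column '", time_name, "' must contain integer values",
         call. = FALSE)
  }
  data[[time_name]] <- as.integer(tvals)
  data <- data[order(match(data[[id]], unique(data[[id]])), data[[time_name]]), ,
               drop = FALSE]
  rownames(data) <- NULL
  structure(data,
            id = id, time_name = time_name, covnames = covnames,
            basecovs = basecovs, outcome_name = outcome_name,
            compevent_name = compevent_name,
            n = length(unique(data[[id]])),
            K = max(data[[time_name]]),
            prebaseline = max(0L, -min(data[[time_name]])),
            class = c("gf_data", "data.frame"))
}

#' Read a long-format person-time table from CSV
#'
#' Reads a UTF-8 CSV with a header row. Empty fields and the literal string
#' `"NA"` are loaded as missing values; missing outcome values are preserved
#' (never coerced to 0), matching the convention that a censored subject's
#' last outcome value may be coded either `NA` or 0.
#'
#' @inheritParams gf_data
#' @param path path to the CSV file.
#' @return A [gf_data] object.
#' @export
load_table <- function(path, id, time_name, covnames, outcome_name,
                       basecovs = NULL, compevent_name = NULL) {
  if (!file.exists(path)) stop("data file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, na.strings = c("", "NA"),
                         stringsAsFactors = FALSE, check.names = FALSE)
  gf_data(raw, id = id, time_name = time_name, covnames = covnames,
          outcome_name = outcome_name, basecovs = basecovs,
          compevent_name = compevent_name)
}

#' Outcome specification
#'
#' Describes the outcome of interest: a survival (failure time) outcome with
#' optional competing events, or a continuous or binary outcome measured at
#' the end of follow-up.
#'
#' @param outcome_type one of `"survival"`, `"continuous_eof"`,
#'   `"binary_eof"`.
#' @param outcome_name outcome column name.
#' @param compevent_name optional competing-event column name; only allowed
#'   for survival outcomes when competing events are modelled rather than
#'   treated as censoring events.
#' @param treat_compevent_as_censoring logical; if `TRUE`, competing events
#'   are treated like censoring events (targets a direct effect under
#'   elimination of competing events) and `compevent_name` must not be set.
#' @param time_points the follow-up horizon `k*` through which risks are
#'   reported; defaults to `K + 1` when left `NULL`.
#' @return An object of class `gf_outcome_spec`.
#' @export
gf_outcome_spec <- function(outcome_type = c("survival", "continuous_eof",
                                             "binary_eof"),
                            outcome_name,
                            compevent_name = NULL,
                            treat_compevent_as_censoring = FALSE,
                            time_points = NULL) {
  outcome_type <- match.arg(outcome_type)
  if (!is.null(compevent_name) &&
      (outcome_type != "survival" || treat_compevent_as_censoring)) {
    stop("compevent_name may only be set for survival outcomes when ",
         "competing events are not treated as censoring events",
         call. = FALSE)
  }
  structure(list(outcome_type = outcome_type,
                 outcome_name = outcome_name,
                 compevent_name = compevent_name,
                 treat_compevent_as_censoring =
                   isTRUE(treat_compevent_as_censoring),
                 time_points = time_points),
            class = "gf_outcome_spec")
}

#' Resolve the follow-up horizon k*
#'
#' Returns the user-specified number of time points when given, and `K + 1`
#' (the full follow-up) otherwise.
#'
#' @param table a [gf_data] object.
#' @param time_points optional positive integer `k* <= K + 1`.
#' @return integer horizon `k*`.
#' @export
resolve_horizon <- function(table, time_points = NULL) {
  K <- attr(table, "K")
  if (is.null(time_points)) return(K + 1L)
  time_points <- as.integer(time_points)
  if (length(time_points) != 1L || is.na(time_points) ||
      time_points <= 0L || time_points > K + 1L) {
    stop("time_points must be a single integer in 1..K+1 = ", K + 1L,
         call. = FALSE)
  }
  time_points
}

#' Validate a longitudinal table against the input coding rules
#'
#' Checks, per subject: consecutive integer time values starting at 0 (or at
#' `-i` with pre-baseline records); constant baseline covariates; for
#' survival outcomes, that an event (`Y = 1`) or competing event (`D = 1`)
#' appears only on a subject's last row and that `Y` is missing on a
#' competing-event row; for end-of-follow-up outcomes, that subjects never
#' have more than `K + 1` follow-up rows. All violations are collected (the
#' check is not fail-fast).
#'
#' @param table a [gf_data] object.
#' @param ospec a [gf_outcome_spec].
#' @return An object of class `gf_validation`: a list with elements `pass`
#'   (logical) and `violations` (data.frame with columns `id`, `time`,
#'   `rule`, `message`).
#' @export
validate_gf_data <- function(table, ospec) {
  idc <- attr(table, "id"); tc <- attr(table, "time_name")
  ycol <- ospec$outcome_name
  dcol <- ospec$compevent_name
  pre <- attr(table, "prebaseline")
  viol <- list()
  add <- function(id, time, rule, message) {
    viol[[length(viol) + 1L]] <<- data.frame(
      id = as.character(id), time = as.integer(time), rule = rule,
      message = message, stringsAsFactors = FALSE)
  }
  for (sid in unique(table[[idc]])) {
    rows <- table[table[[idc]] == sid, , drop = FALSE]
    tt <- sort(rows[[tc]])
    t0 <- tt[1L]
    if (t0 > 0L) add(sid, t0, "time_start", "time index does not start at 0")
    if (t0 < -pre) add(sid, t0, "time_start", "time index below -i")
    if (length(tt) > 1L && any(diff(tt) != 1L)) {
      add(sid, tt[which(diff(tt) != 1L)[1L] + 1L], "time_gap",
          "non-consecutive time index")
    }
    for (bc in attr(table, "basecovs")) {
      if (length(unique(rows[[bc]])) > 1L) {
        add(sid, t0, "baseline_constant",
            paste0("baseline covariate '", bc, "' varies within subject"))
      }
    }
    fup <- rows[rows[[tc]] >= 0L, , drop = FALSE]
    if (nrow(fup) == 0L) {
      add(sid, t0, "no_followup", "subject has no follow-up rows")
      next
    }
    if (ospec$outcome_type == "survival") {
      y <- fup[[ycol]]
      ev <- which(!is.na(y) & y == 1)
      if (length(ev) > 0L && ev[1L] < nrow(fup)) {
        add(sid, fup[[tc]][ev[1L]], "records_after_event",
            "records after event")
      }
      if (!is.null(dcol)) {
        d <- fup[[dcol]]
        de <- which(!is.na(d) & d == 1)
        if (length(de) > 0L) {
          if (de[1L] < nrow(fup)) {
            add(sid, fup[[tc]][de[1L]], "records_after_compevent",
                "records after competing event")
          }
          if (!is.na(y[de[1L]])) {
            add(sid, fup[[tc]][de[1L]], "compevent_outcome_na",
                "outcome must be missing on a competing-event row")
          }
        }
      }
    } else {
      K <- attr(table, "K")
      if (nrow(fup) > K + 1L) {
        add(sid, fup[[tc]][nrow(fup)], "too_many_rows",
            "more than K+1 follow-up rows")
      }
    }
  }
  violations <- if (length(viol) > 0L) {
    do.call(rbind, viol)
  } else {
    data.frame(id = character(), time = integer(), rule = character(),
               message = character(), stringsAsFactors = FALSE)
  }
  structure(list(pass = nrow(violations) == 0L, violations = violations),
            class = "gf_validation")
}

#' @export
print.gf_validation <- function(x, ...) {
  if (x$pass) {
    cat("Longitudinal table: all coding rules satisfied\n")
  } else {
    cat("Longitudinal table: ", nrow(x$violations), " violation(s)\n", sep = "")
    print(x$violations)
  }
  invisible(x)
}
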