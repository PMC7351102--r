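#' Nonparametric natural-course risk
#'
#' Discrete-time product-limit estimate of the risk by each follow-up
#' interval under the natural course, used as a model diagnostic: the
#' interval hazard is the number of events among subjects with a record at
#' `t` divided by the number at risk, and censored subjects leave the risk
#' set at the interval where their records stop. With modelled competing
#' events the Aalen-Johansen form is used,
#' `R(k) = sum_{t<=k} h_t * prod_{j<t} (1 - h_j - hD_j)`, with `hD` the
#' interval proportion of competing events. With no censoring or competing
#' events this reduces to the empirical cumulative proportion failed.
#'
#' @param table a [gf_data] object.
#' @param ospec a [gf_outcome_spec] with `outcome_type = "survival"`.
#' @param time_points horizon `k*` (default `K + 1`).
#' @return data.frame with columns `k`, `n_risk`, `events`, `compevents`,
#'   `risk`.
#' @export
np_risk <- function(table, ospec, time_points = NULL) {
  if (ospec$outcome_type != "survival") {
    stop("np_risk is defined for survival outcomes", call. = FALSE)
  }
  time_points <- resolve_horizon(table, time_points)
  tc <- attr(table, "time_name")
  ycol <- ospec$outcome_name
  dcol <- ospec$compevent_name
  h <- hd <- numeric(time_points)
  n_risk <- events <- compevents <- integer(time_points)
  for (t in seq.int(0L, time_points - 1L)) {
    rows <- table[table[[tc]] == t, , drop = FALSE]
    nr <- nrow(rows)
    n_risk[t + 1L] <- nr
    if (nr == 0L) {
      warning("no subjects at risk at time ", t,
              "; risk reported as missing from there on", call. = FALSE)
      h[(t + 1L):time_points] <- NA_real_
      break
    }
    y <- rows[[ycol]]
    events[t + 1L] <- sum(!is.na(y) & y == 1)
    h[t + 1L] <- events[t + 1L] / nr
    if (!is.null(dcol)) {
      d <- rows[[dcol]]
      compevents[t + 1L] <- sum(!is.na(d) & d == 1)
      hd[t + 1L] <- compevents[t + 1L] / nr
    }
  }
  surv <- cumprod(1 - h - hd)
  risk <- cumsum(h * c(1, surv[-time_points]))
  data.frame(k = seq.int(0L, time_points - 1L), n_risk = n_risk,
             events = events, compevents = compevents, risk = risk)
}

#' Nonparametric covariate means by follow-up time
#'
#' Arithmetic mean of each time-varying covariate at each follow-up time
#' among subjects with a record at that time (no censoring weights).
#' Categorical covariates are expanded into per-level proportions.
#'
#' @param table a [gf_data] object.
#' @param time_points horizon `k*` (default `K + 1`).
#' @param categorical character vector of covariates to summarise as
#'   per-level proportions.
#' @return data.frame with columns `k`, one column per covariate (or
#'   covariate level, named `cov==level`).
#' @export
np_covariate_means <- function(table, time_points = NULL,
                               categorical = character(0)) {
  time_points <- resolve_horizon(table, time_points)
  tc <- attr(table, "time_name")
  covnames <- attr(table, "covnames")
  ks <- seq.int(0L, time_points - 1L)
  out <- data.frame(k = ks)
  for (v in covnames) {
    if (v %in% categorical) {
      levs <- sort(unique(as.character(table[[v]][table[[tc]] >= 0L])))
      for (lev in levs) {
        out[[paste0(v, "==", lev)]] <- vapply(ks, function(t) {
          z <- table[[v]][table[[tc]] == t]
          mean(as.character(z) == lev, na.rm = TRUE)
        }, numeric(1))
      }
    } else {
      out[[v]] <- vapply(ks, function(t) {
        mean(table[[v]][table[[tc]] == t], na.rm = TRUE)
      }, numeric(1))
    }
  }
  out
}

#' Nonparametric end-of-follow-up outcome mean
#'
#' Mean of the outcome over rows with time index `K` and a non-missing
#' outcome (subjects under follow-up through the final interval).
#'
#' @param table a [gf_data] object.
#' @param ospec a [gf_outcome_spec] with an end-of-follow-up outcome type.
#' @return scalar mean.
#' @export
np_eof_mean <- function(table, ospec) {
  if (ospec$outcome_type == "survival") {
    stop("np_eof_mean is defined for end-of-follow-up outcomes",
         call. = FALSE)
  }
  tc <- attr(table, "time_name")
  y <- table[[ospec$outcome_name]][table[[tc]] == attr(table, "K")]
  y <- y[!is.na(y)]
  if (length(y) == 0L) {
    stop("no uncensored subjects at the end of follow-up", call. = FALSE)
  }
  mean(y)
}
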