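#' Functions of covariate history
#'
#' The covariate, treatment, outcome and competing-event models may depend on
#' deterministic functions of past covariate values. Three pre-coded history
#' functions are available, generating columns with a fixed naming scheme
#' that is part of the formula vocabulary:
#'
#' * `lag{i}_Z` — the value of `Z` at time `k - i` (0 on rows with no such
#'   time available for the subject).
#' * `cumavg_Z` — the mean of `Z` over follow-up times `0..k`; equal to
#'   `Z` itself at `k = 0`. Pre-baseline rows never enter the average.
#' * `lag_cumavg{i}_Z` — the cumulative average at time `k - i` (0 on rows
#'   with `k < i`).
#'
#' Lags may read pre-baseline values (negative time indices) when present.
#' The lag padding value is 0 even for categorical covariates; the level set
#' of a padded categorical lag column therefore gains a `"0"` level if the
#' covariate does not already have one.
#'
#' @param table a [gf_data] object.
#' @param vars character vector of covariate names.
#' @param lags maximum lag `r >= 1`; columns are added for `i = 1..r`.
#' @return The table with the new columns appended; rows and row order are
#'   unchanged.
#' @name history
NULL

## split row indices by subject, in table order
.subject_rows <- function(table) {
  idc <- attr(table, "id")
  split(seq_len(nrow(table)), match(table[[idc]], unique(table[[idc]])))
}

.pad0 <- function(template) {
  if (is.numeric(template)) 0 else "0"
}

#' @rdname history
#' @export
add_lagged <- function(table, vars, lags = 1L) {
  stopifnot(lags >= 1L)
  unknown <- setdiff(vars, names(table))
  if (length(unknown) > 0L) {
    stop("unknown variable(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  groups <- .subject_rows(table)
  for (v in vars) {
    z <- table[[v]]
    if (is.factor(z)) z <- as.character(z)
    for (i in seq_len(lags)) {
      out <- rep(.pad0(z), length(z))
      for (g in groups) {
        ng <- length(g)
        if (ng > i) out[g[(i + 1L):ng]] <- z[g[1L:(ng - i)]]
      }
      table[[paste0("lag", i, "_", v)]] <- out
    }
  }
  table
}

#' @rdname history
#' @export
add_cumavg <- function(table, vars) {
  unknown <- setdiff(vars, names(table))
  if (length(unknown) > 0L) {
    stop("unknown variable(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  tc <- attr(table, "time_name")
  groups <- .subject_rows(table)
  for (v in vars) {
    z <- table[[v]]
    if (!is.numeric(z)) {
      stop("cumavg requires a numeric covariate: ", v, call. = FALSE)
    }
    out <- numeric(length(z))
    for (g in groups) {
      fup <- g[table[[tc]][g] >= 0L]
      if (length(fup) > 0L) {
        out[fup] <- cumsum(z[fup]) / seq_along(fup)
      }
      pre <- g[table[[tc]][g] < 0L]
      out[pre] <- 0
    }
    table[[paste0("cumavg_", v)]] <- out
  }
  table
}

#' @rdname history
#' @export
add_lag_cumavg <- function(table, vars, lags = 1L) {
  stopifnot(lags >= 1L)
  table2 <- add_cumavg(table, vars)
  tc <- attr(table, "time_name")
  groups <- .subject_rows(table)
  for (v in vars) {
    ca <- table2[[paste0("cumavg_", v)]]
    for (i in seq_len(lags)) {
      out <- numeric(length(ca))
      for (g in groups) {
        fup <- g[table[[tc]][g] >= 0L]
        nf <- length(fup)
        if (nf > i) out[fup[(i + 1L):nf]] <- ca[fup[1L:(nf - i)]]
      }
      table[[paste0("lag_cumavg", i, "_", v)]] <- out
    }
  }
  table
}

## ---- formula scanning ------------------------------------------------------

## Identify which history features the model formulas require.
## Returns list(lag = named max-lag per var, lagavg = named max-lag per var,
##              cumavg = character vector of vars)
infer_history <- function(formulas, covnames) {
  vars <- unique(unlist(lapply(formulas, all.vars)))
  lag <- integer(0); lagavg <- integer(0); cumavg <- character(0)
  for (v in vars) {
    m <- regmatches(v, regexec("^lag_cumavg([0-9]+)_(.+)$", v))[[1]]
    if (length(m) == 3L && m[3] %in% covnames) {
      i <- as.integer(m[2])
      lagavg[m[3]] <- max(i, lagavg[m[3]], 0L, na.rm = TRUE)
      next
    }
    m <- regmatches(v, regexec("^lag([0-9]+)_(.+)$", v))[[1]]
    if (length(m) == 3L && m[3] %in% covnames) {
      i <- as.integer(m[2])
      lag[m[3]] <- max(i, lag[m[3]], 0L, na.rm = TRUE)
      next
    }
    m <- regmatches(v, regexec("^cumavg_(.+)$", v))[[1]]
    if (length(m) == 2L && m[2] %in% covnames) {
      cumavg <- union(cumavg, m[2])
    }
  }
  list(lag = lag, lagavg = lagavg, cumavg = cumavg)
}

## Apply all required history columns to an observed table before fitting.
add_history_columns <- function(table, hist) {
  for (v in names(hist$lag)) table <- add_lagged(table, v, hist$lag[[v]])
  for (v in names(hist$lagavg)) table <- add_lag_cumavg(table, v, hist$lagavg[[v]])
  for (v in setdiff(hist$cumavg, character(0))) {
    if (!paste0("cumavg_", v) %in% names(table)) {
      table <- add_cumavg(table, v)
    }
  }
  table
}

## ---- incremental history state (vectorised over s simulated subjects) -----

## The simulator maintains, per tracked covariate, a ring-free buffer of the
## most recent `r` values (column 1 = previous time), a running sum/count for
## the cumulative average, and a buffer of the most recent cumulative
## averages. Pushing pre-baseline rows updates only the lag buffers, so the
## cumulative average starts at k = 0 exactly as in the batch computation.
hs_init <- function(s, hist, categorical = character(0)) {
  lagbuf <- list(); cumsums <- list(); lagavgbuf <- list()
  for (v in names(hist$lag)) {
    r <- hist$lag[[v]]
    pad <- if (v %in% categorical) "0" else 0
    lagbuf[[v]] <- matrix(pad, nrow = s, ncol = r)
  }
  cum_vars <- union(hist$cumavg, names(hist$lagavg))
  for (v in cum_vars) cumsums[[v]] <- numeric(s)
  for (v in names(hist$lagavg)) {
    lagavgbuf[[v]] <- matrix(0, nrow = s, ncol = hist$lagavg[[v]])
  }
  list(s = s, lagbuf = lagbuf, cumsums = cumsums, cumn = 0L,
       lagavgbuf = lagavgbuf, hist = hist)
}

## values: named list of length-s vectors for every tracked covariate.
hs_push <- function(state, values, update_cumavg = TRUE) {
  if (update_cumavg) {
    for (v in names(state$cumsums)) {
      state$cumsums[[v]] <- state$cumsums[[v]] + as.numeric(values[[v]])
    }
    state$cumn <- state$cumn + 1L
    for (v in names(state$lagavgbuf)) {
      buf <- state$lagavgbuf[[v]]
      ca <- state$cumsums[[v]] / state$cumn
      if (ncol(buf) > 1L) buf[, 2L:ncol(buf)] <- buf[, 1L:(ncol(buf) - 1L)]
      buf[, 1L] <- ca
      state$lagavgbuf[[v]] <- buf
    }
  }
  for (v in names(state$lagbuf)) {
    buf <- state$lagbuf[[v]]
    val <- values[[v]]
    if (is.character(buf[1L])) val <- as.character(val)
    if (ncol(buf) > 1L) buf[, 2L:ncol(buf)] <- buf[, 1L:(ncol(buf) - 1L)]
    buf[, 1L] <- val
    state$lagbuf[[v]] <- buf
  }
  state
}

## Lagged features available at the start of a time step (before any
## current-time value is known).
hs_lag_features <- function(state) {
  out <- list()
  for (v in names(state$lagbuf)) {
    buf <- state$lagbuf[[v]]
    for (i in seq_len(ncol(buf))) out[[paste0("lag", i, "_", v)]] <- buf[, i]
  }
  for (v in names(state$lagavgbuf)) {
    buf <- state$lagavgbuf[[v]]
    for (i in seq_len(ncol(buf))) {
      out[[paste0("lag_cumavg", i, "_", v)]] <- buf[, i]
    }
  }
  out
}

## Cumulative average through the current time, given the current value.
hs_cumavg_current <- function(state, v, current) {
  if (is.null(state$cumsums[[v]])) {
    stop("cumavg not tracked for ", v, call. = FALSE)
  }
  (state$cumsums[[v]] + as.numeric(current)) / (state$cumn + 1L)
}
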