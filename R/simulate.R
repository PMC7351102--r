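#' Sample the baseline covariate distribution
#'
#' Step 2 of the parametric g-formula starts each simulated history from the
#' observed baseline distribution: if the Monte Carlo sample size `s` equals
#' the number of observed subjects `n`, every observed baseline row is used
#' exactly once; otherwise `s` baselines are resampled with replacement. A
#' subject's baseline covariates, time-varying covariate values at `k = 0`
#' and any pre-baseline history are taken jointly.
#'
#' @param table a [gf_data] object.
#' @param s Monte Carlo sample size (`s >= 1`).
#' @return A list with `idx` (source subject positions), `base` (data.frame
#'   of `s` baseline rows) and `pre` (a list, one element per pre-baseline
#'   time from `-i` to `-1`, each a data.frame of covariate values with 0
#'   filled in for subjects lacking that record).
#' @export
sample_baseline <- function(table, s) {
  s <- as.integer(s)
  if (is.na(s) || s < 1L) stop("nsimul must be a positive integer",
                               call. = FALSE)
  idc <- attr(table, "id"); tc <- attr(table, "time_name")
  covnames <- attr(table, "covnames"); basecovs <- attr(table, "basecovs")
  ids <- unique(table[[idc]])
  n <- length(ids)
  idx <- if (s == n) seq_len(n) else sample.int(n, s, replace = TRUE)
  b0 <- table[table[[tc]] == 0L, , drop = FALSE]
  b0 <- b0[match(ids, b0[[idc]]), , drop = FALSE]
  base <- b0[idx, c(covnames, basecovs), drop = FALSE]
  rownames(base) <- NULL
  pre <- list()
  i_max <- attr(table, "prebaseline")
  if (i_max > 0L) {
    for (t in seq.int(-i_max, -1L)) {
      rt <- table[table[[tc]] == t, , drop = FALSE]
      m <- match(ids, rt[[idc]])
      vals <- as.data.frame(lapply(covnames, function(v) {
        col <- rt[[v]][m]
        fill <- if (is.numeric(table[[v]])) 0 else "0"
        col[is.na(m)] <- fill
        col[idx]
      }), col.names = covnames, stringsAsFactors = FALSE)
      pre[[as.character(t)]] <- vals
    }
  }
  list(idx = idx, base = base, pre = pre)
}

#' Convert discrete-time hazards into cumulative risks
#'
#' Along one simulated history, the risk of the event of interest by each
#' interval is accumulated from the predicted hazards. Without competing
#' events (or with competing events treated as censoring),
#' `R(k) = sum_{t<=k} p_t * prod_{j<t} (1 - p_j)`. With a modelled competing
#' event (cause-specific cumulative incidence), the competing event is
#' resolved before the outcome within each interval:
#' `R(k) = sum_{t<=k} (1 - q_t) p_t * prod_{j<t} (1 - p_j)(1 - q_j)`.
#'
#' @param p matrix (histories x times) or vector of outcome hazards.
#' @param q optional matrix/vector of competing-event hazards (same shape).
#' @param mode `"no_compevent"`, `"compevent_censored"` or
#'   `"compevent_modeled"`.
#' @return risk by each interval, same shape as `p`; nondecreasing along
#'   time and bounded by 1.
#' @export
risk_from_hazards <- function(p, q = NULL,
                              mode = c("no_compevent", "compevent_censored",
                                       "compevent_modeled")) {
  mode <- match.arg(mode)
  vec <- is.vector(p)
  if (vec) p <- matrix(p, nrow = 1L)
  if (any(p < 0 | p > 1)) stop("hazards must lie in [0,1]", call. = FALSE)
  if (mode == "compevent_modeled") {
    if (is.null(q)) stop("competing hazards required", call. = FALSE)
    if (vec && is.vector(q)) q <- matrix(q, nrow = 1L)
    if (!all(dim(q) == dim(p))) {
      stop("outcome and competing hazard sequences differ in length",
           call. = FALSE)
    }
    surv_step <- (1 - p) * (1 - q)
    term <- (1 - q) * p
  } else {
    surv_step <- 1 - p
    term <- p
  }
  T_ <- ncol(p)
  risk <- matrix(0, nrow(p), T_)
  surv <- rep(1, nrow(p))
  acc <- rep(0, nrow(p))
  for (t in seq_len(T_)) {
    acc <- acc + surv * term[, t]
    risk[, t] <- acc
    surv <- surv * surv_step[, t]
  }
  if (vec) risk <- as.vector(risk)
  risk
}

## Build the feature frame columns shared by every model at time k.
## cur: named list of current covariate values already assigned at k.
.assemble_features <- function(k, time_name, base, basecovs, lagfeat,
                               cur, state, cumavg_vars) {
  feat <- data.frame(row.names = seq_len(nrow(base)))
  feat[[time_name]] <- k
  for (b in basecovs) feat[[b]] <- base[[b]]
  for (nm in names(lagfeat)) feat[[nm]] <- lagfeat[[nm]]
  for (v in names(cur)) {
    feat[[v]] <- cur[[v]]
    if (v %in% cumavg_vars) {
      feat[[paste0("cumavg_", v)]] <- hs_cumavg_current(state, v, cur[[v]])
    }
  }
  feat
}

#' Simulate a cohort of counterfactual histories under one intervention
#'
#' Step 2 of the parametric g-formula for a single strategy: starting from
#' the sampled baselines, covariates at each `k >= 1` are simulated one at a
#' time in factorisation order, each conditional on already-simulated
#' same-time covariates earlier in the order and on history features of all
#' covariates; the natural value of every treatment is drawn from its fitted
#' model and then replaced according to the intervention rule. After the
#' covariates at `k` are assigned, the discrete-time outcome hazard (and
#' competing-event hazard, when modelled) is predicted; for end-of-follow-up
#' outcomes the outcome model's prediction is computed at `k = K`.
#'
#' @param models named list of `gf_cov_fit` objects in factorisation order.
#' @param outcome_fit a `gf_outcome_fit`.
#' @param compevent_fit optional `gf_compevent_fit`.
#' @param ospec a [gf_outcome_spec].
#' @param ispec a `gf_intervention`.
#' @param baseline result of [sample_baseline()].
#' @param time_points horizon `k*`.
#' @param time_name time index column name.
#' @param basecovs baseline covariate names.
#' @param hist history requirements as inferred from the model formulas.
#' @return An object of class `gf_cohort`: predicted hazard matrices `p` and
#'   `q` (`s x k*`, survival) or end-of-follow-up predictions `eof_pred`,
#'   per-history risks, per-time covariate value matrices, and the natural
#'   and assigned values of the intervened treatments.
#' @export
simulate_cohort <- function(models, outcome_fit, compevent_fit = NULL,
                            ospec, ispec, baseline, time_points, time_name,
                            basecovs, hist) {
  s <- nrow(baseline$base)
  covnames <- names(models)
  categorical <- covnames[vapply(models, function(m) {
    m$spec$covtype %in% c("categorical", "categorical_time")
  }, logical(1))]
  intervened <- vapply(ispec$components, `[[`, "", "var")
  cumavg_vars <- union(hist$cumavg, names(hist$lagavg))

  state <- hs_init(s, hist, categorical = categorical)
  for (predf in baseline$pre) {
    state <- hs_push(state, as.list(predf), update_cumavg = FALSE)
  }

  survival <- ospec$outcome_type == "survival"
  p <- if (survival) matrix(NA_real_, s, time_points)
  q <- if (survival && !is.null(compevent_fit)) {
    matrix(NA_real_, s, time_points)
  }
  eof_pred <- NULL
  covvals <- lapply(covnames, function(v) {
    if (v %in% categorical) {
      matrix(NA_character_, s, time_points)
    } else {
      matrix(NA_real_, s, time_points)
    }
  })
  names(covvals) <- covnames
  nat_treat <- lapply(intervened, function(v) matrix(NA_real_, s, time_points))
  names(nat_treat) <- intervened

  for (k in seq.int(0L, time_points - 1L)) {
    lagfeat <- hs_lag_features(state)
    cur <- list()
    feat <- .assemble_features(k, time_name, baseline$base, basecovs,
                               lagfeat, cur, state, cumavg_vars)
    for (v in covnames) {
      if (k == 0L) {
        natv <- baseline$base[[v]]
        if (v %in% categorical) natv <- as.character(natv)
      } else {
        natv <- tryCatch(
          draw_covariate(models[[v]], feat, k = k),
          error = function(e) {
            stop("failed to simulate covariate '", v, "' at time ", k, ": ",
                 conditionMessage(e), call. = FALSE)
          })
      }
      val <- natv
      if (v %in% intervened) {
        nat_treat[[v]][, k + 1L] <- as.numeric(natv)
        assigned <- apply_interventions(ispec, k,
                                        stats::setNames(list(natv), v), feat)
        val <- assigned[[v]]
      }
      cur[[v]] <- val
      covvals[[v]][, k + 1L] <- val
      feat[[v]] <- val
      if (v %in% cumavg_vars) {
        feat[[paste0("cumavg_", v)]] <- hs_cumavg_current(state, v, val)
      }
    }
    if (survival) {
      p[, k + 1L] <- predict_probability(outcome_fit, feat)
      if (!is.null(q)) q[, k + 1L] <- predict_probability(compevent_fit, feat)
    } else if (k == time_points - 1L) {
      eof_pred <- as.numeric(stats::predict(outcome_fit$fit, newdata = feat,
                                            type = "response"))
    }
    state <- hs_push(state, cur, update_cumavg = TRUE)
  }

  risk <- NULL
  if (survival) {
    mode <- if (!is.null(q)) "compevent_modeled" else "no_compevent"
    risk <- risk_from_hazards(p, q, mode = mode)
  }
  structure(list(description = ispec$description, s = s,
                 p = p, q = q, risk = risk, eof_pred = eof_pred,
                 covariates = covvals, natural_treatment = nat_treat),
            class = "gf_cohort")
}

#' Point estimates from a simulated cohort
#'
#' Survival outcomes: the risk at each follow-up interval, averaged over the
#' simulated histories' hazard-based risks. End-of-follow-up outcomes: the
#' mean of the outcome model's predictions at the final interval.
#'
#' @param cohort a `gf_cohort`.
#' @param ospec a [gf_outcome_spec].
#' @return For survival, a numeric vector of risks by `k = 0..k*-1`; for
#'   end-of-follow-up outcomes, a single mean.
#' @export
estimate_intervention <- function(cohort, ospec) {
  if (ospec$outcome_type == "survival") {
    colMeans(cohort$risk)
  } else {
    mean(cohort$eof_pred)
  }
}

## Mean of each covariate by follow-up time in a simulated cohort;
## categorical covariates are expanded into per-level proportions.
sim_covariate_means <- function(cohort) {
  out <- list()
  for (v in names(cohort$covariates)) {
    m <- cohort$covariates[[v]]
    if (is.character(m)) {
      for (lev in sort(unique(as.vector(m)))) {
        out[[paste0(v, "==", lev)]] <- colMeans(m == lev)
      }
    } else {
      out[[v]] <- colMeans(m)
    }
  }
  out
}
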